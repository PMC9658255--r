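## Map crosslink densities to storage and loss moduli.
##
## Each species contributes entropic network elasticity above its
## percolation threshold, modified by solvent swelling; the frequency
## response of each channel follows its element type: Winter critical gel
## (PC), fractional Maxwell (sJZ), fractional Kelvin-Voigt (JZ), plus the
## Newtonian polymer-liquid loss.

.excess <- function(n, nc) pmax(n - nc, 0)

#' Swelling factor of the gel network
#'
#' Specific-volume correction `(v/v0)^(1/3) = S * sum_j (n_j - nc_j) / C0`
#' over all crosslink species. Sub-percolation species are clamped at zero
#' so the factor is non-negative (the formula does not state the
#' sub-threshold behaviour; clamping each term keeps the factor and every
#' amplitude it multiplies non-negative).
#'
#' @param densities tibble with columns `n_PC`, `n_sJZ`, `n_JZ`
#'   (from [species_concentrations()]).
#' @param C0 total galacturonic acid concentration, mol/L.
#' @param network a [network_params()] object.
#' @return Dimensionless swelling factor(s), `>= 0`.
#' @export
swelling_factor <- function(densities, C0, network = network_params()) {
  nc <- percolation_densities(C0, network)
  network$S * (.excess(densities$n_PC, nc[["PC"]]) +
               .excess(densities$n_sJZ, nc[["sJZ"]]) +
               .excess(densities$n_JZ, nc[["JZ"]])) / C0
}

#' Frequency-independent network amplitudes per crosslink species
#'
#' Entropic amplitudes `G_i = A (v/v0)^(1/3) kB T (n_i - nc_i)` with the
#' conversion `A = 1e3 N_A` from mol/L to chains per cubic metre. The
#' transient channels (sJZ, PC) carry the active-crosslink ratio `r_act`;
#' the PC amplitude is additionally suppressed by
#' `max(1 - n_JZ/nc_JZ, 0)`, the fraction of point-like crosslinks not yet
#' absorbed into junction zones.
#'
#' @inheritParams swelling_factor
#' @return Tibble with columns `G_PC`, `G_sJZ`, `G_JZ` in Pa.
#' @export
base_amplitudes <- function(densities, C0, network = network_params()) {
  nc <- percolation_densities(C0, network)
  sw <- swelling_factor(densities, C0, network)
  kTA <- .A_conv * .kB * network$T
  tibble(
    G_PC  = kTA * network$r_act * sw * .excess(densities$n_PC, nc[["PC"]]) *
      pmax(1 - densities$n_JZ / nc[["JZ"]], 0),
    G_sJZ = kTA * network$r_act * sw * .excess(densities$n_sJZ, nc[["sJZ"]]),
    G_JZ  = kTA * sw * .excess(densities$n_JZ, nc[["JZ"]])
  )
}

#' Loss modulus of the pre-gel polymer liquid
#'
#' Newtonian response `G''_PL = omega eta_s (1 + [eta] Cp)`.
#'
#' @param omega angular frequency, rad/s.
#' @param solvent a [solvent_params()] object.
#' @return Loss modulus in Pa.
#' @export
polymer_liquid_loss <- function(omega, solvent = solvent_params()) {
  if (any(omega <= 0)) abort("`omega` must be positive")
  omega * solvent$eta_s * (1 + solvent$intrinsic_visc * solvent$Cp)
}

#' Per-channel storage and loss moduli at one frequency
#'
#' Combines the network amplitudes with each channel's frequency response:
#' * PC: Winter critical-gel scaling with exponent 1/2. The loss channel is
#'   `G''_PC = (G_PC / r_act) K_PC (omega/omega_ref)^(1/2)`; by default the
#'   storage channel equals it (loss tangent one, the critical-gel
#'   signature), see `pc_storage` in [network_params()].
#' * sJZ: fractional Maxwell element with exponent `alpha_sJZ` and scale
#'   `K_sJZ`; `x = (omega K_sJZ)^alpha` (product convention, default) or
#'   `x = (omega / K_sJZ)^alpha` (ratio convention).
#' * JZ: fractional Kelvin-Voigt element,
#'   `G'_JZ = G_JZ (omega/omega_ref)^alpha_JZ cos(pi alpha_JZ / 2)` and the
#'   sine analogue for loss.
#'
#' @param densities tibble with `n_PC`, `n_sJZ`, `n_JZ` (mol/L).
#' @param omega angular frequency, rad/s (scalar).
#' @param C0 total galacturonic acid concentration, mol/L.
#' @param network a [network_params()] object.
#' @param solvent a [solvent_params()] object.
#' @return Tibble with columns `Gpp_PL`, `Gp_PC`, `Gpp_PC`, `Gp_sJZ`,
#'   `Gpp_sJZ`, `Gp_JZ`, `Gpp_JZ` (Pa).
#' @export
component_moduli <- function(densities, omega, C0,
                             network = network_params(),
                             solvent = solvent_params()) {
  stopifnot(length(omega) == 1)
  amp <- base_amplitudes(densities, C0, network)
  Gpp_PC <- (amp$G_PC / network$r_act) * network$K_PC *
    sqrt(omega / network$omega_ref)
  Gp_PC <- switch(network$pc_storage,
    winter    = Gpp_PC,
    amplitude = amp$G_PC,
    none      = rep(0, nrow(amp)))
  a <- network$alpha_sJZ
  x <- switch(network$sjz_frequency_convention,
    product = (omega * network$K_sJZ)^a,
    ratio   = (omega / network$K_sJZ)^a)
  den <- x^2 + 2 * x * cos(pi * a / 2) + 1
  b <- network$alpha_JZ
  wr <- (omega / network$omega_ref)^b
  tibble(
    Gpp_PL  = rep(polymer_liquid_loss(omega, solvent), nrow(amp)),
    Gp_PC   = Gp_PC,
    Gpp_PC  = Gpp_PC,
    Gp_sJZ  = amp$G_sJZ * (x^2 + x * cos(pi * a / 2)) / den,
    Gpp_sJZ = amp$G_sJZ * x * sin(pi * a / 2) / den,
    Gp_JZ   = amp$G_JZ * wr * cos(pi * b / 2),
    Gpp_JZ  = amp$G_JZ * wr * sin(pi * b / 2)
  )
}

#' Forward model: moduli profile of a gelling sample
#'
#' Full forward map from a binding trajectory to the time-dependent storage
#' and loss moduli at one oscillation frequency. Totals are exact component
#' sums: `Gp = Gp_PC + Gp_sJZ + Gp_JZ` and
#' `Gpp = Gpp_PL + Gpp_PC + Gpp_sJZ + Gpp_JZ`.
#'
#' @param trajectory a [solve_binding_ode()] result.
#' @param omega angular frequency, rad/s (scalar).
#' @param network a [network_params()] object.
#' @param solvent a [solvent_params()] object.
#' @param lengths a [segment_lengths()] object.
#' @param clamp_phi_product passed to [species_concentrations()].
#' @return A tibble of class `"moduli_profile"` with columns `time_s`,
#'   `omega_rad_s`, `R`, `Gp_Pa`, `Gpp_Pa` and the per-channel components.
#' @examples
#' p <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
#' tr <- solve_binding_ode(p, seq(0, 15000, by = 50))
#' prof <- forward_profile(tr, omega = 1)
#' @export
forward_profile <- function(trajectory, omega,
                            network = network_params(),
                            solvent = solvent_params(),
                            lengths = segment_lengths(),
                            clamp_phi_product = FALSE) {
  params <- attr(trajectory, "params")
  if (is.null(params)) abort("trajectory lacks kinetic parameters")
  dens <- species_concentrations(trajectory$R, params$C0, network$phi,
                                 lengths, clamp_phi_product)
  comp <- component_moduli(dens, omega, params$C0, network, solvent)
  out <- dplyr::bind_cols(
    tibble(time_s = trajectory$time_s,
           omega_rad_s = omega,
           R = trajectory$R,
           Gp_Pa = comp$Gp_PC + comp$Gp_sJZ + comp$Gp_JZ,
           Gpp_Pa = comp$Gpp_PL + comp$Gpp_PC + comp$Gpp_sJZ + comp$Gpp_JZ),
    comp)
  class(out) <- c("moduli_profile", class(out))
  attr(out, "params") <- params
  attr(out, "network") <- network
  out
}
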