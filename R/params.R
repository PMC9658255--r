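#' Kinetic parameters of the calcium-binding reaction system
#'
#' Assembles and validates the rate constants, concentrations and derived
#' characteristic scales of the enzyme-catalyzed calcium-pectin binding
#' system. The binding reaction has forward rate constant `k1` (per M^2 per
#' second, second order in carboxyl sites and first order in calcium), the
#' enzymatic demethylation is pseudo-first-order with rate constant `kE`,
#' and the calcium stoichiometry is expressed as `Rmax = 2[Ca2+]/C0`.
#'
#' Exactly one of `gamma` (calcium activity coefficient) or `tau_Ca` (the
#' binding characteristic time, `1/(k1*C0^2*gamma)`) must be supplied; the
#' other is derived. `C0` may be given directly (mol/L) or via `seed_conc`
#' (g seed / 100 mL), which is converted linearly with `seed_conc_to_C0`.
#'
#' Derived fields: `tau_Ca`, `tau_E = 1/kE`, the demethylation ratio
#' `D = 1 - cm0_frac` (initially active carboxyl fraction), and the
#' dimensionless groups `t_bar = tau_E/tau_Ca` and `R_bar = Rmax/D`.
#'
#' @param kE enzymatic demethylation rate constant, 1/s.
#' @param k1 forward binding rate constant, 1/(M^2 s).
#' @param k_rev reverse binding rate constant, 1/s. Defaults to 0: the
#'   dimensionless form of the binding equation that is analyzed and fitted
#'   omits the reverse term.
#' @param gamma calcium activity coefficient (dimensionless), or `NULL` to
#'   derive it from `tau_Ca`.
#' @param tau_Ca calcium-binding characteristic time in seconds, or `NULL`
#'   to derive it from `gamma`.
#' @param C0 total galacturonic acid concentration, mol/L.
#' @param seed_conc seed weight concentration, g/100 mL (alternative to `C0`).
#' @param cm0_frac initial methoxylated fraction `CM0/C0` (dimensionless).
#' @param Rmax calcium-to-binding-site stoichiometry ratio `2[Ca2+]/C0`.
#' @param seed_conc_to_C0 mol/L of galacturonic acid per (g/100 mL) of seeds.
#'
#' @return An object of class `"kinetic_params"`: a named list with the
#'   supplied and derived fields.
#' @examples
#' p <- kinetic_params(kE = 1e-4, k1 = 50, tau_Ca = 980, C0 = 5.22e-3,
#'                     Rmax = 0.158)
#' p$gamma      # ~0.749
#' p$t_bar      # ~10.2
#' @export
kinetic_params <- function(kE, k1 = 50, k_rev = 0, gamma = NULL, tau_Ca = NULL,
                           C0 = NULL, seed_conc = NULL, cm0_frac = 0.6,
                           Rmax, seed_conc_to_C0 = .C0_per_seed) {
  if (is.null(C0)) {
    if (is.null(seed_conc)) abort("supply either `C0` or `seed_conc`")
    C0 <- seed_conc * seed_conc_to_C0
  }
  if (!is.numeric(C0) || C0 <= 0) abort("`C0` must be positive")
  if (kE <= 0 || k1 <= 0) abort("rate constants must be positive")
  if (k_rev < 0) abort("`k_rev` must be non-negative")
  if (cm0_frac < 0 || cm0_frac >= 1) abort("`cm0_frac` must lie in [0, 1)")
  if (Rmax < 0) abort("`Rmax` must be non-negative")
  if (is.null(gamma) && is.null(tau_Ca))
    abort("supply either `gamma` or `tau_Ca` (the other is derived)")
  if (is.null(tau_Ca)) tau_Ca <- 1 / (k1 * C0^2 * gamma)
  if (is.null(gamma)) gamma <- 1 / (k1 * C0^2 * tau_Ca)
  structure(list(
    kE = kE, k1 = k1, k_rev = k_rev, gamma = gamma,
    C0 = C0, cm0_frac = cm0_frac, Rmax = Rmax,
    tau_Ca = tau_Ca, tau_E = 1 / kE,
    D = 1 - cm0_frac, t_bar = (1 / kE) / tau_Ca, R_bar = Rmax / (1 - cm0_frac)
  ), class = "kinetic_params")
}

#' Build kinetic parameters from a flat configuration list
#'
#' Thin wrapper over [kinetic_params()] for configurations read with
#' [read_gel_config()]. Unknown keys are rejected.
#'
#' @param config named list of scalars (keys: `kE`, `k1`, `k_rev`, `gamma`,
#'   `tau_Ca`, `C0`, `seed_conc`, `cm0_frac`, `Rmax`, `seed_conc_to_C0`).
#' @return A `"kinetic_params"` object.
#' @export
derive_params <- function(config) {
  allowed <- names(formals(kinetic_params))
  bad <- setdiff(names(config), allowed)
  if (length(bad)) abort(paste0("unknown kinetic keys: ", paste(bad, collapse = ", ")))
  do.call(kinetic_params, config)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  C0 = %.4g M, Rmax = %.4g, D = %.3g, k_rev = %.3g 1/s\n",
              x$C0, x$Rmax, x$D, x$k_rev))
  cat(sprintf("  tau_Ca = %.4g s, tau_E = %.4g s, t_bar = %.4g, R_bar = %.4g\n",
              x$tau_Ca, x$tau_E, x$t_bar, x$R_bar))
  invisible(x)
}

#' Crosslink species run-length boundaries
#'
#' Consecutive-bound-site run lengths that separate point-like crosslinks
#' (PC), short junction zones (sJZ) and stable egg-box junction zones (JZ).
#' Species intervals are `[l_PC, l_sJZ)`, `[l_sJZ, l_JZ)` and `[l_JZ, Inf)`.
#'
#' @param l_PC,l_sJZ,l_JZ integer run-length boundaries, `1 <= l_PC < l_sJZ < l_JZ`.
#' @return An object of class `"segment_lengths"`.
#' @export
segment_lengths <- function(l_PC = 4, l_sJZ = 6, l_JZ = 8) {
  if (!(1 <= l_PC && l_PC < l_sJZ && l_sJZ < l_JZ))
    abort("need 1 <= l_PC < l_sJZ < l_JZ")
  structure(list(l_PC = l_PC, l_sJZ = l_sJZ, l_JZ = l_JZ),
            class = "segment_lengths")
}

#' Network elasticity and fractional viscoelastic parameters
#'
#' Parameters of the percolation-thresholded network model: the swelling fit
#' constant `S`, the enzyme-enhanced sequential binding factor `phi`, the
#' per-chain percolation numbers `Nc_*` (threshold densities are
#' `nc_i = Nc_i * C0 / DP` with degree of polymerization `DP`), the Winter
#' critical-gel coefficient `K_PC` (product of the Winter coefficient and
#' the PC active-crosslink ratio), the fractional Maxwell scale `K_sJZ`, the
#' active crosslink ratio `r_act` applied to the transient PC and sJZ
#' channels, the fractional exponents `alpha_sJZ` and `alpha_JZ`, the
#' reference frequency `omega_ref` (rad/s) and temperature `T` (K).
#'
#' `sjz_frequency_convention` selects how the sJZ fractional Maxwell element
#' combines frequency with `K_sJZ`: `"product"` uses `x = (omega*K_sJZ)^alpha`
#' (`K_sJZ` acting as a characteristic time), `"ratio"` uses
#' `x = (omega/K_sJZ)^alpha` (`K_sJZ` as a characteristic frequency). See the
#' methods vignette for the consequences of each reading.
#'
#' `pc_storage` selects the storage contribution of point-like crosslinks:
#' `"winter"` (default) treats the PC channel as a Winter critical-gel
#' element with exponent 1/2, i.e. equal storage and loss contributions;
#' `"amplitude"` uses the full network amplitude; `"none"` drops it.
#'
#' @param S swelling fit parameter (dimensionless).
#' @param phi enzyme-enhanced sequential binding factor, >= 1.
#' @param Nc_PC,Nc_sJZ,Nc_JZ per-chain percolation numbers.
#' @param DP degree of polymerization of the pectin backbone.
#' @param K_PC Winter coefficient times PC active-crosslink ratio.
#' @param K_sJZ fractional Maxwell unit scale for short junction zones.
#' @param r_act active crosslink ratio for transient crosslinks, in (0, 1].
#' @param alpha_sJZ,alpha_JZ fractional exponents.
#' @param omega_ref reference angular frequency, rad/s.
#' @param T temperature, K.
#' @param sjz_frequency_convention `"product"` or `"ratio"` (see Details).
#' @param pc_storage `"winter"`, `"amplitude"` or `"none"`.
#' @return An object of class `"network_params"`.
#' @export
network_params <- function(S = 300, phi = 5.33,
                           Nc_PC = 1, Nc_sJZ = 19, Nc_JZ = 62, DP = 15000,
                           K_PC = 0.00085, K_sJZ = 0.0014, r_act = 0.128,
                           alpha_sJZ = 0.5, alpha_JZ = 0.018,
                           omega_ref = 10, T = 296.15,
                           sjz_frequency_convention = c("product", "ratio"),
                           pc_storage = c("winter", "amplitude", "none")) {
  sjz_frequency_convention <- match.arg(sjz_frequency_convention)
  pc_storage <- match.arg(pc_storage)
  vals <- c(S = S, phi = phi, Nc_PC = Nc_PC, Nc_sJZ = Nc_sJZ, Nc_JZ = Nc_JZ,
            DP = DP, K_PC = K_PC, K_sJZ = K_sJZ, omega_ref = omega_ref, T = T)
  if (any(vals <= 0)) abort("network parameters must be positive")
  if (r_act <= 0 || r_act > 1) abort("`r_act` must lie in (0, 1]")
  if (alpha_sJZ <= 0 || alpha_sJZ > 1) abort("`alpha_sJZ` must lie in (0, 1]")
  if (alpha_JZ <= 0 || alpha_JZ >= 1) abort("`alpha_JZ` must lie in (0, 1)")
  structure(list(S = S, phi = phi, Nc_PC = Nc_PC, Nc_sJZ = Nc_sJZ,
                 Nc_JZ = Nc_JZ, DP = DP, K_PC = K_PC, K_sJZ = K_sJZ,
                 r_act = r_act, alpha_sJZ = alpha_sJZ, alpha_JZ = alpha_JZ,
                 omega_ref = omega_ref, T = T,
                 sjz_frequency_convention = sjz_frequency_convention,
                 pc_storage = pc_storage),
            class = "network_params")
}

#' Solvent and polymer-liquid parameters
#'
#' @param eta_s solvent viscosity, kg/(m s).
#' @param intrinsic_visc intrinsic viscosity of the pectin, L/g.
#' @param Cp pectin weight concentration, g/L.
#' @return An object of class `"solvent_params"`.
#' @export
solvent_params <- function(eta_s = 1e-3, intrinsic_visc = 3.28, Cp = 0.80) {
  if (eta_s <= 0 || intrinsic_visc <= 0 || Cp < 0)
    abort("solvent parameters must be positive (Cp may be zero)")
  structure(list(eta_s = eta_s, intrinsic_visc = intrinsic_visc, Cp = Cp),
            class = "solvent_params")
}

#' Percolation threshold densities per crosslink species
#'
#' @param C0 total galacturonic acid concentration, mol/L.
#' @param network `"network_params"` object.
#' @return Named numeric vector `c(PC =, sJZ =, JZ =)` in mol/L.
#' @export
percolation_densities <- function(C0, network = network_params()) {
  c(PC = network$Nc_PC, sJZ = network$Nc_sJZ, JZ = network$Nc_JZ) *
    C0 / network$DP
}
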