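## Run-length statistics of consecutively calcium-bound sites.
##
## Along the backbone, bound-site runs have the geometric-type distribution
## p_m(R) = R^(m-1) (1 - R)^2, m >= 1. Runs of length in [l_PC, l_sJZ) act
## as point-like crosslinks, [l_sJZ, l_JZ) as short junction zones, and
## [l_JZ, Inf) as stable egg-box junction zones.

#' Run-length probability mass
#'
#' Probability weight of a consecutively bound run of exact length `m` at
#' binding ratio `R`: `R^(m-1) (1-R)^2`. Summed over `m >= 1` this gives
#' `1 - R`.
#'
#' @param R binding ratio(s) in `[0, 1)`.
#' @param m run length(s), integer `>= 1`.
#' @return Probability weight(s).
#' @export
run_length_pmf <- function(R, m) {
  if (any(R < 0) || any(R >= 1)) abort("`R` must lie in [0, 1)")
  if (any(m < 1)) abort("`m` must be >= 1")
  R^(m - 1) * (1 - R)^2
}

## R^(l-1) with the convention R^Inf = 0 (open upper interval bound).
.pow_lm1 <- function(R, l) if (is.finite(l)) R^(l - 1) else rep(0, length(R))

#' Probability of a run length in an interval
#'
#' Closed form of `sum_{m = l_i}^{l_j - 1} p_m(R)`:
#' `(1 - R)(R^(l_i - 1) - R^(l_j - 1))`, with `R^Inf = 0` so `l_j = Inf`
#' gives the open tail.
#'
#' @inheritParams run_length_pmf
#' @param l_i,l_j interval bounds, `1 <= l_i <= l_j`; `l_j` may be `Inf`.
#' @return Probability weight(s).
#' @export
interval_probability <- function(R, l_i, l_j) {
  if (any(R < 0) || any(R >= 1)) abort("`R` must lie in [0, 1)")
  if (l_i < 1 || l_i > l_j) abort("need 1 <= l_i <= l_j")
  (1 - R) * (.pow_lm1(R, l_i) - .pow_lm1(R, l_j))
}

#' Fraction of bound sites in runs of a given length interval
#'
#' Closed form of `sum_{m = l_i}^{l_j - 1} m p_m(R)`:
#' `(1 - R)(l_i R^(l_i - 1) - l_j R^(l_j - 1)) + R^l_i - R^l_j`. With
#' `l_i = 1, l_j = Inf` this sums to 1 for all `R` in `[0, 1)`.
#'
#' @inheritParams interval_probability
#' @return Bound-site fraction(s), non-negative.
#' @export
bound_site_fraction <- function(R, l_i, l_j) {
  if (any(R < 0) || any(R >= 1)) abort("`R` must lie in [0, 1)")
  if (l_i < 1 || l_i > l_j) abort("need 1 <= l_i <= l_j")
  t1 <- l_i * .pow_lm1(R, l_i)
  t2 <- if (is.finite(l_j)) l_j * R^(l_j - 1) else 0
  t3 <- if (is.finite(l_j)) R^l_j else 0
  (1 - R) * (t1 - t2) + R^l_i - t3
}

#' Crosslink species concentrations from the binding ratio
#'
#' Converts binding ratios into molar concentrations of the three crosslink
#' species. For species `i` occupying run lengths `[l_i, l_j)`,
#' `n_i = C0 R P(R; l_i, l_j) a_{i,j}(R phi) / a_{i,j}(R)` where `P` is
#' [interval_probability()], `a` is [bound_site_fraction()] and `phi >= 1`
#' is the enzyme-enhanced sequential binding factor that skews runs toward
#' consecutive binding. At `R = 0` the analytic limit `n_i = 0` is used
#' rather than the 0/0 ratio.
#'
#' The construction is undefined once `R * phi >= 1`; by default this is an
#' error. Set `clamp_phi_product = TRUE` to clamp the product at
#' `1 - 1e-9` (with a warning) for exploratory runs at large `Rmax`.
#'
#' @param R binding ratio(s) in `[0, 1)`.
#' @param C0 total galacturonic acid concentration, mol/L.
#' @param phi enzyme-enhanced sequential binding factor, `>= 1`.
#' @param lengths a [segment_lengths()] object.
#' @param clamp_phi_product clamp `R * phi` at `1 - 1e-9` instead of
#'   erroring when it reaches 1.
#' @return A tibble with columns `R`, `n_PC`, `n_sJZ`, `n_JZ` (mol/L).
#' @examples
#' species_concentrations(0.1, C0 = 5.22e-3)
#' @export
species_concentrations <- function(R, C0, phi = 5.33,
                                   lengths = segment_lengths(),
                                   clamp_phi_product = FALSE) {
  if (any(R < 0) || any(R >= 1)) abort("`R` must lie in [0, 1)")
  if (phi < 1) abort("`phi` must be >= 1")
  Rphi <- R * phi
  if (any(Rphi >= 1)) {
    if (!clamp_phi_product)
      abort(paste0(
        "enzyme-enhanced product R * phi reached 1 (saturation of the ",
        "sequential-binding construction); largest R * phi = ",
        signif(max(Rphi), 4),
        ". Set clamp_phi_product = TRUE to clamp for exploratory runs."))
    warn("R * phi >= 1 clamped to 1 - 1e-9")
    Rphi <- pmin(Rphi, 1 - 1e-9)
  }
  one_species <- function(l_i, l_j) {
    n <- numeric(length(R))
    pos <- R > 0
    n[pos] <- C0 * R[pos] * interval_probability(R[pos], l_i, l_j) *
      bound_site_fraction(Rphi[pos], l_i, l_j) /
      bound_site_fraction(R[pos], l_i, l_j)
    n
  }
  tibble(
    R = R,
    n_PC  = one_species(lengths$l_PC, lengths$l_sJZ),
    n_sJZ = one_species(lengths$l_sJZ, lengths$l_JZ),
    n_JZ  = one_species(lengths$l_JZ, Inf)
  )
}
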