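## Analytic and empirical machinery for the characteristic times t_gel and
## t_star and their stoichiometry dependence.

#' Approximation parameters for the characteristic-time closed forms
#'
#' `tau_c` is the dimensionless time representing the averaged degree of
#' methylation in the effective demethylation ratio
#' `rho = 1 - (1 - D) exp(-tau_c / t_bar)`; `eps` is the near-constant
#' consumption rate (1/s) of active unbound sites in the interval between
#' the gel point and the inflection point. Both are fitted constants.
#'
#' @param tau_c dimensionless averaged-methylation time.
#' @param eps consumption rate constant, 1/s.
#' @return An object of class `"approx_params"`.
#' @export
approx_params <- function(tau_c = 4.507, eps = 7.71e-6) {
  if (eps <= 0) abort("`eps` must be positive")
  structure(list(tau_c = tau_c, eps = eps), class = "approx_params")
}

#' Effective demethylation ratio
#'
#' `rho = 1 - (1 - D) exp(-tau_c / t_bar)`. Interpolates between `D`
#' (`tau_c -> 0`: no extra demethylation during gelation) and 1
#' (`tau_c -> Inf`: complete demethylation).
#'
#' @param params a [kinetic_params()] object.
#' @param tau_c dimensionless averaged-methylation time.
#' @return Effective demethylation ratio in `[D, 1]`.
#' @export
rho_effective <- function(params, tau_c) {
  1 - (1 - params$D) * exp(-tau_c / params$t_bar)
}

#' Analytic gel time
#'
#' Closed-form gel time branches:
#' * `"ELCC_rho"`: the enzyme-limited calcium-binding controlled closed
#'   form with the demethylation ratio replaced by the effective
#'   `rho = rho_effective(params, tau_c)`, evaluated at the supplied
#'   critical binding ratio `R_gel`;
#' * `"ELCC_adjusted"`: the same with `R_gel` taken from the empirical
#'   stoichiometry relation [empirical_critical_ratios()] at `params$Rmax`;
#' * `"EC"`: the enzyme-controlled form
#'   `tau_E log((1 - D)/(1 - R_gel))` (with `R_gel` from the empirical
#'   relation when not supplied).
#'
#' @param params a [kinetic_params()] object.
#' @param R_gel critical binding ratio at the gel point; required for
#'   `"ELCC_rho"`, defaulted from the empirical relation otherwise.
#' @param approx an [approx_params()] object.
#' @param branch closed-form branch.
#' @param rel an [empirical_relations()] object (adjusted/EC branches).
#' @return Gel time in seconds.
#' @export
tgel_analytic <- function(params, R_gel = NULL, approx = approx_params(),
                          branch = c("ELCC_rho", "ELCC_adjusted", "EC"),
                          rel = empirical_relations()) {
  branch <- match.arg(branch)
  if (branch != "ELCC_rho" && is.null(R_gel))
    R_gel <- empirical_critical_ratios(params$Rmax, rel)$R_gel
  if (is.null(R_gel)) abort("`R_gel` is required for the ELCC_rho branch")
  if (branch == "EC") {
    if (R_gel >= 1) abort("`R_gel` must be < 1 on the EC branch")
    return(params$tau_E * log((1 - params$D) / (1 - R_gel)))
  }
  rho <- rho_effective(params, approx$tau_c)
  if (R_gel >= min(params$Rmax, rho) || R_gel < 0)
    abort("`R_gel` outside the ELCC branch domain [0, min(Rmax, rho))")
  params$tau_Ca * .cf_tau(R_gel, params$Rmax, rho)
}

## Integral of the squared active-unbound-site fraction over
## (t_gel, t_gel + dt), entering the implicit relation for t_star:
## R_star - R_gel = eps * .tstar_gap(dt, ...).
.tstar_gap <- function(dt, R_gel, D, kE, t_gel) {
  e1 <- exp(-kE * t_gel)
  (1 - R_gel)^2 * dt +
    2 * (1 - R_gel) * (1 - D) * e1 / kE * (exp(-kE * dt) - 1) -
    (1 - D)^2 * e1^2 / (2 * kE) * (exp(-2 * kE * dt) - 1)
}

#' Analytic inflection time
#'
#' The inflection critical ratio `R_star` is linked to `t_star` through the
#' integrated consumption relation (the `eps`-approximation of the binding
#' kinetics between `t_gel` and `t_star`). Branches:
#' * `"implicit"` (default): solves the integral relation for `t_star`
#'   exactly by one-dimensional root finding. The relation's right-hand
#'   side is monotone in `t_star` (its derivative is the squared
#'   active-unbound fraction), so the root is unique.
#' * `"explicit"`: the printed linearized approximation with constants
#'   0.191 and 0.0311 (built from `exp(-0.3) ~ 0.74` and
#'   `exp(kE t_gel) ~ e`), retained verbatim.
#' * `"adjusted"`: the explicit form with `R_gel`, `R_star` from the
#'   empirical stoichiometry relations at `params$Rmax` and `eps` from
#'   [eps_extrapolate()]; `t_gel` defaults to the `"ELCC_adjusted"` gel
#'   time.
#' * `"EC"`: the enzyme-controlled counterpart
#'   `tau_E log((1 - D)/(1 - R_star))`.
#'
#' @param params a [kinetic_params()] object.
#' @param t_gel gel time in seconds (required except for `"EC"`, optional
#'   for `"adjusted"`).
#' @param R_gel,R_star critical binding ratios; defaulted from the
#'   empirical relations for `"adjusted"` and `"EC"`.
#' @param approx an [approx_params()] object.
#' @param branch see Details.
#' @param rel an [empirical_relations()] object.
#' @return Inflection time `t_star` in seconds.
#' @export
tstar_analytic <- function(params, t_gel = NULL, R_gel = NULL, R_star = NULL,
                           approx = approx_params(),
                           branch = c("implicit", "explicit", "adjusted", "EC"),
                           rel = empirical_relations()) {
  branch <- match.arg(branch)
  if (branch %in% c("adjusted", "EC")) {
    emp <- empirical_critical_ratios(params$Rmax, rel)
    R_gel <- R_gel %||% emp$R_gel
    R_star <- R_star %||% emp$R_star
  }
  if (branch == "EC") {
    if (R_star >= 1) abort("`R_star` must be < 1 on the EC branch")
    return(params$tau_E * log((1 - params$D) / (1 - R_star)))
  }
  if (is.null(R_gel) || is.null(R_star))
    abort("`R_gel` and `R_star` are required")
  eps <- approx$eps
  if (branch == "adjusted") {
    eps <- eps_extrapolate(params$Rmax, eps_ref = approx$eps, rel = rel)
    if (is.null(t_gel))
      t_gel <- tgel_analytic(params, approx = approx,
                             branch = "ELCC_adjusted", rel = rel)
  }
  if (is.null(t_gel)) abort("`t_gel` is required")
  if (R_star < R_gel) abort("`R_star` must be >= `R_gel`")
  if (branch == "implicit") {
    target <- (R_star - R_gel) / eps
    f <- function(dt) .tstar_gap(dt, R_gel, params$D, params$kE, t_gel) - target
    hi <- 10 * params$tau_E
    if (f(hi) < 0) abort("no inflection root in (t_gel, t_gel + 10 tau_E)")
    return(t_gel + uniroot(f, c(0, hi), tol = 1e-9 * hi)$root)
  }
  ## explicit / adjusted: printed linearization
  q <- (1 - params$D) / (1 - R_gel)
  t_gel + (R_star - R_gel) / (eps * (1 - R_gel)^2) +
    0.191 / params$kE * q - 0.0311 / params$kE * q^2
}

#' Extrapolate the consumption rate constant in stoichiometry
#'
#' Linear extrapolation of the near-constant consumption rate from its
#' reference value at `Rmax = Rmax_ref`:
#' `eps(Rmax) = eps_ref (Rmax - R_gel(Rmax)) / (Rmax_ref - R_gel_ref)`.
#'
#' @param Rmax stoichiometry ratio(s).
#' @param eps_ref reference consumption rate, 1/s.
#' @param Rmax_ref reference stoichiometry (the natural-extract value).
#' @param Rgel_ref critical ratio at the reference; defaults to the
#'   empirical relation at `Rmax_ref`.
#' @param rel an [empirical_relations()] object.
#' @return Extrapolated rate(s), 1/s.
#' @export
eps_extrapolate <- function(Rmax, eps_ref = 7.71e-6, Rmax_ref = .Rmax_ref,
                            Rgel_ref = NULL, rel = empirical_relations()) {
  Rgel_ref <- Rgel_ref %||% empirical_critical_ratios(Rmax_ref, rel)$R_gel
  num <- Rmax - empirical_critical_ratios(Rmax, rel)$R_gel
  if (any(num <= 0))
    abort("Rmax - R_gel(Rmax) must be positive for the extrapolation")
  eps_ref * num / (Rmax_ref - Rgel_ref)
}

#' Empirical molar-ratio regression coefficients
#'
#' Coefficients of the linear relations between the free-ion molar ratios
#' and the stoichiometry: `MR = slope_MR * Rmax + intercept_MR` at the gel
#' point and the starred analogue at the inflection point. Half-widths are
#' the printed 2.5-standard-error boxes.
#'
#' @param slope_MR,intercept_MR,slope_MRstar,intercept_MRstar central
#'   coefficients.
#' @param hw named numeric vector of 2.5-SE half-widths for the four
#'   coefficients.
#' @return An object of class `"empirical_relations"`.
#' @export
empirical_relations <- function(slope_MR = 1.72, intercept_MR = -0.19,
                                slope_MRstar = 1.43, intercept_MRstar = -0.25,
                                hw = c(slope_MR = 0.16, intercept_MR = 0.12,
                                       slope_MRstar = 0.13,
                                       intercept_MRstar = 0.10)) {
  structure(list(slope_MR = slope_MR, intercept_MR = intercept_MR,
                 slope_MRstar = slope_MRstar,
                 intercept_MRstar = intercept_MRstar, hw = hw),
            class = "empirical_relations")
}

#' Critical binding ratios from the empirical stoichiometry relations
#'
#' Inverts the molar-ratio regressions: from `MR = (Rmax - R_gel)/R_gel =
#' slope * Rmax + intercept` follows
#' `R_gel = Rmax / (1 + intercept + slope * Rmax)` (and the starred
#' analogue). With `band = "2.5SE"` the min/max over the printed
#' coefficient box is propagated by interval arithmetic (the ratio is
#' monotone decreasing in both coefficients).
#'
#' @param Rmax stoichiometry ratio(s), positive.
#' @param rel an [empirical_relations()] object.
#' @param band `"none"` for central values only, `"2.5SE"` to add bounds.
#' @return A tibble with columns `Rmax`, `R_gel`, `R_star` (and `_lo`/`_hi`
#'   bounds when requested).
#' @export
empirical_critical_ratios <- function(Rmax, rel = empirical_relations(),
                                      band = c("none", "2.5SE")) {
  band <- match.arg(band)
  if (any(Rmax <= 0)) abort("`Rmax` must be positive")
  ratio <- function(slope, icept) Rmax / (1 + icept + slope * Rmax)
  out <- tibble(
    Rmax = Rmax,
    R_gel = ratio(rel$slope_MR, rel$intercept_MR),
    R_star = ratio(rel$slope_MRstar, rel$intercept_MRstar)
  )
  if (band == "2.5SE") {
    h <- rel$hw
    out$R_gel_lo <- ratio(rel$slope_MR + h[["slope_MR"]],
                          rel$intercept_MR + h[["intercept_MR"]])
    out$R_gel_hi <- ratio(rel$slope_MR - h[["slope_MR"]],
                          rel$intercept_MR - h[["intercept_MR"]])
    out$R_star_lo <- ratio(rel$slope_MRstar + h[["slope_MRstar"]],
                           rel$intercept_MRstar + h[["intercept_MRstar"]])
    out$R_star_hi <- ratio(rel$slope_MRstar - h[["slope_MRstar"]],
                           rel$intercept_MRstar - h[["intercept_MRstar"]])
  }
  out
}

#' Critical binding ratios at detected characteristic times
#'
#' Evaluates the binding trajectory at the detected gel and inflection
#' times.
#'
#' @param trajectory a [solve_binding_ode()] result.
#' @param t_gel,t_star times in seconds within the trajectory range.
#' @return A tibble with columns `R_gel`, `R_star`.
#' @export
critical_ratios_from_times <- function(trajectory, t_gel, t_star) {
  tibble(R_gel = binding_ratio_at(trajectory, t_gel),
         R_star = binding_ratio_at(trajectory, t_star))
}

#' Gelation markers of a moduli profile
#'
#' Detects the gel point and inflection point on a forward-model or
#' measured profile and derives the stoichiometry quantities: the critical
#' binding ratios, the gel-point storage modulus, the free-ion molar ratios
#' `MR = (Rmax - R_gel)/R_gel` and `MR* = (Rmax - R_star)/R_star`, the
#' doped-site fraction `y = 1 - 0.158/R_gel` (relative to the natural
#' extract stoichiometry), and the thermally normalized modulus
#' `G'_gel / (A C0 kB T)`.
#'
#' @param profile a [forward_profile()] result or a profile read from a
#'   time sweep (single frequency).
#' @param trajectory the matching [solve_binding_ode()] result; when `NULL`
#'   the profile's own `R` column is interpolated.
#' @param window smoothing window passed to [detect_inflection()].
#' @param T temperature in kelvin for the normalized modulus.
#' @return A one-row tibble with columns `t_gel`, `t_star`, `R_gel`,
#'   `R_star`, `G_gel_prime`, `MR`, `MR_star`, `y`, `normalized_G`.
#' @export
gelation_markers <- function(profile, trajectory = NULL, window = 1,
                             T = 296.15) {
  params <- attr(profile, "params")
  t_gel <- detect_crossover(profile)
  t_star <- detect_inflection(profile, window = window, t_gel = t_gel)
  if (!is.null(trajectory)) {
    rr <- critical_ratios_from_times(trajectory, t_gel, t_star)
  } else if ("R" %in% names(profile)) {
    rr <- tibble(R_gel = approx(profile$time_s, profile$R, t_gel)$y,
                 R_star = approx(profile$time_s, profile$R, t_star)$y)
  } else {
    rr <- tibble(R_gel = NA_real_, R_star = NA_real_)
  }
  G_gel <- approx(profile$time_s, profile$Gp_Pa, t_gel)$y
  Rmax <- if (!is.null(params)) params$Rmax else NA_real_
  C0 <- if (!is.null(params)) params$C0 else NA_real_
  tibble(
    t_gel = t_gel, t_star = t_star,
    R_gel = rr$R_gel, R_star = rr$R_star,
    G_gel_prime = G_gel,
    MR = (Rmax - rr$R_gel) / rr$R_gel,
    MR_star = (Rmax - rr$R_star) / rr$R_star,
    y = 1 - .Rmax_ref / rr$R_gel,
    normalized_G = G_gel / (.A_conv * C0 * .kB * T)
  )
}

#' Predicted characteristic times across a stoichiometry grid
#'
#' Tabulates the analytic gel and inflection times and the empirical
#' critical ratios over a grid of `Rmax`, holding the kinetic scales fixed.
#' The `"ELCC"` branch uses the effective-demethylation closed form with
#' the empirical `R_gel(Rmax)` and the stoichiometry-extrapolated
#' consumption rate; the `"EC"` branch uses the enzyme-controlled forms.
#'
#' @param Rmax_grid stoichiometry ratios.
#' @param params a [kinetic_params()] object (its `Rmax` is overridden by
#'   the grid).
#' @param approx an [approx_params()] object.
#' @param branch `"ELCC"` or `"EC"`.
#' @param rel an [empirical_relations()] object.
#' @return A tibble with columns `Rmax`, `t_gel`, `t_star`, `R_gel`,
#'   `R_star`, `MR`, `MR_star`.
#' @export
predict_characteristic_times <- function(Rmax_grid, params,
                                         approx = approx_params(),
                                         branch = c("ELCC", "EC"),
                                         rel = empirical_relations()) {
  branch <- match.arg(branch)
  purrr::map_dfr(Rmax_grid, function(rmax) {
    p <- modifyList(params, list(Rmax = rmax, R_bar = rmax / params$D))
    class(p) <- "kinetic_params"
    emp <- empirical_critical_ratios(rmax, rel)
    if (branch == "ELCC") {
      tg <- tgel_analytic(p, approx = approx, branch = "ELCC_adjusted",
                          rel = rel)
      ts <- tstar_analytic(p, t_gel = tg, approx = approx,
                           branch = "adjusted", rel = rel)
    } else {
      tg <- tgel_analytic(p, approx = approx, branch = "EC", rel = rel)
      ts <- tstar_analytic(p, approx = approx, branch = "EC", rel = rel)
    }
    tibble(Rmax = rmax, t_gel = tg, t_star = ts,
           R_gel = emp$R_gel, R_star = emp$R_star,
           MR = (rmax - emp$R_gel) / emp$R_gel,
           MR_star = (rmax - emp$R_star) / emp$R_star)
  })
}
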