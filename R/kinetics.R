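## Reaction kinetics: the binding-ratio ODE and its closed-form limits.
##
## The binding ratio R = 2[Ca-PGA]/C0 obeys
##   dR/dt = (1/tau_Ca) (Rmax - R) [1 - cm0_frac e^{-kE t} - R]^2 - k_rev R
## The bracket is the fraction of active (demethylated) but unbound sites.

.binding_rhs <- function(t, R, p) {
  avail <- 1 - p$cm0_frac * exp(-p$kE * t) - R
  (p$Rmax - R) * avail^2 / p$tau_Ca - p$k_rev * R
}

#' Solve the calcium-binding reaction-kinetics ODE
#'
#' Integrates the binding-ratio equation with `R(0) = 0` on the supplied
#' time grid using an adaptive-step solver (relative tolerance `1e-8`,
#' absolute `1e-12`; closed-form comparisons at the `1e-3` level need solver
#' error well below that). The returned trajectory stores the exact
#' right-hand-side slope at every node so the solution can be evaluated at
#' arbitrary intermediate times by cubic Hermite interpolation
#' (see [binding_ratio_at()]).
#'
#' @param params a [kinetic_params()] object.
#' @param t_grid strictly increasing time grid in seconds starting at 0.
#' @return A tibble of class `"binding_trajectory"` with columns `time_s`,
#'   `R` and `dRdt`, and the parameters stored in attribute `"params"`.
#' @examples
#' p <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
#' tr <- solve_binding_ode(p, seq(0, 15000, by = 10))
#' @export
solve_binding_ode <- function(params, t_grid) {
  stopifnot(inherits(params, "kinetic_params"))
  if (t_grid[1] != 0) abort("`t_grid` must start at 0")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing")
  sol <- deSolve::lsoda(
    y = c(R = 0), times = t_grid,
    func = function(t, y, p) list(.binding_rhs(t, y, p)),
    parms = params, rtol = 1e-8, atol = 1e-12
  )
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    abort("ODE solver failed to meet tolerance")
  R <- pmin(pmax(as.numeric(sol[, "R"]), 0), params$Rmax)
  out <- tibble(time_s = t_grid, R = R,
                dRdt = .binding_rhs(t_grid, R, params))
  class(out) <- c("binding_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Evaluate a binding trajectory at arbitrary times
#'
#' Cubic Hermite interpolation using the stored node values and exact ODE
#' slopes; error is O(h^4) in the grid spacing.
#'
#' @param trajectory a [solve_binding_ode()] result.
#' @param t times in seconds, within the trajectory range.
#' @return Numeric vector of binding ratios.
#' @export
binding_ratio_at <- function(trajectory, t) {
  tt <- trajectory$time_s
  if (any(t < tt[1] - 1e-9) || any(t > tt[length(tt)] + 1e-9))
    abort("times outside trajectory range")
  t <- pmin(pmax(t, tt[1]), tt[length(tt)])
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  i <- pmin(i, length(tt) - 1)
  h <- tt[i + 1] - tt[i]
  s <- (t - tt[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * trajectory$R[i] + h10 * h * trajectory$dRdt[i] +
    h01 * trajectory$R[i + 1] + h11 * h * trajectory$dRdt[i + 1]
}

#' Classify the kinetic regime of the gelation system
#'
#' The competition between enzymatic demethylation and calcium binding is
#' summarized by `t_bar = tau_E/tau_Ca` and `R_bar = Rmax/D`. Slow-enzyme
#' systems (`t_bar` large) split by calcium stoichiometry: with excess
#' calcium (`R_bar > 1`) the system is enzyme-controlled (EC), with limiting
#' calcium it is enzyme-limited calcium-binding controlled (ELCC). Fast
#' enzymes (`t_bar` below the threshold) give a calcium-binding controlled
#' (CC) system.
#'
#' @param params a [kinetic_params()] object.
#' @param t_bar_threshold boundary between CC and the slow-enzyme regimes.
#'   The asymptotic analysis only states "much less/greater than 1"; the
#'   default threshold is 1.
#' @return An object of class `"regime_label"`: list with `label` (one of
#'   `"CC"`, `"ELCC"`, `"EC"`), `t_bar` and `R_bar`.
#' @export
classify_regime <- function(params, t_bar_threshold = 1) {
  label <- if (params$t_bar < t_bar_threshold) "CC"
           else if (params$R_bar > 1) "EC" else "ELCC"
  structure(list(label = label, t_bar = params$t_bar, R_bar = params$R_bar),
            class = "regime_label")
}

## Dimensionless time to reach binding ratio R when the availability bracket
## is frozen at (Deff - R): partial-fraction integral of
##   dtau/dR = 1 / ((Rmax - R) (Deff - R)^2).
## Deff = D (slow-enzyme limit), 1 (fast-enzyme limit) or the effective
## demethylation ratio rho.
.cf_tau <- function(R, Rmax, Deff) {
  if (abs(Deff - Rmax) < 1e-12)   # degenerate double root
    return((1 / (Deff - R)^2 - 1 / Deff^2) / 2)
  (log((1 - R / Deff) / (1 - R / Rmax)) -
     (Deff - Rmax) * R / (Deff * (Deff - R))) / (Deff - Rmax)^2
}

.regime_chr <- function(regime) {
  if (inherits(regime, "regime_label")) regime$label
  else match.arg(regime, c("CC", "ELCC", "EC"))
}

## Upper limit of the binding ratio on each closed-form branch.
.branch_sup <- function(params, label) {
  switch(label,
    EC   = min(params$Rmax, 1),
    ELCC = min(params$Rmax, params$D),
    CC   = min(params$Rmax, 1))
}

#' Closed-form limiting solutions: time to reach a binding ratio
#'
#' Closed forms of the binding kinetics in its three limits. EC (slow
#' enzyme, excess calcium): binding tracks demethylation,
#' `t = tau_E log((1 - D)/(1 - R))`, valid for `R >= D`. ELCC (slow enzyme,
#' limiting calcium) and CC (fast enzyme) integrate
#' `dtau/dR = 1/((Rmax - R)(Deff - R)^2)` with `Deff = D` or 1 respectively,
#' and return `tau * tau_Ca` in seconds.
#'
#' @param R binding ratio(s) inside the branch domain.
#' @param params a [kinetic_params()] object.
#' @param regime a [classify_regime()] result or one of `"CC"`, `"ELCC"`,
#'   `"EC"`.
#' @return Time(s) in seconds; monotone increasing in `R`, diverging as `R`
#'   approaches the limiting-reactant bound.
#' @export
closed_form_time <- function(R, params, regime) {
  label <- .regime_chr(regime)
  sup <- .branch_sup(params, label)
  lo <- if (label == "EC") params$D else 0
  if (any(R < lo - 1e-12) || any(R >= sup))
    abort(sprintf("R outside the %s branch domain [%g, %g)", label, lo, sup))
  switch(label,
    EC   = params$tau_E * log((1 - params$D) / (1 - R)),
    ELCC = params$tau_Ca * .cf_tau(R, params$Rmax, params$D),
    CC   = params$tau_Ca * .cf_tau(R, params$Rmax, 1))
}

#' Invert the closed-form limiting solutions
#'
#' Numerical inversion of [closed_form_time()] on its monotone branch. The
#' EC branch is inverted algebraically,
#' `R = 1 - (1 - D) exp(-t/tau_E)`; the ELCC and CC branches by safeguarded
#' root bracketing to relative tolerance `1e-10`.
#'
#' @param t time(s) in seconds, `>= 0`.
#' @inheritParams closed_form_time
#' @return Binding ratio(s).
#' @export
invert_closed_form <- function(t, params, regime) {
  if (any(t < 0)) abort("`t` must be non-negative")
  label <- .regime_chr(regime)
  if (label == "EC")
    return(1 - (1 - params$D) * exp(-t / params$tau_E))
  sup <- .branch_sup(params, label)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    f <- function(R) closed_form_time(R, params, label) - ti
    upper <- sup * (1 - 1e-13)
    while (f(upper) < 0 && sup - upper > .Machine$double.xmin)
      upper <- sup - (sup - upper) / 2
    uniroot(f, c(0, upper), tol = 1e-12 * max(1, sup))$root
  }, numeric(1))
}
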