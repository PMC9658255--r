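## Parameter estimation from time-sweep data: relative least squares on
## log-moduli over both channels, bounded multistart local optimization.

.fittable <- c("kE", "tau_Ca", "S", "phi", "K_PC", "K_sJZ", "r_act", "Rmax")

#' Default box bounds for fittable parameters
#'
#' Broad physically plausible ranges used by [fit_forward_model()] when no
#' bounds are supplied.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_fit_bounds <- function() {
  list(kE = c(1e-5, 1e-3), tau_Ca = c(50, 5000), S = c(50, 1000),
       phi = c(1.5, 20), K_PC = c(1e-4, 1e-2), K_sJZ = c(1e-4, 1e-1),
       r_act = c(0.01, 1), Rmax = c(0.01, 1))
}

## Assemble kinetic/network parameter objects with free-parameter overrides.
.assemble <- function(theta, sc, network) {
  kin_keys <- intersect(names(theta), c("kE", "tau_Ca", "Rmax"))
  net_keys <- intersect(names(theta), c("S", "phi", "K_PC", "K_sJZ", "r_act"))
  sc2 <- sc
  for (k in kin_keys) sc2[[k]] <- theta[[k]]
  net2 <- network
  for (k in net_keys) net2[[k]] <- theta[[k]]
  list(params = scenario_params(sc2), network = net2, sc = sc2)
}

## Sum of squared log-moduli residuals over both channels.
.fit_objective <- function(theta, data, sc, network, solvent, lengths,
                           floor) {
  pn <- tryCatch({
    a <- .assemble(theta, sc, network)
    grid <- sort(unique(data$time_s))
    full <- if (grid[1] == 0) grid else c(0, grid)
    tr <- solve_binding_ode(a$params, full)
    obj <- 0
    for (w in unique(data$omega_rad_s)) {
      rows <- data[data$omega_rad_s == w, ]
      pr <- forward_profile(tr, w, a$network, solvent, lengths,
                            clamp_phi_product = a$sc$clamp_phi_product)
      idx <- match(rows$time_s, full)
      obj <- obj +
        sum((log(pr$Gp_Pa[idx] + floor) - log(rows$Gp_Pa + floor))^2) +
        sum((log(pr$Gpp_Pa[idx] + floor) - log(rows$Gpp_Pa + floor))^2)
    }
    obj
  }, error = function(e) NA_real_)
  if (!is.finite(pn)) 1e10 else pn
}

#' Fit the forward model to time-sweep data
#'
#' Minimizes the summed squared difference of `log(G + floor)` between
#' model and data over both moduli channels and all frequencies present.
#' The log transform handles the ~4-decade span of the moduli across
#' gelation; the floor regularizes pre-gel near-zero storage readings.
#' Free parameters are optimized in log10 space by bounded local
#' optimization (`nlminb`) from `n_starts` Latin-hypercube starting points;
#' the run is deterministic given `rng_seed`.
#'
#' @param data tibble with `time_s`, `omega_rad_s`, `Gp_Pa`, `Gpp_Pa`.
#' @param sc a [scenario()] holding the fixed kinetic condition (free
#'   kinetic parameters override its fields); defaults to the scenario
#'   attached to synthetic data.
#' @param free character vector of free parameter names, a subset of
#'   `kE, tau_Ca, S, phi, K_PC, K_sJZ, r_act, Rmax`. May be empty, in
#'   which case the objective is evaluated without optimization.
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   defaults from [default_fit_bounds()].
#' @param network,solvent,lengths fixed model parameter objects.
#' @param n_starts number of multistart points.
#' @param rng_seed seed for the Latin-hypercube design.
#' @param floor modulus floor inside the log, Pa.
#' @return An object of class `"gel_fit"`: estimates, best objective,
#'   per-start table, convergence flags, and a recovered-vs-true table
#'   when the data carry their generating scenario.
#' @export
fit_forward_model <- function(data, sc = NULL, free = c("kE", "tau_Ca"),
                              bounds = NULL, network = network_params(),
                              solvent = solvent_params(),
                              lengths = segment_lengths(),
                              n_starts = 5, rng_seed = 1, floor = 1e-3) {
  .check_profile(data, c("time_s", "omega_rad_s", "Gp_Pa", "Gpp_Pa"))
  sc <- sc %||% attr(data, "scenario")
  if (is.null(sc)) abort("supply `sc`: the fixed kinetic condition")
  bad <- setdiff(free, .fittable)
  if (length(bad))
    abort(paste0("not fittable: ", paste(bad, collapse = ", ")))
  obj_fun <- function(theta) .fit_objective(theta, data, sc, network,
                                            solvent, lengths, floor)
  truth_all <- c(kE = sc$kE, tau_Ca = sc$tau_Ca, Rmax = sc$Rmax,
                 S = network$S, phi = network$phi, K_PC = network$K_PC,
                 K_sJZ = network$K_sJZ, r_act = network$r_act)
  if (!length(free)) {
    out <- structure(list(estimates = numeric(0),
                          objective = obj_fun(list()),
                          free = character(0), starts = tibble(),
                          converged = TRUE, truth = truth_all,
                          n_obs = nrow(data)), class = "gel_fit")
    return(out)
  }
  bb <- default_fit_bounds()
  if (!is.null(bounds)) bb[names(bounds)] <- bounds
  bb <- bb[free]
  if (any(!vapply(bb, function(b) all(is.finite(b)) && b[1] < b[2],
                  logical(1))))
    abort("bounds must be finite and ordered")
  lo <- log10(vapply(bb, `[`, numeric(1), 1))
  hi <- log10(vapply(bb, `[`, numeric(1), 2))
  k <- length(free)
  set.seed(rng_seed)
  design <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(design, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- free
  runs <- purrr::map_dfr(seq_len(n_starts), function(i) {
    fit <- nlminb(starts[i, ],
                  function(lth) obj_fun(as.list(setNames(10^lth, free))),
                  lower = lo, upper = hi,
                  control = list(rel.tol = 1e-10, x.tol = 1e-8))
    tibble(start = i, objective = fit$objective,
           converged = fit$convergence == 0,
           message = fit$message %||% NA_character_,
           par = list(setNames(10^fit$par, free)))
  })
  ## a start that never produced a finite model objective is a failure;
  ## nlminb's "false convergence" at a genuine optimum is not
  if (all(runs$objective >= 1e9)) abort("all starts failed to converge")
  best <- which.min(runs$objective)
  est <- runs$par[[best]]
  structure(list(estimates = est, objective = runs$objective[best],
                 free = free, bounds = bb,
                 starts = dplyr::select(runs, -"par"),
                 start_values = starts,
                 converged = runs$converged[best],
                 truth = truth_all, n_obs = nrow(data)),
            class = "gel_fit")
}

#' @export
print.gel_fit <- function(x, ...) {
  cat("<gel_fit> objective", format(x$objective, digits = 6), "\n")
  if (length(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Tidy a forward-model fit
#'
#' @param x a `"gel_fit"` object.
#' @param ... unused.
#' @return One row per free parameter: `term`, `estimate`, `lower`,
#'   `upper`, `truth` (generating value) and `rel_error`.
#' @export
tidy.gel_fit <- function(x, ...) {
  if (!length(x$estimates)) return(tibble())
  tr <- x$truth[x$free]
  tibble(term = x$free, estimate = unname(x$estimates[x$free]),
         lower = vapply(x$bounds, `[`, numeric(1), 1),
         upper = vapply(x$bounds, `[`, numeric(1), 2),
         truth = unname(tr),
         rel_error = unname(x$estimates[x$free] / tr - 1))
}

#' Fit summary
#'
#' @param x a `"gel_fit"` object.
#' @param ... unused.
#' @return One-row tibble: best objective, start count, convergence,
#'   observation count.
#' @export
glance.gel_fit <- function(x, ...) {
  tibble(objective = x$objective,
         n_starts = nrow(x$starts) %||% 0L,
         converged = x$converged, n_obs = x$n_obs)
}

#' Ordinary least squares with coefficient standard errors
#'
#' Simple linear regression `y = intercept + slope * x`, as used for the
#' empirical molar-ratio relations.
#'
#' @param x,y numeric vectors, length >= 3; `x` must vary.
#' @return An object of class `"gel_linfit"` with `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `sigma2` (residual variance) and `n`.
#' @export
linear_fit_with_se <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y))
    abort("need >= 3 paired points")
  if (max(x) - min(x) <= 0) abort("`x` is degenerate (no variation)")
  fit <- lm(y ~ x)
  ## exact-line input is a supported case (SEs collapse to 0); silence the
  ## perfect-fit warning from summary.lm
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 se_slope = sm$coefficients[2, 2],
                 se_intercept = sm$coefficients[1, 2],
                 sigma2 = sm$sigma^2, n = length(x)),
            class = "gel_linfit")
}

#' @export
print.gel_linfit <- function(x, ...) {
  cat(sprintf("<gel_linfit> slope %.4g (se %.3g), intercept %.4g (se %.3g)\n",
              x$slope, x$se_slope, x$intercept, x$se_intercept))
  invisible(x)
}

#' @rdname linear_fit_with_se
#' @param ... unused.
#' @export
tidy.gel_linfit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$se_intercept, x$se_slope))
}

#' @rdname linear_fit_with_se
#' @export
glance.gel_linfit <- function(x, ...) {
  tibble(sigma2 = x$sigma2, n = x$n)
}

#' Parameter-recovery experiment over a scenario grid
#'
#' Generates noisy synthetic sweeps for each scenario and seed, refits the
#' free parameters, and summarizes relative bias and RMSE per parameter.
#'
#' @param scenarios list of [scenario()] objects.
#' @param free free parameter names.
#' @param n_seeds number of independent noise replicates per scenario.
#' @param noise a [noise_model()] object.
#' @param ... passed to [fit_forward_model()].
#' @return A tibble with one row per parameter: `term`, `truth_mean`,
#'   `bias_rel`, `rmse_rel`, `n_fits`; the per-run table is attached as
#'   attribute `"runs"`.
#' @export
recovery_report <- function(scenarios, free = c("kE", "tau_Ca"),
                            n_seeds = 3, noise = noise_model(), ...) {
  runs <- purrr::map_dfr(scenarios, function(sc)
    purrr::map_dfr(seq_len(n_seeds), function(s) {
      dat <- generate_time_sweep(sc, noise, rng_seed = sc$rng_seed + s - 1)
      fit <- fit_forward_model(dat, sc = sc, free = free,
                               rng_seed = sc$rng_seed + s - 1, ...)
      dplyr::mutate(tidy(fit), scenario = sc$name, seed = s)
    }))
  out <- runs |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(truth_mean = mean(.data$truth),
                     bias_rel = mean(.data$rel_error),
                     rmse_rel = sqrt(mean(.data$rel_error^2)),
                     n_fits = dplyr::n(), .groups = "drop")
  attr(out, "runs") <- runs
  out
}
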