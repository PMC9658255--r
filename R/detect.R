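## Characteristic-time detection on moduli profiles (model output or
## rheometer time sweeps read with read_time_sweep()).

.check_profile <- function(profile, need = c("time_s", "Gp_Pa", "Gpp_Pa")) {
  miss <- setdiff(need, names(profile))
  if (length(miss))
    abort(paste0("profile lacks columns: ", paste(miss, collapse = ", ")))
  if (nrow(profile) < 2) abort("profile needs at least 2 points")
}

## Local-quadratic (Savitzky-Golay) smoothing; window must be odd and > 2.
## m = 0 smooths, m = 2 returns the smoothed second derivative.
.sgolay <- function(y, window, h = 1, m = 0) {
  if (window <= 1) {
    if (m == 0) return(y)
    d2 <- c(NA, diff(y, differences = 2), NA) / h^2
    d2[1] <- d2[2]; d2[length(d2)] <- d2[length(d2) - 1]
    return(d2)
  }
  if (window %% 2 == 0) abort("smoothing window must be odd")
  window <- min(window, if (length(y) %% 2 == 1) length(y) else length(y) - 1)
  signal::sgolayfilt(y, p = 2, n = window, m = m, ts = h)
}

#' Detect the gel point as the G'=G'' crossover
#'
#' The gel point is the first time at which the storage modulus overtakes
#' the loss modulus: the first sign change of `Gp - Gpp` from negative (or
#' zero) to positive, located by linear interpolation between the
#' bracketing samples.
#'
#' @param profile data frame with columns `time_s`, `Gp_Pa`, `Gpp_Pa` (one
#'   frequency).
#' @return Gel time in seconds.
#' @export
detect_crossover <- function(profile) {
  .check_profile(profile)
  d <- profile$Gp_Pa - profile$Gpp_Pa
  n <- length(d)
  i <- which(d[-n] <= 0 & d[-1] > 0)
  if (!length(i)) abort("no gel point in window: G' never crosses G''")
  i <- i[1]
  t0 <- profile$time_s[i]; t1 <- profile$time_s[i + 1]
  t0 + (0 - d[i]) / (d[i + 1] - d[i]) * (t1 - t0)
}

#' Detect the inflection point of the storage modulus
#'
#' Finds the structural-rearrangement time `t*`: the curvature sign change
#' of (optionally smoothed) `G'` associated with the dominant post-gel
#' kink or inflection. The noiseless forward model carries small-amplitude
#' curvature ripples from the point-like crosslink channel well before the
#' junction-zone surge, and measured data carry noise-induced wiggles, so
#' the first sign change after the gel point is not a usable estimator.
#' Instead the detector (1) locates the first post-gel sample whose
#' second-derivative magnitude reaches `min_prominence` times the post-gel
#' maximum — the onset of the dominant curvature event — and (2) reports
#' the zero crossing of the second derivative immediately preceding that
#' onset (or, when the curvature is already significant at the gel point
#' as for a smooth sigmoid, the first crossing after it). The crossing is
#' located by linear interpolation of the second derivative.
#'
#' For noisy data set `window` to an odd number of samples (e.g. 21): `G'`
#' is then smoothed and differentiated by a local quadratic
#' (Savitzky-Golay) filter over that window.
#'
#' @param profile data frame with `time_s` and `Gp_Pa` on a near-uniform
#'   dense grid.
#' @param window odd smoothing window in samples; 1 (default) disables
#'   smoothing and uses central second differences.
#' @param t_gel gel time; computed with [detect_crossover()] if `NULL`.
#' @param min_prominence fraction of the maximum post-gel
#'   second-derivative magnitude that defines the dominant curvature
#'   event.
#' @return Inflection time `t*` in seconds.
#' @export
detect_inflection <- function(profile, window = 1, t_gel = NULL,
                              min_prominence = 0.05) {
  .check_profile(profile, c("time_s", "Gp_Pa"))
  if (is.null(t_gel)) t_gel <- detect_crossover(profile)
  tt <- profile$time_s
  h <- diff(tt)
  if (max(h) > 1.5 * min(h))
    abort("`detect_inflection` needs a near-uniform time grid")
  d2 <- .sgolay(profile$Gp_Pa, window, h = mean(h), m = 2)
  post <- which(tt > t_gel)
  if (length(post) < 3) abort("no samples after the gel point")
  thr <- min_prominence * max(abs(d2[post]), na.rm = TRUE)
  k0 <- post[which(abs(d2[post]) >= thr)[1]]
  if (is.na(k0)) abort("no inflection point found after the gel point")
  cross_at <- function(k)   # zero of d2 between samples k and k+1
    tt[k] + (0 - d2[k]) / (d2[k + 1] - d2[k]) * (tt[k + 1] - tt[k])
  k <- k0
  while (k > post[1] && d2[k - 1] * d2[k] > 0) k <- k - 1
  if (k > post[1]) return(cross_at(k - 1))
  ## curvature already significant at the gel point: first crossing after
  for (k in k0:(length(d2) - 1))
    if (d2[k] * d2[k + 1] < 0 || (d2[k] != 0 && d2[k + 1] == 0))
      return(cross_at(k))
  abort("no inflection point found after the gel point")
}

#' Locate the post-gel local maximum/minimum pair of the loss modulus
#'
#' At higher frequencies the microstructural shuffling from point-like
#' crosslinks to junction zones can appear as a local maximum of `G''`
#' followed by a local minimum. Returns both times if the pair exists after
#' the gel point, otherwise `NULL` (absence is a valid result).
#'
#' A maximum only counts when the subsequent minimum sits at least
#' `min_prominence` (relative) below it, so smoothed measurement wiggles
#' on an essentially monotone curve are not reported as a shuffling
#' signature.
#'
#' @param profile data frame with `time_s` and `Gpp_Pa`.
#' @param window odd smoothing window (samples); 1 disables smoothing.
#' @param t_gel gel time; computed with [detect_crossover()] if `NULL`.
#' @param min_prominence minimum relative drop from the local maximum to
#'   the following minimum.
#' @return `list(t_max =, t_min =)` in seconds, or `NULL`.
#' @export
detect_gpp_extrema <- function(profile, window = 1, t_gel = NULL,
                               min_prominence = 0.02) {
  .check_profile(profile, c("time_s", "Gpp_Pa"))
  if (is.null(t_gel)) t_gel <- detect_crossover(profile)
  tt <- profile$time_s
  y <- .sgolay(profile$Gpp_Pa, window, h = mean(diff(tt)))
  s <- sign(diff(y))
  idx <- which(tt[-1] > t_gel)
  idx <- idx[idx < length(s)]
  maxima <- idx[which(s[idx] >= 0 & s[idx + 1] < 0)]
  for (imax in maxima) {
    rest <- idx[idx > imax]
    imin <- rest[which(s[rest] <= 0 & s[rest + 1] > 0)]
    if (!length(imin)) return(NULL)
    imin <- imin[1]
    drop <- (y[imax + 1] - y[imin + 1]) / max(y[imax + 1], .Machine$double.eps)
    if (drop >= min_prominence)
      return(list(t_max = tt[imax + 1], t_min = tt[imin + 1]))
  }
  NULL
}
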