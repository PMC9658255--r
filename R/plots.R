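#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a moduli profile
#'
#' Storage and loss moduli versus time on a log scale, with the detected
#' gel point marked when present.
#'
#' @param object a [forward_profile()] result.
#' @param mark_gel draw a vertical line at the G'=G'' crossover.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.moduli_profile <- function(object, mark_gel = TRUE, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time_s", "Gp_Pa", "Gpp_Pa"),
    c("Gp_Pa", "Gpp_Pa"), names_to = "channel", values_to = "G")
  df$channel <- factor(df$channel, c("Gp_Pa", "Gpp_Pa"), c("G'", "G''"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, pmax(.data$G, 1e-6),
                                        colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "modulus (Pa)", colour = NULL,
                  title = sprintf("omega = %g rad/s",
                                  object$omega_rad_s[1]))
  if (mark_gel) {
    tg <- tryCatch(detect_crossover(object), error = function(e) NULL)
    if (!is.null(tg))
      p <- p + ggplot2::geom_vline(xintercept = tg, linetype = 2,
                                   colour = "grey40")
  }
  p
}

#' Plot a binding trajectory
#'
#' @param object a [solve_binding_ode()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.binding_trajectory <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_s, .data$R)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$Rmax, linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "binding ratio R")
}

#' Plot the per-channel decomposition of a moduli profile
#'
#' Shows the polymer-liquid, point-like crosslink, short-junction-zone and
#' junction-zone contributions to either modulus channel.
#'
#' @param profile a [forward_profile()] result.
#' @param channel `"loss"` (default) or `"storage"`.
#' @return A ggplot object.
#' @export
plot_components <- function(profile, channel = c("loss", "storage")) {
  channel <- match.arg(channel)
  cols <- if (channel == "loss")
    c("Gpp_PL", "Gpp_PC", "Gpp_sJZ", "Gpp_JZ") else
    c("Gp_PC", "Gp_sJZ", "Gp_JZ")
  df <- tidyr::pivot_longer(
    dplyr::select(as_tibble(profile), "time_s", dplyr::all_of(cols)),
    -"time_s", names_to = "component", values_to = "G")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, pmax(.data$G, 1e-6),
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "modulus (Pa)")
}
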