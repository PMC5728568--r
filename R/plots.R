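#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, all returning
#' ggplot objects that can be themed further.
#'
#' @param object A result object.
#' @param ... Unused.
#' @name neff-plots
NULL

#' @rdname neff-plots
#' @export
autoplot.psth <- function(object, ...) {
  ycol <- if (isTRUE(attr(object, "zscored"))) "z" else "rate_hz"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_start_s, y = .data[[ycol]],
                               colour = .data$condition)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time from tone onset (s)",
                  y = if (ycol == "z") "z-scored rate" else "rate (Hz)")
}

#' @rdname neff-plots
#' @export
autoplot.mi_curve <- function(object, ...) {
  best <- max(object$summary$I_mean)
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$window * 1000, y = .data$I_mean)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$fraction * best,
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$window * 1000,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "window length (ms)",
                  y = "<I> (bits, bias-corrected)")
}

#' @rdname neff-plots
#' @export
autoplot.efficiency_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$delta_p1ij, y = .data$delta_H)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$E, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = expression(Delta * p["1ij"]),
                  y = expression(Delta * H ~ "(bits)"),
                  subtitle = sprintf("E = %.2f [%.2f, %.2f]", object$E,
                                     object$ci95[1], object$ci95[2]))
}

#' @rdname neff-plots
#' @export
autoplot.efficiency_timecourse <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$E,
                               colour = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time from tone onset (s)",
                  y = "efficiency E (bits / unit p1)")
}

#' @rdname neff-plots
#' @export
autoplot.surrogate_ensemble <- function(object, ...) {
  ggplot2::ggplot(tibble(E_star = object$E_star),
                  ggplot2::aes(x = .data$E_star)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed$E, colour = "red") +
    ggplot2::labs(x = "surrogate efficiency E*", y = "count",
                  subtitle = sprintf("observed E = %.3f, p = %.3f",
                                     object$observed$E,
                                     object$p_values$E))
}

#' @rdname neff-plots
#' @param levels Contour levels overlaid on each surface (default: 5
#'   pretty levels per surface).
#' @export
autoplot.lif_sweep <- function(object, levels = NULL, ...) {
  long <- object |>
    select("W_r", "lambda_ex", entropy = "H_corrected", p1ij = "p1ij") |>
    pivot_longer(c("entropy", "p1ij"), names_to = "surface",
                 values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$W_r, y = .data$lambda_ex,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$value),
                          colour = "white", bins = 6) +
    ggplot2::facet_wrap(~surface, scales = "free") +
    ggplot2::labs(x = expression(W[r] ~ "(mV)"),
                  y = expression(lambda[Ex] ~ "(Hz)"))
}
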