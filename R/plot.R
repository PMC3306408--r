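# Dose-response figures. Doses are drawn on a log10 axis; the untreated
# control (dose 0) is placed at a pseudo-dose two decades below the
# smallest treated dose, the usual display convention for designs with a
# zero control.

hf_pseudo_dose <- function(dose) {
  min_pos <- min(dose[dose > 0])
  ifelse(dose == 0, min_pos / 100, dose)
}

#' Plot a fitted hormetic dose-response curve
#'
#' Observed responses (per-dose means with SD bars) and the fitted mean
#' curve on a log-dose axis. The control is displayed at a pseudo-dose two
#' decades below the smallest treated dose.
#'
#' @param object A `hormesis_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hormesis_fit
#' @export
autoplot.hormesis_fit <- function(object, n_grid = 200, ...) {
  summ <- dose_summaries(object$data)
  summ$x <- hf_pseudo_dose(summ$dose)
  lo <- min(summ$x)
  hi <- max(summ$dose)
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  eval_dose <- ifelse(grid <= min(summ$x) * 1.0001, 0, grid)
  curve <- tibble(x = grid,
                  y = object$model$mean_fn(
                    c(object$estimates, object$fixed), eval_dose))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (log scale; control at left edge)",
                  y = "response",
                  title = sprintf("%s fit", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot a two-model comparison
#'
#' Both fitted curves over the shared data, labelled with the case
#' classification.
#'
#' @param object A `hormesis_comparison`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hormesis_comparison
#' @export
autoplot.hormesis_comparison <- function(object, n_grid = 200, ...) {
  fits <- Filter(function(f) inherits(f, "hormesis_fit"), object$fits)
  summ <- dose_summaries(fits[[1]]$data)
  summ$x <- hf_pseudo_dose(summ$dose)
  lo <- min(summ$x); hi <- max(summ$dose)
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  eval_dose <- ifelse(grid <= min(summ$x) * 1.0001, 0, grid)
  curves <- purrr::imap_dfr(fits, function(f, nm) {
    tibble(model = nm, x = grid,
           y = f$model$mean_fn(c(f$estimates, f$fixed), eval_dose))
  })
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.05, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$model)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (log scale; control at left edge)",
                  y = "response", colour = NULL,
                  title = sprintf("model comparison: %s", object$case)) +
    ggplot2::theme_minimal()
}
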