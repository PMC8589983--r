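#' Plot behavioural-signature summaries
#'
#' Optional ggplot2 helpers mirroring the standard presentation of the
#' confidence signatures: accuracy by confidence bin, the folded-X
#' pattern, psychometric curves split by confidence, and the relative
#' confidence curves of a parameter sweep. Presentation details are not
#' part of the package contract.
#'
#' @param summary output of [accuracy_by_confidence()], [folded_x()],
#'   [psychometric_by_confidence()] or [run_sweep()] respectively
#' @return A ggplot object.
#' @name plots
NULL

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' @rdname plots
#' @export
plot_accuracy_by_confidence <- function(summary) {
  need_ggplot()
  summary$mid <- (summary$lo + summary$hi) / 2
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$mid,
                                        y = .data$accuracy)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy - .data$se,
      ymax = .data$accuracy + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "confidence readout (Hz)", y = "correct ratio")
}

#' @rdname plots
#' @export
plot_folded_x <- function(summary) {
  need_ggplot()
  summary$outcome <- ifelse(summary$correct, "correct", "error")
  ggplot2::ggplot(summary[!is.na(summary$mean), ],
                  ggplot2::aes(x = .data$coherence_pct, y = .data$mean,
                               colour = .data$outcome)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "coherence (%)", y = "confidence readout (Hz)")
}

#' @rdname plots
#' @export
plot_psychometric_by_confidence <- function(summary) {
  need_ggplot()
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$coherence_pct,
                               y = .data$accuracy,
                               colour = .data$confidence)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy - .data$se,
      ymax = .data$accuracy + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "coherence (%)", y = "correct ratio")
}

#' @rdname plots
#' @export
plot_sweep <- function(summary) {
  need_ggplot()
  stopifnot(inherits(summary, "sweep_result"))
  ggplot2::ggplot(summary$slopes,
                  ggplot2::aes(x = factor(.data$a_1),
                               y = factor(.data$a_0),
                               fill = .data$slope)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "spike-driven adaptation strength (A1)",
                  y = "subthreshold adaptation strength (A0)",
                  fill = "coding slope\n(Hz per % coherence)")
}
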