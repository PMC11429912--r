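# ggplot2 autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a GQ cutoff sweep
#'
#' Estimated QV improvement as a function of the swept cutoff(s). For
#' multi-cutoff scenarios the curve is shown per 1 bp-insertion cutoff with
#' the remaining cutoffs fixed at their optimum.
#'
#' @param object A `gq_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gq_sweep
#' @export
autoplot.gq_sweep <- function(object, ...) {
  cur <- object$curve
  opt <- object$optimum
  if (object$scenario != "single") {
    cur <- cur[cur$gq_del1 == opt$gq_del1 & cur$gq_other == opt$gq_other, ]
  }
  ggplot2::ggplot(cur, ggplot2::aes(x = .data$gq_ins1, y = .data$delta_qv)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = opt$gq_ins1, linetype = 2) +
    ggplot2::labs(
      x = "GQ cutoff (1 bp insertions)", y = "estimated QV improvement",
      title = paste("GQ sweep:", object$scenario),
      subtitle = sprintf(
        "optimum INS1 %g / DEL1 %g / OTHER %g",
        opt$gq_ins1, opt$gq_del1, opt$gq_other
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot proposed edits by class and GQ
#'
#' @param object A `polish_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot polish_result
#' @export
autoplot.polish_result <- function(object, ...) {
  ggplot2::ggplot(object$edits, ggplot2::aes(x = .data$gq, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 5, boundary = 0, colour = "grey30") +
    ggplot2::facet_wrap(~class, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "genotype quality", y = "edits",
      title = "Proposed polishing edits by class"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot before/after QV for a pipeline run
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  df <- tibble::tibble(
    stage = factor(c("draft", "polished"), levels = c("draft", "polished")),
    qv = c(object$qv$draft$qv, object$qv$polished$qv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$qv)) +
    ggplot2::geom_col(fill = c("grey60", "steelblue"), width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$qv)),
      vjust = -0.4
    ) +
    ggplot2::labs(
      x = NULL, y = "k-mer QV",
      title = "Assembly quality before and after polishing",
      subtitle = sprintf("delta QV %.2f", object$qv$delta)
    ) +
    ggplot2::theme_minimal()
}
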