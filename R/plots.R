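#' Plot methods for workflow results
#'
#' `autoplot()` methods render the standard diagnostic views:
#' a refinement trace shows best-new versus input pLDDT per iteration; a QA
#' score table shows the consensus (APOLLO) score against global pLDDT; a
#' native evaluation shows per-model GDT-TS against TM-score with the
#' correct-fold threshold marked. `plot_similarity()` draws the pool
#' similarity matrix as a heatmap.
#'
#' @param object A `refinement_trace`, `qa_scores` or `native_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name foldrank-plots
NULL

#' @rdname foldrank-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.refinement_trace <- function(object, ...) {
  df <- tidy(object)
  df_long <- tidyr::pivot_longer(df, c("input_plddt", "best_new_plddt"),
                                 names_to = "series", values_to = "plddt")
  ggplot2::ggplot(df_long, ggplot2::aes(x = .data$iteration, y = .data$plddt,
                                        colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = df$iteration) +
    ggplot2::labs(x = "refinement iteration", y = "global pLDDT",
                  colour = NULL, title = "Refinement trace") +
    ggplot2::theme_minimal()
}

#' @rdname foldrank-plots
#' @export
autoplot.qa_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$plddt_global, y = .data$apollo)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "global pLDDT", y = "APOLLO consensus score",
                  title = "Pool quality scores") +
    ggplot2::theme_minimal()
}

#' @rdname foldrank-plots
#' @export
autoplot.native_evaluation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tm_score, y = .data$gdt_ts)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "TM-score vs native", y = "GDT-TS vs native",
                  title = "Pool evaluation against the native") +
    ggplot2::theme_minimal()
}

#' @rdname foldrank-plots
#' @param sim A similarity matrix from [similarity_matrix()].
#' @export
plot_similarity <- function(sim, ...) {
  df <- tibble::as_tibble(as.data.frame.table(sim, responseName = "similarity"))
  names(df)[1:2] <- c("model_i", "model_j")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_i, y = .data$model_j,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise model similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
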