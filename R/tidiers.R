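#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for workflow results
#'
#' `tidy()` returns the per-unit tibble of a result (per-iteration trace,
#' per-model evaluation or QA rows); `glance()` returns a one-row summary.
#'
#' @param x A `refinement_result`, `refinement_trace`,
#'   `native_evaluation`, `qa_scores` or `sampling_plan` object.
#' @param ... Unused.
#' @return A tibble.
#' @name foldrank-tidiers
NULL

#' @rdname foldrank-tidiers
#' @export
tidy.refinement_result <- function(x, ...) tidy(x$trace)

#' @rdname foldrank-tidiers
#' @export
tidy.refinement_trace <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "refinement_trace")
  attr(out, "final_model_id") <- NULL
  out
}

#' @rdname foldrank-tidiers
#' @export
glance.refinement_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x$trace),
    n_accepted = sum(x$trace$accepted),
    refined = x$refined,
    final_model_id = x$final_model_id,
    final_plddt = global_plddt(x$model)
  )
}

#' @rdname foldrank-tidiers
#' @export
glance.native_evaluation <- function(x, ...) {
  tibble::tibble(
    target_id = attr(x, "target_id"),
    n_models = nrow(x),
    best_tm_score = attr(x, "best_tm_score"),
    best_gdt_ts = attr(x, "best_gdt_ts"),
    correct_topology_fraction = attr(x, "correct_topology_fraction"),
    high_accuracy_fraction = attr(x, "high_accuracy_fraction"),
    top1_id = attr(x, "top1_id") %||% NA_character_,
    ranking_loss = attr(x, "ranking_loss") %||% NA_real_,
    pearson = attr(x, "pearson") %||% NA_real_
  )
}

#' @rdname foldrank-tidiers
#' @export
glance.sampling_plan <- function(x, ...) {
  tibble::tibble(n_combos = nrow(x), planned_models = planned_models(x))
}
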