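#' Iterative structure-alignment-based model refinement
#'
#' The refinement loop around a structure-search backend and a folding
#' backend: each iteration searches the current input model for similar
#' structures, converts the hit alignments into MSA rows and augments the
#' current alignment (cumulatively --- each iteration deepens the previous
#' iteration's filtered alignment, so the deeper-MSA effect compounds),
#' selects the top hits as templates, and folds `models_per_iter` new
#' models. If the best new model's global pLDDT strictly exceeds the
#' current input's, the iteration is accepted and the loop continues from
#' that model; otherwise it stops. The loop also stops after `max_iters`
#' iterations (default 5). The returned model is the highest-pLDDT model
#' generated across *all* iterations, not necessarily the last accepted
#' one. If the very first search returns no hits there is nothing to
#' refine: the trace records a single empty iteration and the input model
#' is returned unchanged.
#'
#' @param initial_model A [structure_model()] with pLDDT populated.
#' @param initial_msa The [msa()] used to generate the initial model; its
#'   query must equal the model's sequence.
#' @param search A search backend: `function(model) -> hit table` (see
#'   [mock_search_backend()] for the contract).
#' @param fold A folding backend: `function(msa, templates, n_models) ->
#'   list of structure_model` with pLDDT populated (see
#'   [mock_folding_backend()]).
#' @param max_iters Iteration cap, default 5.
#' @param models_per_iter Models folded per iteration, default 5.
#' @param template_k Templates selected per iteration, default 4.
#' @return A list of class `refinement_result`: `model` (the output
#'   [structure_model()]), `trace` (a tibble of class `refinement_trace`
#'   with one row per iteration: `iteration`, `n_hits`,
#'   `msa_depth_after_filter`, `best_new_plddt`, `input_plddt`,
#'   `accepted`), `refined` (whether any refined model was produced) and
#'   `final_model_id`.
#' @export
run_refinement <- function(initial_model, initial_msa, search, fold,
                           max_iters = 5, models_per_iter = 5, template_k = 4) {
  stopifnot(inherits(initial_model, "structure_model"), inherits(initial_msa, "msa"))
  query_seq <- paste(initial_model$aa, collapse = "")
  if (initial_msa$aln[1] != query_seq) {
    stop("MSA query does not match the model sequence", call. = FALSE)
  }
  current_model <- initial_model
  current_msa <- initial_msa
  best_model <- NULL
  best_plddt <- -Inf
  best_id <- NULL
  trace <- list()
  for (iter in seq_len(max_iters)) {
    input_plddt <- global_plddt(current_model)
    hits <- with_backend_context(iter, "search", search(current_model))
    if (nrow(hits) == 0) {
      trace[[iter]] <- tibble::tibble(
        iteration = iter, n_hits = 0L,
        msa_depth_after_filter = msa_depth(current_msa),
        best_new_plddt = NA_real_, input_plddt = input_plddt, accepted = FALSE)
      break
    }
    current_msa <- augment_msa(current_msa, hits)
    templates <- select_templates(hits, k = template_k)
    models <- with_backend_context(iter, "fold",
                                   fold(current_msa, templates, models_per_iter))
    check_fold_output(models, models_per_iter, nrow(initial_model))
    plddts <- vapply(models, global_plddt, numeric(1))
    ids <- vapply(models, model_id, character(1))
    ord <- order(-plddts, ids)
    top <- models[[ord[1]]]
    best_new <- plddts[ord[1]]
    if (best_new > best_plddt ||
        (best_new == best_plddt && !is.null(best_id) && ids[ord[1]] < best_id)) {
      best_model <- top
      best_plddt <- best_new
      best_id <- ids[ord[1]]
    }
    accepted <- best_new > input_plddt
    trace[[iter]] <- tibble::tibble(
      iteration = iter, n_hits = nrow(hits),
      msa_depth_after_filter = msa_depth(current_msa),
      best_new_plddt = best_new, input_plddt = input_plddt, accepted = accepted)
    if (!accepted) break
    current_model <- top
  }
  trace <- dplyr::bind_rows(trace)
  refined <- !is.null(best_model)
  out_model <- if (refined) set_model_meta(best_model, source_tag = "refined")
               else initial_model
  trace_tbl <- trace
  attr(trace_tbl, "final_model_id") <- model_id(out_model)
  class(trace_tbl) <- c("refinement_trace", class(trace_tbl))
  structure(list(model = out_model, trace = trace_tbl, refined = refined,
                 final_model_id = model_id(out_model)),
            class = "refinement_result")
}

with_backend_context <- function(iter, what, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s backend failed at refinement iteration %d: %s",
                 what, iter, conditionMessage(e)), call. = FALSE)
  })
}

check_fold_output <- function(models, n_models, query_length) {
  if (!is.list(models) || length(models) != n_models) {
    stop("folding backend must return exactly ", n_models, " models", call. = FALSE)
  }
  lens <- vapply(models, nrow, integer(1))
  if (any(lens != query_length)) {
    stop("folding backend returned model(s) of wrong length", call. = FALSE)
  }
  invisible(models)
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> %d iteration(s), %s, final model %s (pLDDT %.2f)\n",
              nrow(x$trace), if (x$refined) "refined" else "not refined",
              x$final_model_id, global_plddt(x$model)))
  invisible(x)
}

#' Refine the top five models and re-pool
#'
#' The selection rule of the refinement-based predictor: each of the five
#' input models is run through [run_refinement()] with its own MSA, the
#' five refined outputs are pooled with the five unrefined inputs, and the
#' five highest-pLDDT models of the ten are returned (ties broken by model
#' id). When refinement never improves a model the unrefined inputs win on
#' equal footing.
#'
#' @param top5 A list of exactly 5 `structure_model` objects.
#' @param msas A list of 5 matching [msa()] objects (same order).
#' @param search,fold Backends, as in [run_refinement()].
#' @param ... Passed on to [run_refinement()].
#' @return A list of class `refine_topk_result`: `models` (the 5 selected
#'   models, best first) and `traces` (per-input refinement traces).
#' @export
refine_topk <- function(top5, msas, search, fold, ...) {
  if (length(top5) != 5 || length(msas) != 5) {
    stop("refine_topk requires exactly 5 models and 5 MSAs", call. = FALSE)
  }
  results <- purrr::map2(top5, msas, function(m, a) {
    run_refinement(m, a, search = search, fold = fold, ...)
  })
  refined <- purrr::map(purrr::keep(results, ~ .x$refined), "model")
  refined <- purrr::imap(refined, function(m, i) {
    set_model_meta(m, model_id = paste0(model_id(m), "_refined"))
  })
  cand <- c(top5, refined)
  ids <- vapply(cand, model_id, character(1))
  pl <- vapply(cand, global_plddt, numeric(1))
  ord <- order(-pl, ids)
  structure(list(models = cand[utils::head(ord, 5)],
                 traces = purrr::map(results, "trace")),
            class = "refine_topk_result")
}
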