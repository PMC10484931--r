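#' Build a model pool for one target
#'
#' A `model_pool` is a tibble with one row per model: `model_id`,
#' `source_tag`, `n_res`, `plddt_global` and a `model` list-column holding
#' the [structure_model()] objects. All models must share one target and
#' carry unique ids.
#'
#' @param models A list of `structure_model` objects (or a single model).
#' @return A tibble of class `model_pool` with a `target_id` attribute.
#' @export
model_pool <- function(models) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  ids <- unname(vapply(models, model_id, character(1)))
  if (anyDuplicated(ids)) {
    stop("duplicate model ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  tgt <- unique(vapply(models, target_id, character(1)))
  if (length(tgt) != 1) {
    stop("all models in a pool must share one target_id", call. = FALSE)
  }
  out <- tibble::tibble(
    model_id = ids,
    source_tag = unname(vapply(models, source_tag, character(1))),
    n_res = unname(vapply(models, nrow, integer(1))),
    plddt_global = unname(vapply(models, global_plddt, numeric(1))),
    model = unname(models)
  )
  attr(out, "target_id") <- tgt
  class(out) <- c("model_pool", class(out))
  out
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool> target %s: %d models\n", attr(x, "target_id"), nrow(x)))
  NextMethod()
}

#' Extract the models of a pool as a named list
#'
#' @param pool A [model_pool()].
#' @return Named list of `structure_model` objects, names = model ids.
#' @export
pool_models <- function(pool) {
  stats::setNames(pool$model, pool$model_id)
}

#' Add models to a pool
#'
#' @param pool A [model_pool()].
#' @param models List of additional `structure_model` objects; ids must not
#'   collide with models already in the pool.
#' @return The enlarged pool (similarity/QA caches do not survive, since the
#'   pool contents changed).
#' @export
add_models <- function(pool, models) {
  if (inherits(models, "structure_model")) models <- list(models)
  if (length(models) == 0) return(pool)
  model_pool(c(pool_models(pool), models))
}
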