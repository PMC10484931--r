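#' Consensus and hybrid quality scores for a model pool
#'
#' Four per-model quality scores drive model selection:
#'
#' * `apollo_score()`: the APOLLO consensus score of model j, the average
#'   pairwise structural similarity to the other models,
#'   `sum_{i != j} sim_ij / (n - 1)`, in \[0, 1\].
#' * `apollo_plddt_weight()`: the pLDDT-weighted pairwise similarity,
#'   `sum_{i != j} sim_ij * plddt_i / (n - 1)` --- note the weight is the
#'   *other* model's pLDDT. Left on the 0--100-ish scale of its definition,
#'   since only its ranking is consumed.
#' * `apollo_plddt_avg()`: the mean of the APOLLO score and pLDDT/100 (pLDDT
#'   rescaled so both addends live in \[0, 1\]).
#' * the global pLDDT itself (see [global_plddt()]).
#'
#' @param sim Symmetric n x n similarity matrix with unit diagonal, n >= 2
#'   (from [similarity_matrix()]).
#' @param plddt Numeric vector of n global pLDDT values in \[0, 100\], in
#'   matrix row order.
#' @param apollo Numeric vector of APOLLO scores (for `apollo_plddt_avg`).
#' @return A numeric vector with one score per model (named when `sim`
#'   carries dimnames).
#' @export
apollo_score <- function(sim) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < 2 || ncol(sim) != n) stop("need a square similarity matrix with n >= 2", call. = FALSE)
  (colSums(sim) - diag(sim)) / (n - 1)
}

#' @rdname apollo_score
#' @export
apollo_plddt_weight <- function(sim, plddt) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < 2 || ncol(sim) != n) stop("need a square similarity matrix with n >= 2", call. = FALSE)
  if (length(plddt) != n) stop("plddt must have one value per model", call. = FALSE)
  off <- sim
  diag(off) <- 0
  stats::setNames(as.numeric(crossprod(off, plddt)) / (n - 1), colnames(sim))
}

#' @rdname apollo_score
#' @export
apollo_plddt_avg <- function(apollo, plddt) {
  if (length(apollo) != length(plddt)) {
    stop("apollo and plddt must have equal length", call. = FALSE)
  }
  (apollo + plddt / 100) / 2
}

#' Pool diversity: average pairwise similarity score (PSS)
#'
#' The mean of all off-diagonal entries of the pool similarity matrix
#' (equivalently the mean APOLLO score). High PSS (> 0.9) indicates the pool
#' collapsed onto one conformation; low PSS flags conformational diversity.
#'
#' @inheritParams apollo_score
#' @return A number in \[0, 1\].
#' @export
pss <- function(sim) {
  mean(apollo_score(sim))
}

#' Rank model ids by score
#'
#' Descending by score, ties broken lexicographically by model id so the
#' ordering is deterministic.
#'
#' @param scores Numeric vector of finite scores.
#' @param model_ids Character vector of ids, same length.
#' @return `model_ids` reordered from best to worst.
#' @export
rank_models <- function(scores, model_ids = names(scores)) {
  if (length(scores) != length(model_ids) || is.null(model_ids)) {
    stop("scores and model_ids must pair up", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  unname(model_ids[order(-scores, model_ids)])
}

#' Per-target ranking loss
#'
#' The true quality of the best model in the pool minus the true quality of
#' the model a selector ranked first (GDT-TS units when `true_scores` are
#' GDT-TS). Zero iff the selector picked a true-best model; never negative.
#'
#' @param true_scores Named numeric vector of true quality scores.
#' @param selected_top1 Id of the model the selector ranked first.
#' @return A number >= 0.
#' @export
ranking_loss <- function(true_scores, selected_top1) {
  if (is.null(names(true_scores))) stop("true_scores must be named by model id", call. = FALSE)
  if (!selected_top1 %in% names(true_scores)) {
    stop("unknown model id: ", selected_top1, call. = FALSE)
  }
  max(true_scores) - true_scores[[selected_top1]]
}

#' Per-target Pearson correlation of predicted vs true quality
#'
#' @param predicted,true Numeric vectors of length >= 3; neither may be
#'   constant (a constant vector has no defined correlation and raises an
#'   error rather than returning NaN).
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
per_target_correlation <- function(predicted, true) {
  if (length(predicted) != length(true) || length(predicted) < 3) {
    stop("need >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(true) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(predicted, true)
}

#' Weighted z-score combination of component scores
#'
#' The CASP-style combined score: each component column is standardised to
#' z-scores across models (population standard deviation; a constant column
#' yields z = 0 for every model rather than an error), and the combined
#' score of a model is `sum over groups of weight_g * sum of z over the
#' group's components`. The default grouping mirrors the official CASP15
#' formula: four components at weight 1/16, three at 1/12 and three at 1/6.
#' The component metrics themselves are supplied by the caller; this is a
#' generic combiner.
#'
#' @param score_table A data frame or matrix, models x components; an
#'   optional `model_id` column is carried through.
#' @param groups A list of groups, each `list(weight = w, components = chr)`.
#'   Defaults to the three-tier 1/16, 1/12, 1/6 grouping over the table's
#'   columns taken in order (4, 3 and 3 columns).
#' @return A tibble with `model_id` (if present) and `combined`.
#' @export
zscore_combine <- function(score_table, groups = NULL) {
  tbl <- tibble::as_tibble(score_table)
  ids <- if ("model_id" %in% names(tbl)) tbl$model_id else NULL
  num <- dplyr::select(tbl, -dplyr::any_of("model_id"))
  if (nrow(num) == 0 || ncol(num) == 0) stop("empty score table", call. = FALSE)
  if (nrow(num) < 2) stop("z-scores need at least 2 models", call. = FALSE)
  if (is.null(groups)) {
    cols <- names(num)
    if (length(cols) == 10) {
      groups <- list(list(weight = 1 / 16, components = cols[1:4]),
                     list(weight = 1 / 12, components = cols[5:7]),
                     list(weight = 1 / 6, components = cols[8:10]))
    } else {
      groups <- list(list(weight = 1, components = cols))
    }
  }
  zcol <- function(x) {
    s <- pop_sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z <- purrr::map_dfc(num, zcol)
  combined <- rep(0, nrow(z))
  for (g in groups) {
    miss <- setdiff(g$components, names(z))
    if (length(miss) > 0) stop("unknown component(s): ", paste(miss, collapse = ", "), call. = FALSE)
    combined <- combined + g$weight * rowSums(z[, g$components, drop = FALSE])
  }
  out <- tibble::tibble(combined = combined)
  if (!is.null(ids)) out <- tibble::tibble(model_id = ids, combined = combined)
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Compute the QA score table of a pool
#'
#' Convenience wrapper producing all four quality scores for every model of
#' a pool: global pLDDT, APOLLO consensus score, their average, and the
#' pLDDT-weighted pairwise similarity.
#'
#' @param pool A [model_pool()] with >= 2 models.
#' @param sim Optional precomputed similarity matrix (rows/cols in pool
#'   order); computed with the default TM-score metric when missing.
#' @return A tibble of class `qa_scores` with columns `model_id`,
#'   `plddt_global`, `apollo`, `apollo_plddt_avg`, `apollo_plddt_weight`.
#' @export
qa_scores <- function(pool, sim = NULL) {
  sim <- sim %||% similarity_matrix(pool)
  stopifnot(all(rownames(sim) == pool$model_id))
  ap <- apollo_score(sim)
  out <- tibble::tibble(
    model_id = pool$model_id,
    plddt_global = pool$plddt_global,
    apollo = unname(ap),
    apollo_plddt_avg = unname(apollo_plddt_avg(ap, pool$plddt_global)),
    apollo_plddt_weight = unname(apollo_plddt_weight(sim, pool$plddt_global))
  )
  class(out) <- c("qa_scores", class(out))
  out
}
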