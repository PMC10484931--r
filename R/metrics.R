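#' Structural similarity metrics
#'
#' TM-score and GDT-TS are computed over the residues corresponded by
#' residue number, by searching over rigid superpositions seeded from
#' contiguous fragments of lengths M, M/2, M/4 and 4 at every offset; each
#' seed superposition is refined by repeatedly re-superposing on the
#' residues currently within a distance cutoff until the included set is
#' stable (at most 20 rounds), and the best score seen over all seeds and
#' rounds is returned. Every superposition examined is a least-squares fit
#' on a residue subset, so the search result is bounded above by exhaustive
#' subset-superposition enumeration. For small correspondences (M <= 12)
#' the search *is* that enumeration --- exact maximisation is cheap there
#' --- so the metrics are exact on small inputs and heuristic above.
#'
#' `tm_score` is normalised by the reference length `lref` with
#' `d0 = max(1.24 * (lref - 15)^(1/3) - 1.8, 0.5)` (the floor covers short
#' chains). `gdt_ts` averages, over the cutoffs 1, 2, 4 and 8 Angstrom, the
#' maximal fraction of corresponded residues placeable within the cutoff.
#' `lddt_ca` is superposition-free: over residue pairs at sequence
#' separation >= 2 whose reference CA distance is below 15 Angstrom, the
#' fraction whose model-vs-reference distance difference stays below a
#' threshold, averaged over thresholds 0.5, 1, 2 and 4 Angstrom.
#'
#' @param model,reference `structure_model` objects of the same target;
#'   `reference` is the normalising side for TM-score.
#' @param lref Normalising length for TM-score; defaults to the reference's
#'   residue count. Pairwise model--model similarity uses the larger of the
#'   two residue counts (a stand-in for the target length) for both
#'   orientations.
#' @return A single number: TM-score in (0, 1], GDT-TS in \[0, 1\] or
#'   CA-lDDT in \[0, 1\]. Each equals 1 exactly on identical inputs.
#' @name metrics
NULL

# exact enumeration threshold: below this many corresponded residues the
# superposition search enumerates every residue subset of size >= 3 (at most
# 4017 subsets), which makes the metric the exact subset-superposition
# maximum on small inputs; larger inputs use the heuristic seed search
EXACT_SEARCH_MAX_M <- 12L

# contiguous seed fragments: lengths {M, M/2, M/4, 4} at all offsets
seed_index_sets <- function(m) {
  lens <- unique(pmin(m, pmax(3L, as.integer(floor(c(m, m / 2, m / 4, 4))))))
  out <- list()
  for (l in lens) {
    for (o in seq_len(m - l + 1L)) out[[length(out) + 1L]] <- o:(o + l - 1L)
  }
  out
}

# distances of superposed P to Q for an index-subset fit; NULL if degenerate
subset_fit_distances <- function(P, Q, idx) {
  sup <- tryCatch(kabsch_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(sup)) return(NULL)
  sqrt(rowSums((apply_superposition(sup, P) - Q)^2))
}

# lean variant for the heuristic search path: skips validation and object
# construction (a 3x3 SVD cannot fail; a degenerate subset merely yields a
# non-optimal fit, which the maximisation ignores)
fast_fit_distances <- function(P, Q, idx) {
  Ps <- P[idx, , drop = FALSE]
  Qs <- Q[idx, , drop = FALSE]
  pc <- colMeans(Ps); qc <- colMeans(Qs)
  H <- crossprod(sweep(Ps, 2, pc), sweep(Qs, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qc - as.numeric(R %*% pc)
  moved <- sweep(tcrossprod(P, R), 2, tr, `+`)
  sqrt(rowSums((moved - Q)^2))
}

# iterative include/re-superpose refinement from one seed, generic in the
# inclusion cutoff; calls `score_fn(d)` on each round's distance vector and
# returns the best value seen
refine_seed <- function(P, Q, seed, cutoff, score_fn, max_rounds = 20) {
  best <- -Inf
  idx <- seed
  for (round in seq_len(max_rounds)) {
    d <- fast_fit_distances(P, Q, idx)
    best <- max(best, score_fn(d))
    cut <- cutoff
    new_idx <- which(d < cut)
    while (length(new_idx) < 3) {
      cut <- cut + 0.5
      new_idx <- which(d < cut)
    }
    if (length(new_idx) == length(idx) && all(new_idx == idx)) break
    idx <- new_idx
  }
  best
}

# best value of each score function over the searched superpositions; exact
# subset enumeration for small M, seed search above EXACT_SEARCH_MAX_M
superposition_search <- function(P, Q, cutoffs, score_fns) {
  if (is.function(score_fns)) score_fns <- list(score_fns)
  m <- nrow(P)
  best <- rep(-Inf, length(score_fns))
  if (m <= EXACT_SEARCH_MAX_M) {
    for (k in 3:m) {
      sets <- utils::combn(m, k)
      for (ci in seq_len(ncol(sets))) {
        d <- subset_fit_distances(P, Q, sets[, ci])
        if (is.null(d)) next
        for (f in seq_along(score_fns)) best[f] <- max(best[f], score_fns[[f]](d))
      }
    }
    return(best)
  }
  for (f in seq_along(score_fns)) {
    for (seed in seed_index_sets(m)) {
      for (cut in cutoffs[[f]]) {
        best[f] <- max(best[f], refine_seed(P, Q, seed, cut, score_fns[[f]]))
      }
    }
  }
  best
}

tm_d0 <- function(lref) {
  if (lref > 15) max(1.24 * (lref - 15)^(1 / 3) - 1.8, 0.5) else 0.5
}

#' @rdname metrics
#' @export
tm_score <- function(model, reference, lref = NULL) {
  cr <- correspond(model, reference)
  lref <- lref %||% nrow(reference)
  d0 <- tm_d0(lref)
  score_fn <- function(d) sum(1 / (1 + (d / d0)^2)) / lref
  # refinement cutoffs derived from d0, bracketing the standard search band
  cutoffs <- list(unique(pmax(d0, c(4.5, 8))))
  superposition_search(cr$P, cr$Q, cutoffs, score_fn)[1]
}

#' @rdname metrics
#' @export
gdt_ts <- function(model, reference) {
  cr <- correspond(model, reference)
  m <- nrow(cr$P)
  cuts <- c(1, 2, 4, 8)
  score_fns <- lapply(cuts, function(d) {
    force(d)
    function(dist) sum(dist <= d) / m
  })
  cutoffs <- lapply(cuts, function(d) c(d, 2 * d))
  mean(superposition_search(cr$P, cr$Q, cutoffs, score_fns))
}

#' @rdname metrics
#' @export
lddt_ca <- function(model, reference) {
  cr <- correspond(model, reference, min_pairs = 2)
  resno <- cr$resno
  dm <- as.matrix(stats::dist(cr$P))
  dr <- as.matrix(stats::dist(cr$Q))
  sep <- abs(outer(resno, resno, `-`))
  qual <- sep >= 2 & dr < 15 & upper.tri(dr)
  if (!any(qual)) stop("no qualifying residue pairs for lDDT", call. = FALSE)
  diffs <- abs(dm[qual] - dr[qual])
  mean(vapply(c(0.5, 1, 2, 4), function(t) mean(diffs < t), numeric(1)))
}

#' Pairwise similarity matrix of a model pool
#'
#' Computes the n x n matrix of pairwise structural similarities among the
#' models of a pool. Each entry is symmetrised as the mean of the two
#' orientations of the chosen metric; the diagonal is 1. This matrix is the
#' input to the consensus (APOLLO-style) quality scores and the pool
#' diversity statistic [pss()].
#'
#' @param pool A [model_pool()] with at least two models.
#' @param metric `"tm_score"` (default) or `"gdt_ts"`.
#' @return A symmetric numeric matrix with model ids as dimnames.
#' @export
similarity_matrix <- function(pool, metric = c("tm_score", "gdt_ts")) {
  metric <- match.arg(metric)
  models <- pool_models(pool)
  n <- length(models)
  if (n < 2) stop("similarity matrix needs at least 2 models", call. = FALSE)
  ids <- names(models)
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (metric == "tm_score") {
        l <- max(nrow(models[[i]]), nrow(models[[j]]))
        a <- tm_score(models[[i]], models[[j]], lref = l)
        b <- tm_score(models[[j]], models[[i]], lref = l)
      } else {
        a <- gdt_ts(models[[i]], models[[j]])
        b <- gdt_ts(models[[j]], models[[i]])
      }
      sim[i, j] <- sim[j, i] <- (a + b) / 2
    }
  }
  sim
}

#' Write a similarity matrix as TSV
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param path Output path; model ids form the header row and first column.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(model_id = rownames(sim), sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
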