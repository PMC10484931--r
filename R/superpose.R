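#' Residue correspondence between two models of the same target
#'
#' Pairs residues sharing a residue number in both models, in increasing
#' residue-number order. Correspondence is strictly by residue number; models
#' of the same target are never re-aligned by sequence.
#'
#' @param model_a,model_b `structure_model` objects sharing a target.
#' @param min_pairs Minimum number of corresponded residues required
#'   (default 3, the minimum for a rigid superposition).
#' @return A list with matrices `P` (coordinates from `model_a`), `Q`
#'   (from `model_b`), both M x 3, and the shared `resno` vector.
#' @export
correspond <- function(model_a, model_b, min_pairs = 3) {
  if (!identical(target_id(model_a), target_id(model_b))) {
    stop("models belong to different targets: ", target_id(model_a), " vs ",
         target_id(model_b), call. = FALSE)
  }
  shared <- intersect(model_a$resno, model_b$resno)
  if (length(shared) < min_pairs) {
    stop(sprintf("insufficient residue correspondence: %d shared residues (need >= %d)",
                 length(shared), min_pairs), call. = FALSE)
  }
  shared <- sort(shared)
  ia <- match(shared, model_a$resno)
  ib <- match(shared, model_b$resno)
  list(P = ca_coords(model_a)[ia, , drop = FALSE],
       Q = ca_coords(model_b)[ib, , drop = FALSE],
       resno = shared)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the rotation (proper, determinant +1; reflections excluded) and
#' translation minimising the RMSD of `rotation %*% p + translation` onto the
#' paired points of `Q`, via singular value decomposition of the covariance
#' of the centred point sets.
#'
#' @param P,Q M x 3 coordinate matrices of paired points (M >= 3,
#'   not all collinear).
#' @return A list of class `superposition` with elements `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` and `n_pairs`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- matrix(as.numeric(P), ncol = 3)
  Q <- matrix(as.numeric(Q), ncol = 3)
  m <- nrow(P)
  if (nrow(Q) != m) stop("P and Q must pair the same number of points", call. = FALSE)
  if (m < 3) stop("superposition needs at least 3 point pairs", call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  # collinear (rank < 2) point sets have no unique rotation
  if (svd(Pc, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, abs(Pc)) ||
      svd(Qc, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, abs(Qc))) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- qc - as.numeric(R %*% pc)
  moved <- tcrossprod(P, R)
  moved <- sweep(moved, 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_pairs = m),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

# apply a superposition to an M x 3 coordinate matrix
apply_superposition <- function(sup, X) {
  sweep(tcrossprod(X, sup$rotation), 2, sup$translation, `+`)
}
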