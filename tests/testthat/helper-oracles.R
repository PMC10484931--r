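# Independent brute-force oracles used to check the superposition metrics.
# Deliberately written from the definitions, not via the package internals.

# least-squares rigid fit of P[idx,] onto Q[idx,] from first principles;
# NULL when the subset is (near-)collinear
oracle_fit <- function(P, Q, idx) {
  Ps <- P[idx, , drop = FALSE]
  Qs <- Q[idx, , drop = FALSE]
  pc <- colMeans(Ps)
  qc <- colMeans(Qs)
  Pc <- sweep(Ps, 2, pc)
  Qc <- sweep(Qs, 2, qc)
  if (svd(Pc)$d[2] < 1e-8 || svd(Qc)$d[2] < 1e-8) return(NULL)
  s <- svd(t(Pc) %*% Qc)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  list(R = R, t = qc - as.numeric(R %*% pc))
}

# distances of all points of P (transformed) to Q under a subset fit
oracle_distances <- function(P, Q, idx) {
  fit <- oracle_fit(P, Q, idx)
  if (is.null(fit)) return(NULL)
  moved <- sweep(P %*% t(fit$R), 2, fit$t, `+`)
  sqrt(rowSums((moved - Q)^2))
}

# exhaustive subset-superposition oracle: best value of each score function
# over least-squares fits on every residue subset of size >= 3
oracle_subset_search <- function(P, Q, score_fns) {
  m <- nrow(P)
  best <- rep(-Inf, length(score_fns))
  for (k in 3:m) {
    sets <- utils::combn(m, k)
    for (ci in seq_len(ncol(sets))) {
      d <- oracle_distances(P, Q, sets[, ci])
      if (is.null(d)) next
      for (f in seq_along(score_fns)) {
        best[f] <- max(best[f], score_fns[[f]](d))
      }
    }
  }
  best
}

oracle_tm <- function(P, Q, lref) {
  d0 <- max(1.24 * max(lref - 15, 0)^(1 / 3) - 1.8, 0.5)
  oracle_subset_search(P, Q, list(function(d) sum(1 / (1 + (d / d0)^2)) / lref))[1]
}

oracle_gdt <- function(P, Q) {
  m <- nrow(P)
  fns <- lapply(c(1, 2, 4, 8), function(ct) {
    force(ct)
    function(d) sum(d <= ct) / m
  })
  mean(oracle_subset_search(P, Q, fns))
}

# a random rigid transform (rotation from QR of a Gaussian matrix)
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    qr_dec <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_dec)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    list(R = R, t = rnorm(3, sd = 20))
  })
}

transform_model <- function(model, rigid) {
  xyz <- sweep(ca_coords(model) %*% t(rigid$R), 2, rigid$t, `+`)
  structure_model(model$resno, model$aa, xyz, model$plddt,
                  model_id = model_id(model), target_id = target_id(model),
                  source_tag = source_tag(model))
}

# small noisy instance on a helix, optionally with a rigidly displaced block
random_instance <- function(r, m = NULL) {
  withr::with_seed(1000 + r, {
    m <- if (is.null(m)) sample(5:10, 1) else m
    sigma <- sample(c(0.3, 0.8, 1.5, 3), 1)
    displace <- r %% 3 == 0
    k <- if (displace) sample(2:(m - 2), 1) else 0
  })
  native <- make_helix(m, target_id = "oracle_toy")
  model <- perturb_model(native, sigma, seed = 2000 + r)
  if (k > 0) model$x[(m - k + 1):m] <- model$x[(m - k + 1):m] + 30
  list(native = native, model = model, m = m)
}
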