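test_that("correspondence pairs residues by residue number", {
  a <- toy_model(resno = 1:10, id = "a")
  b <- toy_model(resno = 1:10, id = "b")
  expect_equal(length(correspond(a, b)$resno), 10)
  b2 <- toy_model(resno = 6:15, id = "b2")
  cr <- correspond(a, b2)
  expect_equal(cr$resno, 6:10)
  expect_equal(nrow(cr$P), 5)
  b3 <- toy_model(resno = 21:30, id = "b3")
  expect_error(correspond(a, b3), "insufficient residue correspondence")
  expect_error(correspond(a, toy_model(resno = 1:10, target = "other")),
               "different targets")
})

test_that("Kabsch superposition recovers identity, translation and rotation", {
  P <- cbind(c(0, 1, 0, 2), c(0, 0, 1, 2), c(0, 0, 0, 1))
  s_id <- kabsch_superpose(P, P)
  expect_equal(s_id$rmsd, 0, tolerance = 1e-10)
  expect_equal(s_id$rotation, diag(3), tolerance = 1e-8)

  Q <- sweep(P, 2, c(5, 0, 0), `+`)
  s_tr <- kabsch_superpose(P, Q)
  expect_equal(s_tr$rmsd, 0, tolerance = 1e-10)
  expect_equal(s_tr$translation, c(5, 0, 0), tolerance = 1e-8)
  expect_equal(s_tr$rotation, diag(3), tolerance = 1e-8)

  # rotation by 90 degrees about z on a 5-point helix fragment
  H <- ca_coords(make_helix(5))
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Qr <- H %*% t(Rz)
  s_rot <- kabsch_superpose(H, Qr)
  expect_equal(s_rot$rmsd, 0, tolerance = 1e-8)
  expect_equal(s_rot$rotation, Rz, tolerance = 1e-6)
  # grid oracle over z-rotations at 1 degree: no grid angle beats the fit
  grid_rmsd <- vapply(0:359, function(deg) {
    th <- deg * pi / 180
    Rg <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    moved <- H %*% t(Rg)
    moved <- sweep(moved, 2, colMeans(Qr) - colMeans(moved), `+`)
    sqrt(mean(rowSums((moved - Qr)^2)))
  }, numeric(1))
  expect_lte(s_rot$rmsd, min(grid_rmsd) + 1e-9)

  expect_true(all(abs(crossprod(s_rot$rotation) - diag(3)) < 1e-8))
  expect_equal(det(s_rot$rotation), 1, tolerance = 1e-8)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]), "at least 3")
})

test_that("TM-score is 1 on identical structures and uses the d0 floor", {
  m50 <- make_helix(50)
  expect_equal(tm_score(m50, m50), 1.0, tolerance = 1e-9)
  # L = 20: d0 = max(1.24 * 5^(1/3) - 1.8, 0.5) = 0.5 (floor engaged)
  m20 <- make_helix(20)
  expect_equal(1.24 * (20 - 15)^(1 / 3) - 1.8, 0.32037, tolerance = 1e-4)
  expect_equal(tm_score(m20, m20), 1.0, tolerance = 1e-9)
})

test_that("TM-score equals the exhaustive subset-superposition oracle on a displaced-half toy", {
  native <- make_helix(8)
  model <- perturb_model(native, 0.2, seed = 7)
  model$x[5:8] <- model$x[5:8] + 40 # displace one half
  cr <- correspond(model, native)
  expect_equal(tm_score(model, native), oracle_tm(cr$P, cr$Q, 8),
               tolerance = 1e-6)
})

test_that("GDT-TS scores a rigid half-displacement at 0.5 and is translation-invariant", {
  native <- make_helix(10)
  model <- native
  model$x[6:10] <- model$x[6:10] + 50
  expect_equal(gdt_ts(model, native), 0.5, tolerance = 1e-9)
  cr <- correspond(model, native)
  expect_equal(gdt_ts(model, native), oracle_gdt(cr$P, cr$Q), tolerance = 1e-6)
  shifted <- transform_model(native, list(R = diag(3), t = c(10, -4, 2)))
  expect_equal(gdt_ts(shifted, native), 1.0, tolerance = 1e-9)
  expect_equal(gdt_ts(native, native), 1.0, tolerance = 1e-12)
})

test_that("TM-score and GDT-TS match the exhaustive oracle on random small instances", {
  for (r in 1:25) {
    inst <- random_instance(r)
    cr <- correspond(inst$model, inst$native)
    expect_equal(tm_score(inst$model, inst$native),
                 oracle_tm(cr$P, cr$Q, inst$m), tolerance = 1e-6)
    expect_equal(gdt_ts(inst$model, inst$native),
                 oracle_gdt(cr$P, cr$Q), tolerance = 1e-6)
  }
})

test_that("metrics are invariant under rigid transforms", {
  native <- make_helix(20)
  model <- perturb_model(native, 0.8, seed = 3)
  tm0 <- tm_score(model, native)
  gdt0 <- gdt_ts(model, native)
  lddt0 <- lddt_ca(model, native)
  for (s in 1:3) {
    rigid <- random_rigid(s)
    both_m <- transform_model(model, rigid)
    both_n <- transform_model(native, rigid)
    # common transform: all metrics invariant
    expect_equal(tm_score(both_m, both_n), tm0, tolerance = 1e-6)
    expect_equal(gdt_ts(both_m, both_n), gdt0, tolerance = 1e-6)
    expect_equal(lddt_ca(both_m, both_n), lddt0, tolerance = 1e-9)
    # transform of one side only: superposition metrics invariant
    expect_equal(tm_score(both_m, native), tm0, tolerance = 1e-6)
    expect_equal(gdt_ts(both_m, native), gdt0, tolerance = 1e-6)
  }
})

test_that("CA-lDDT follows the hand-enumerated pass table on a 4-residue toy", {
  # square in the xy plane: qualifying pairs (|i-j| >= 2, ref dist < 15)
  # are (1,3), (1,4), (2,4); perturb residue 4 by 1.5 A along x
  coords <- cbind(c(0, 3, 3, 0), c(0, 0, 3, 3), 0)
  ref <- toy_model(resno = 1:4, coords = coords, id = "ref")
  mod_coords <- coords
  mod_coords[4, 1] <- mod_coords[4, 1] + 1.5
  mod <- toy_model(resno = 1:4, coords = mod_coords, id = "mod")
  d_ref_13 <- sqrt(18); d_mod_13 <- sqrt(18)           # untouched
  d_ref_14 <- 3;        d_mod_14 <- sqrt(1.5^2 + 9)    # diff ~ 0.3541
  d_ref_24 <- sqrt(18); d_mod_24 <- sqrt(1.5^2 + 9)    # diff ~ 0.8876
  diffs <- abs(c(d_mod_13 - d_ref_13, d_mod_14 - d_ref_14, d_mod_24 - d_ref_24))
  expected <- mean(vapply(c(0.5, 1, 2, 4), function(t) mean(diffs < t), numeric(1)))
  expect_equal(lddt_ca(mod, ref), expected, tolerance = 1e-12)
  expect_equal(expected, (2 / 3 + 1 + 1 + 1) / 4, tolerance = 1e-9)
})

test_that("CA-lDDT hits the endpoints", {
  m <- make_helix(12)
  expect_equal(lddt_ca(m, m), 1.0)
  # inflate all distances by scaling coordinates far beyond every threshold
  blown <- structure_model(m$resno, m$aa, ca_coords(m) * 10, m$plddt,
                           model_id = "blown", target_id = target_id(m))
  expect_equal(lddt_ca(blown, m), 0.0)
})

test_that("similarity matrix is symmetric, unit-diagonal and recomputable", {
  native <- make_helix(16, target_id = "simtoy")
  pool <- make_pool(native, c(0.3, 1.2), seeds = 1)
  pool <- add_models(pool, list(perturb_model(native, 0.6, seed = 9,
                                              model_id = "extra")))
  sim <- similarity_matrix(pool)
  expect_equal(sim, t(sim))
  expect_equal(unname(diag(sim)), rep(1, 3))
  models <- pool_models(pool)
  for (i in 1:2) for (j in (i + 1):3) {
    l <- max(nrow(models[[i]]), nrow(models[[j]]))
    manual <- (tm_score(models[[i]], models[[j]], lref = l) +
               tm_score(models[[j]], models[[i]], lref = l)) / 2
    expect_equal(sim[i, j], manual, tolerance = 1e-12)
  }
  ident_pool <- model_pool(list(
    set_model_meta(native, model_id = "c1"),
    set_model_meta(native, model_id = "c2")))
  expect_equal(unname(similarity_matrix(ident_pool)),
               matrix(1, 2, 2), tolerance = 1e-9)
  expect_error(similarity_matrix(model_pool(list(native))), "at least 2")
})
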