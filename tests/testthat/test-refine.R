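# shared toy refinement setting: a 20-residue target with a known native,
# a 2-row starting alignment and donor models feeding the mock search
refine_setting <- function(n = 20, seed = 1) {
  seqs <- foldrank:::random_aa(n, seed = seed)
  native <- make_helix(n, model_id = "native", target_id = "rt", sequence = seqs)
  initial <- perturb_model(native, 1.2, seed = seed + 5, model_id = "initial")
  initial$plddt <- rep(70, n)
  donors <- lapply(1:3, function(i) {
    d <- perturb_model(native, 0.4 * i, seed = seed + 10 + i,
                       model_id = paste0("donor", i))
    d$aa <- strsplit(foldrank:::mutate_seq(seqs, 0.4, seed + 20 + i), "")[[1]]
    d
  })
  base_msa <- msa(c("rt", "hom1"),
                  c(seqs, foldrank:::mutate_seq(seqs, 0.5, seed + 2)))
  list(native = native, initial = initial, donors = donors, msa = base_msa)
}

test_that("an always-improving backend runs to the 5-iteration cap", {
  st <- refine_setting()
  fold <- mock_folding_backend(st$native, start = 71, delta = 1, seed = 3)
  res <- run_refinement(st$initial, st$msa,
                        search = mock_search_backend(st$donors), fold = fold)
  expect_equal(nrow(res$trace), 5)
  expect_true(all(res$trace$accepted))
  expect_equal(res$trace$input_plddt, c(70, 71, 72, 73, 74))
  expect_equal(res$trace$best_new_plddt, c(71, 72, 73, 74, 75))
  expect_true(all(diff(res$trace$input_plddt) > 0))
  expect_equal(global_plddt(res$model), 75)
  expect_equal(source_tag(res$model), "refined")
})

test_that("a never-improving backend stops after one rejected iteration", {
  st <- refine_setting()
  fold <- mock_folding_backend(st$native, start = 50, delta = 0, seed = 3)
  res <- run_refinement(st$initial, st$msa,
                        search = mock_search_backend(st$donors), fold = fold)
  expect_equal(nrow(res$trace), 1)
  expect_false(res$trace$accepted)
  expect_true(res$refined)
  expect_equal(global_plddt(res$model), 50) # best model of iteration 1
})

test_that("improvement on iterations 1-2 only gives a 3-iteration trace with output from the best call", {
  st <- refine_setting()
  fold <- mock_folding_backend(st$native, values = c(72, 74, 60), seed = 3)
  res <- run_refinement(st$initial, st$msa,
                        search = mock_search_backend(st$donors), fold = fold)
  expect_equal(nrow(res$trace), 3)
  expect_equal(res$trace$accepted, c(TRUE, TRUE, FALSE))
  expect_equal(res$trace$input_plddt, c(70, 72, 74))
  expect_equal(global_plddt(res$model), 74)
  # output pLDDT never below the best of iteration 1
  expect_gte(global_plddt(res$model), res$trace$best_new_plddt[1])
})

test_that("zero hits in iteration 1 returns the input with a one-row trace", {
  st <- refine_setting()
  fold <- mock_folding_backend(st$native, start = 90, delta = 1, seed = 3)
  res <- run_refinement(st$initial, st$msa,
                        search = mock_search_backend(list()), fold = fold)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$trace$n_hits, 0L)
  expect_false(res$refined)
  expect_identical(res$model, st$initial)
})

test_that("backend failures propagate with iteration context and contracts are enforced", {
  st <- refine_setting()
  boom <- function(model) stop("disk on fire")
  fold <- mock_folding_backend(st$native, start = 90, seed = 3)
  expect_error(run_refinement(st$initial, st$msa, search = boom, fold = fold),
               "search backend failed at refinement iteration 1")
  bad_fold <- function(msa, templates, n_models = 5) list(st$initial)
  expect_error(run_refinement(st$initial, st$msa,
                              search = mock_search_backend(st$donors),
                              fold = bad_fold),
               "exactly 5 models")
  wrong_msa <- msa("other", strrep("A", 20))
  if (paste(st$initial$aa, collapse = "") != strrep("A", 20)) {
    expect_error(run_refinement(st$initial, wrong_msa,
                                search = mock_search_backend(st$donors),
                                fold = fold),
                 "does not match the model sequence")
  }
})

test_that("refinement is bit-reproducible with a seeded mock", {
  st <- refine_setting()
  run_once <- function() {
    fold <- mock_folding_backend(st$native, start = 71, delta = 1, seed = 11)
    run_refinement(st$initial, st$msa,
                   search = mock_search_backend(st$donors), fold = fold)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$trace, b$trace)
  expect_identical(ca_coords(a$model), ca_coords(b$model))
})

test_that("with an oracle-confidence backend refinement never loses true quality", {
  st <- refine_setting(n = 14)
  for (s in 1:3) {
    fold <- mock_folding_backend(st$native, sigma = 0.6, seed = s,
                                 plddt_mode = "oracle")
    init <- st$initial
    init$plddt <- rep(1, nrow(init)) # low self-estimate: accept while improving
    res <- run_refinement(init, st$msa,
                          search = mock_search_backend(st$donors), fold = fold)
    iter1_best <- res$trace$best_new_plddt[1] / 100
    expect_gte(gdt_ts(res$model, st$native) + 1e-9, iter1_best)
  }
})

test_that("refine_topk pools refined and unrefined models and keeps the best five", {
  st <- refine_setting()
  top5 <- lapply(1:5, function(i) {
    m <- perturb_model(st$native, 0.8, seed = 30 + i, model_id = paste0("u", i))
    m$plddt <- rep(60 + i, nrow(m))
    m
  })
  msas <- rep(list(st$msa), 5)
  # never-improving refinement: every refined model sits at 40
  fold_lo <- function() mock_folding_backend(st$native, start = 40, delta = 0, seed = 2)
  rk <- refine_topk(top5, msas, search = mock_search_backend(st$donors),
                    fold = fold_lo())
  expect_equal(sort(vapply(rk$models, model_id, character(1))),
               sort(paste0("u", 1:5)))
  # always much better: the five refined models win
  fold_hi <- mock_folding_backend(st$native, start = 90, delta = 0, seed = 2)
  rk2 <- refine_topk(top5, msas, search = mock_search_backend(st$donors),
                     fold = fold_hi)
  expect_true(all(grepl("_refined$", vapply(rk2$models, model_id, character(1)))))
  expect_error(refine_topk(top5[1:4], msas[1:4],
                           search = mock_search_backend(st$donors),
                           fold = fold_hi),
               "exactly 5")
})
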