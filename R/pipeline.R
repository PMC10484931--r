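#' The canonical MSA/template sampling presets
#'
#' Eight MSA--template combinations drive model sampling: four MSA families
#' (default, original, colabfold, img), each paired with either the
#' standard pdb70 template set or the in-house resolution- and
#' redundancy-curated template database (the `_seq_temp` variants). Engine
#' parameters are fixed at `num_ensemble = 8` and `num_recycles = 8`; the
#' external sequence-search engines behind each MSA are out of scope and
#' recorded here as configuration only.
#'
#' @return A tibble with columns `msa_name` and `template_db` in canonical
#'   order.
#' @export
sampling_presets <- function() {
  tibble::tibble(
    msa_name = c("default", "default_seq_temp", "original", "ori_seq_temp",
                 "colabfold", "colab_seq_temp", "img", "img_seq_temp"),
    template_db = rep(c("pdb70", "PDB_sort90"), 4)
  )
}

#' Build the per-target sampling plan
#'
#' One combination per available MSA name, in canonical preset order, each
#' folding `models_per_combo` models (5 by default, for up to 40 planned
#' models with all eight combinations). The deep-search alignments (`img`,
#' `img_seq_temp`) are reserved for hard targets: they are dropped from the
#' plan when the default MSA's depth is strictly greater than 200.
#'
#' @param available_msas Character vector of available MSA names; must
#'   include `"default"` and contain only preset names.
#' @param default_msa_depth Depth (row count) of the default MSA.
#' @param models_per_combo Models folded per combination, default 5.
#' @return A tibble of class `sampling_plan` with columns `msa_name`,
#'   `template_db`, `models_per_combo`, `num_ensemble`, `num_recycles`,
#'   and a `planned_models` attribute with the total.
#' @export
build_sampling_plan <- function(available_msas, default_msa_depth,
                                models_per_combo = 5) {
  presets <- sampling_presets()
  unknown <- setdiff(available_msas, presets$msa_name)
  if (length(unknown) > 0) {
    stop("unknown MSA name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"default" %in% available_msas) {
    stop("'default' MSA must be available", call. = FALSE)
  }
  plan <- presets[presets$msa_name %in% available_msas, , drop = FALSE]
  if (default_msa_depth > 200) {
    plan <- plan[!plan$msa_name %in% c("img", "img_seq_temp"), , drop = FALSE]
  }
  plan$models_per_combo <- as.integer(models_per_combo)
  plan$num_ensemble <- 8L
  plan$num_recycles <- 8L
  attr(plan, "planned_models") <- sum(plan$models_per_combo)
  class(plan) <- c("sampling_plan", class(plan))
  plan
}

#' Planned model count of a sampling plan
#'
#' @param plan A `sampling_plan`.
#' @return Integer total of models the plan schedules.
#' @export
planned_models <- function(plan) attr(plan, "planned_models")

#' Rank a pool and select the submission under a predictor policy
#'
#' The four predictor policies differ only in how they rank and whether
#' they refine:
#'
#' * `"deep"`: rank by global pLDDT.
#' * `"egnn"` (and the `"human"` alias, which simply ranks a generally
#'   larger pool): rank by the pLDDT/APOLLO average.
#' * `"refine"`: egnn ranking, then [refine_topk()] on the top five.
#' * `"qa"`: refinement applied to the five models from the `"default"`
#'   sampling combination only, then the refined/unrefined ten re-pooled by
#'   pLDDT as in [refine_topk()].
#'
#' When the pool contains assembly-derived models they are preferred for
#' the leading submission slots via [compose_submission()].
#'
#' @param pool A [model_pool()].
#' @param policy One of `"deep"`, `"egnn"`, `"refine"`, `"qa"`, `"human"`.
#' @param backends For the refining policies, a list with elements
#'   `search`, `fold` and `msas` (a named list of [msa()] objects keyed by
#'   model id).
#' @param sim Optional precomputed similarity matrix.
#' @param n Number of models to select, default 5.
#' @param assembly_slots Leading slots reserved for assembly-derived
#'   models, default 4.
#' @return A [model_pool()] of the selected models in submission order.
#' @export
rank_and_select <- function(pool, policy = c("deep", "egnn", "refine", "qa", "human"),
                            backends = NULL, sim = NULL, n = 5,
                            assembly_slots = 4) {
  policy <- match.arg(policy)
  needs_sim <- policy %in% c("egnn", "refine", "human")
  scores_tbl <- if (needs_sim && nrow(pool) >= 2) qa_scores(pool, sim = sim) else NULL
  score_of <- function(column) {
    if (is.null(scores_tbl)) {
      tibble::tibble(model_id = pool$model_id, score = pool$plddt_global)
    } else {
      tibble::tibble(model_id = scores_tbl$model_id, score = scores_tbl[[column]])
    }
  }
  if (policy %in% c("refine", "qa")) {
    if (is.null(backends) || is.null(backends$search) || is.null(backends$fold) ||
        is.null(backends$msas)) {
      stop("policy '", policy, "' requires backends: search, fold, msas", call. = FALSE)
    }
    if (policy == "refine") {
      ranked <- rank_models(score_of("apollo_plddt_avg")$score,
                            score_of("apollo_plddt_avg")$model_id)
      top_ids <- utils::head(ranked, 5)
    } else {
      def <- pool[pool$source_tag == "default", , drop = FALSE]
      top_ids <- utils::head(rank_models(def$plddt_global, def$model_id), 5)
    }
    if (length(top_ids) < 5) {
      stop("policy '", policy, "' needs 5 rankable models", call. = FALSE)
    }
    models5 <- pool_models(pool)[top_ids]
    msas5 <- backends$msas[top_ids]
    if (any(vapply(msas5, is.null, logical(1)))) {
      stop("backends$msas must cover the top 5 model ids", call. = FALSE)
    }
    rk <- refine_topk(unname(models5), unname(msas5),
                      search = backends$search, fold = backends$fold)
    return(model_pool(rk$models))
  }
  column <- switch(policy, deep = "plddt_global", egnn = , human = "apollo_plddt_avg")
  scores <- score_of(column)
  if (any(pool$source_tag == "assembly_extracted")) {
    compose_submission(pool, scores, n = n, assembly_slots = assembly_slots)
  } else {
    chosen <- utils::head(rank_models(scores$score, scores$model_id), min(n, nrow(pool)))
    out <- model_pool(pool_models(pool)[chosen])
    out[match(chosen, out$model_id), ]
  }
}

#' Evaluate a pool against the native structure
#'
#' Computes TM-score, GDT-TS and CA-lDDT of every pool model against the
#' native, plus pool-level summaries: the best-of-pool values, the share of
#' models with the correct fold (TM-score > 0.5) and the high-accuracy
#' share (TM-score > 0.8). When selector scores are supplied, the top-1
#' model, its ranking loss in GDT-TS units and the per-target Pearson
#' correlation between the scores and true GDT-TS are evaluated as well.
#'
#' @param pool A [model_pool()] sharing the native's target.
#' @param native The native [structure_model()].
#' @param scores Optional tibble with columns `model_id` and `score`.
#' @return A tibble of class `native_evaluation` with per-model columns
#'   `model_id`, `tm_score`, `gdt_ts`, `lddt_ca`; summaries are attached
#'   as attributes and surfaced by [glance.native_evaluation()].
#' @export
evaluate_against_native <- function(pool, native, scores = NULL) {
  models <- pool_models(pool)
  out <- tibble::tibble(
    model_id = names(models),
    tm_score = unname(vapply(models, function(m) tm_score(m, native), numeric(1))),
    gdt_ts = unname(vapply(models, function(m) gdt_ts(m, native), numeric(1))),
    lddt_ca = unname(vapply(models, function(m) lddt_ca(m, native), numeric(1)))
  )
  attr(out, "target_id") <- attr(pool, "target_id")
  attr(out, "correct_topology_fraction") <- mean(out$tm_score > 0.5)
  attr(out, "high_accuracy_fraction") <- mean(out$tm_score > 0.8)
  attr(out, "best_gdt_ts") <- max(out$gdt_ts)
  attr(out, "best_tm_score") <- max(out$tm_score)
  if (!is.null(scores)) {
    scores <- tibble::as_tibble(scores)
    top1 <- rank_models(scores$score, scores$model_id)[1]
    true_gdt <- stats::setNames(out$gdt_ts, out$model_id)
    attr(out, "top1_id") <- top1
    attr(out, "ranking_loss") <- ranking_loss(true_gdt, top1)
    pred <- stats::setNames(scores$score, scores$model_id)[out$model_id]
    attr(out, "pearson") <- tryCatch(
      per_target_correlation(unname(pred), out$gdt_ts),
      error = function(e) NA_real_)
  }
  class(out) <- c("native_evaluation", class(out))
  out
}

#' Write an evaluation or QA table as TSV
#'
#' @param x A tibble (e.g. `native_evaluation` or `qa_scores`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full toy workflow end to end
#'
#' Generates a synthetic target, builds the sampling plan, assembles the
#' model pool, scores and ranks it, refines the top models with mock
#' backends, composes the submission and evaluates everything against the
#' hidden native --- entirely offline and deterministically under `seed`.
#' Intended for demonstrations and reproducibility checks.
#'
#' @param seed Integer master seed.
#' @param n Residue count of the toy target, default 40.
#' @param sigmas Pool noise levels.
#' @param seeds Replicates per noise level.
#' @return A list with `plan`, `pool`, `scores`, `selection` (model ids in
#'   submission order), `refinement` (trace tibble), `evaluation` and
#'   `summary` (one-row tibble).
#' @export
demo_pipeline <- function(seed = 1, n = 40, sigmas = c(0.3, 0.8, 1.5, 2.5, 4),
                          seeds = 1:2) {
  seqs <- random_aa(n, seed = seed)
  native <- make_helix(n, model_id = "native", target_id = "toy", sequence = seqs)
  pool <- make_pool(native, sigmas, seeds = as.integer(seed) * 100L + seeds)
  plan <- build_sampling_plan(sampling_presets()$msa_name,
                              default_msa_depth = 150)
  sim <- similarity_matrix(pool)
  scores <- qa_scores(pool, sim = sim)
  base_msa <- msa(c("toy", "hom1"), c(seqs, mutate_seq(seqs, 0.5, seed + 1)))
  donors <- purrr::map(1:3, function(i) {
    d <- perturb_model(native, sigma = 0.3 * i, seed = seed + 40 + i,
                       model_id = paste0("donor", i))
    d$aa <- strsplit(mutate_seq(seqs, 0.3 * i, seed + 50 + i), "", fixed = TRUE)[[1]]
    d
  })
  backends <- list(
    search = mock_search_backend(donors),
    fold = mock_folding_backend(native, start = 70, delta = 1, sigma = 0.4,
                                seed = seed),
    msas = stats::setNames(rep(list(base_msa), nrow(pool)), pool$model_id)
  )
  selection <- rank_and_select(pool, "refine", backends = backends)
  ranked <- rank_models(scores$apollo_plddt_avg, scores$model_id)
  refinement <- run_refinement(
    pool_models(pool)[[ranked[1]]], base_msa,
    search = backends$search,
    fold = mock_folding_backend(native, start = 70, delta = 1, sigma = 0.4,
                                seed = seed + 99))
  evaluation <- evaluate_against_native(
    pool, native,
    scores = tibble::tibble(model_id = scores$model_id,
                            score = scores$apollo_plddt_avg))
  summary <- tibble::tibble(
    planned_models = planned_models(plan),
    pool_size = nrow(pool),
    pss = pss(sim),
    top1 = attr(evaluation, "top1_id"),
    ranking_loss = attr(evaluation, "ranking_loss"),
    best_gdt_ts = attr(evaluation, "best_gdt_ts"),
    correct_topology_fraction = attr(evaluation, "correct_topology_fraction"),
    refine_iters = nrow(refinement$trace),
    selected_best_plddt = global_plddt(selection$model[[1]])
  )
  list(plan = plan, pool = pool, scores = scores,
       selection = selection$model_id, refinement = refinement$trace,
       evaluation = evaluation, summary = summary)
}
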