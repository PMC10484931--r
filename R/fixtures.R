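#' Synthetic structures, pools and backends
#'
#' Deterministic generators used for offline testing of the whole
#' workflow: an ideal helical CA trace, Gaussian coordinate perturbations
#' with a confidence proxy tied to the noise level, pools with known
#' quality ordering, synthetic structure-search hit tables, and mock
#' folding/search backends honouring the backend contracts.
#'
#' @name fixtures
NULL

#' Ideal alpha-helical CA trace
#'
#' A poly-alanine helix with rise 1.5 Angstrom, radius 2.3 Angstrom and 100
#' degrees of twist per residue, giving the canonical ~3.83 Angstrom
#' consecutive CA--CA spacing. Confidence is a flat 90. Deterministic:
#' the geometry does not depend on any random state.
#'
#' @param n Residue count, at least 4.
#' @param model_id,target_id,source_tag Metadata for the model.
#' @param sequence Optional one-letter sequence of length `n`
#'   (default poly-alanine).
#' @return A [structure_model()].
#' @export
make_helix <- function(n, model_id = "helix", target_id = "toy",
                       source_tag = "default", sequence = NULL) {
  if (n < 4) stop("a helix fixture needs at least 4 residues", call. = FALSE)
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  coords <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  aa <- if (is.null(sequence)) rep("A", n) else strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(aa) != n) stop("sequence length must equal n", call. = FALSE)
  structure_model(seq_len(n), aa, coords, plddt = rep(90, n),
                  model_id = model_id, target_id = target_id,
                  source_tag = source_tag)
}

#' Gaussian coordinate perturbation with a confidence proxy
#'
#' Adds independent Gaussian noise of standard deviation `sigma` to every
#' coordinate and sets every residue's confidence to `100 * exp(-sigma)`,
#' a monotone proxy tying self-estimated confidence to true quality so
#' that QA-recovery tests have ground truth. The true noise level is
#' recorded in the `sigma` attribute.
#'
#' @param model A [structure_model()].
#' @param sigma Noise standard deviation in Angstrom (>= 0).
#' @param seed Integer seed; the perturbation is deterministic given it.
#' @param model_id Optional id for the perturbed model.
#' @return A perturbed [structure_model()].
#' @export
perturb_model <- function(model, sigma, seed = 1, model_id = NULL) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  n <- nrow(model)
  noise <- withr::with_seed(as.integer(seed), matrix(stats::rnorm(3 * n, sd = sigma), n, 3))
  out <- structure_model(
    model$resno, model$aa, ca_coords(model) + noise,
    plddt = rep(min(100, 100 * exp(-sigma)), n),
    model_id = model_id %||% sprintf("%s_s%.3g_r%d", model_id(model), sigma, seed),
    target_id = target_id(model),
    chain_id = attr(model, "chain_id"),
    source_tag = source_tag(model)
  )
  attr(out, "sigma") <- sigma
  out
}

#' Pool of perturbed models with known quality ordering
#'
#' One perturbed copy of the native per (sigma, seed) combination, so the
#' true quality ordering of the pool is known by construction (lower sigma
#' means closer to the native).
#'
#' @param native A [structure_model()].
#' @param sigmas Non-empty numeric vector of noise levels.
#' @param seeds Integer vector of replicate seeds (default 1).
#' @param source_tag Source tag applied to the generated models.
#' @return A [model_pool()]; each member records its true `sigma`
#'   attribute.
#' @export
make_pool <- function(native, sigmas, seeds = 1L, source_tag = "default") {
  if (length(sigmas) == 0) stop("sigmas must be non-empty", call. = FALSE)
  grid <- expand.grid(seed = seeds, sigma = sigmas)
  models <- purrr::map(seq_len(nrow(grid)), function(k) {
    m <- perturb_model(native, grid$sigma[k], seed = grid$seed[k],
                       model_id = sprintf("m%02d_s%.3g_r%d", k, grid$sigma[k], grid$seed[k]))
    set_model_meta(m, source_tag = source_tag)
  })
  model_pool(models)
}

#' Synthesise structure-search hits from donor models
#'
#' Builds the full-span, gapless hit rows a structure search would report
#' for donors that share the query's residues (truncated donors yield
#' correspondingly shortened intervals). E-values increase with the donor's
#' recorded noise level (`sigma` attribute; donors without one are ordered
#' as given), so better donors rank first.
#'
#' @param query_model The query [structure_model()].
#' @param donor_models List of donor models.
#' @return A `structure_hits` tibble.
#' @export
make_hits_from_models <- function(query_model, donor_models) {
  if (length(donor_models) == 0) {
    return(structure_hits(tibble::tibble(
      query_id = character(), hit_id = character(), evalue = numeric(),
      tm = numeric(), qstart = integer(), qend = integer(),
      tstart = integer(), tend = integer(), qaln = character(),
      taln = character())))
  }
  sig <- vapply(donor_models, function(m) attr(m, "sigma") %||% NA_real_, numeric(1))
  rank_key <- if (all(is.na(sig))) seq_along(donor_models) else rank(sig, ties.method = "first")
  rows <- purrr::map(seq_along(donor_models), function(i) {
    d <- donor_models[[i]]
    shared <- intersect(query_model$resno, d$resno)
    if (length(shared) == 0) return(NULL)
    qs <- min(match(shared, query_model$resno))
    qe <- max(match(shared, query_model$resno))
    span_q <- query_model$aa[qs:qe]
    ts <- min(match(shared, d$resno))
    te <- max(match(shared, d$resno))
    span_t <- d$aa[ts:te]
    if (length(span_q) != length(span_t)) return(NULL)
    tibble::tibble(
      query_id = target_id(query_model), hit_id = model_id(d),
      evalue = 1e-10 * 10^(rank_key[i] - 1), tm = NA_real_,
      qstart = qs, qend = qe, tstart = ts, tend = te,
      qaln = paste(span_q, collapse = ""), taln = paste(span_t, collapse = ""))
  })
  structure_hits(dplyr::bind_rows(purrr::compact(rows)))
}

#' Write a hit table as TSV in the default dialect
#'
#' @param hits A hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, c("query_id", "hit_id", "evalue", "tm", "qstart",
                              "qend", "tstart", "tend", "qaln", "taln")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Mock folding backend
#'
#' Returns a function honouring the folding-backend contract
#' (`function(msa, templates, n_models)`) that perturbs a hidden native
#' and assigns confidences according to a schedule, deterministically per
#' (seed, call index):
#'
#' * `plddt_mode = "schedule"`: the best model of call k gets global pLDDT
#'   `start + delta * (k - 1)` (or `values[k]` when `values` is given);
#'   its siblings trail by one point each.
#' * `plddt_mode = "oracle"`: every model's pLDDT is its true GDT-TS
#'   against the hidden native times 100, tying self-reported confidence
#'   to true quality.
#'
#' @param hidden_native The native [structure_model()] the mock perturbs.
#' @param start,delta Best-pLDDT schedule: call k yields
#'   `start + delta * (k - 1)`.
#' @param values Optional explicit best-pLDDT per call (overrides
#'   start/delta); calls beyond the vector reuse its last value.
#' @param sigma Coordinate noise of the generated models (default 0.5).
#' @param seed Backend seed.
#' @param plddt_mode `"schedule"` or `"oracle"`.
#' @return A folding backend closure with a call counter.
#' @export
mock_folding_backend <- function(hidden_native, start = 70, delta = 1,
                                 values = NULL, sigma = 0.5, seed = 1,
                                 plddt_mode = c("schedule", "oracle")) {
  plddt_mode <- match.arg(plddt_mode)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  force(hidden_native)
  function(msa, templates, n_models = 5) {
    counter$k <- counter$k + 1L
    k <- counter$k
    best <- if (!is.null(values)) values[min(k, length(values))]
            else start + delta * (k - 1)
    purrr::map(seq_len(n_models), function(m) {
      sub_seed <- (as.integer(seed) * 1000L + k * 29L + m * 7L) %% .Machine$integer.max
      mdl <- perturb_model(hidden_native, sigma, seed = sub_seed,
                           model_id = sprintf("fold_c%02d_m%d", k, m))
      pl <- switch(plddt_mode,
        schedule = max(0, min(100, best - (m - 1))),
        oracle = 100 * gdt_ts(mdl, hidden_native))
      mdl$plddt <- rep(pl, nrow(mdl))
      set_model_meta(mdl, source_tag = "refined")
    })
  }
}

#' Mock search backend
#'
#' Returns a function honouring the search-backend contract
#' (`function(model) -> hit table`) that reports the given donor models as
#' hits via [make_hits_from_models()]. With no donors it returns an empty
#' hit table (the zero-hit case).
#'
#' @param donor_models List of donor `structure_model` objects (possibly
#'   empty).
#' @return A search backend closure.
#' @export
mock_search_backend <- function(donor_models = list()) {
  force(donor_models)
  function(model) make_hits_from_models(model, donor_models)
}

#' Write a complete toy workspace
#'
#' Materialises a self-contained toy prediction workspace on disk: a native
#' structure, a pool of perturbed model PDBs, the query alignment, a
#' structure-search hit table and a template metadata table. Everything is
#' deterministic given `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param n Residue count of the toy target (default 40).
#' @param sigmas Noise levels of the pool (default 0.3, 0.8, 1.5, 2.5, 4).
#' @param seeds Replicate seeds per noise level (default 1:2).
#' @param seed Master seed controlling donor sequences.
#' @return Invisibly, a list of the paths written.
#' @export
simulate_workspace <- function(dir, n = 40, sigmas = c(0.3, 0.8, 1.5, 2.5, 4),
                               seeds = 1:2, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pool"), showWarnings = FALSE)
  seqs <- random_aa(n, seed = seed)
  native <- make_helix(n, model_id = "native", target_id = "toy", sequence = seqs)
  native_path <- file.path(dir, "native.pdb")
  write_model(native, native_path)
  pool <- make_pool(native, sigmas, seeds)
  pool_paths <- purrr::map_chr(seq_len(nrow(pool)), function(i) {
    p <- file.path(dir, "pool", paste0(pool$model_id[i], ".pdb"))
    write_model(pool$model[[i]], p)
    p
  })
  aln <- msa(c("toy", "homolog1"), c(seqs, mutate_seq(seqs, 0.5, seed + 1)))
  msa_path <- file.path(dir, "query.a3m")
  write_a3m(aln, msa_path)
  donors <- purrr::map(1:3, function(i) {
    d <- perturb_model(native, sigma = 0.4 * i, seed = seed + 10 + i,
                       model_id = paste0("donor", i))
    d$aa <- strsplit(mutate_seq(seqs, 0.3 * i, seed + 20 + i), "", fixed = TRUE)[[1]]
    d
  })
  hits <- make_hits_from_models(native, donors)
  hits_path <- file.path(dir, "hits.tsv")
  write_hits(hits, hits_path)
  # one clean template, one low-resolution, one too short, one redundant
  tpl_seq <- random_aa(40, seed = seed + 30)
  templates <- tibble::tibble(
    template_id = c("1abcA", "2defB", "3ghiC", "4jklD"),
    sequence = c(tpl_seq, random_aa(40, seed + 31),
                 substr(tpl_seq, 1, 25), mutate_seq(tpl_seq, 0.05, seed + 33)),
    resolution = c(2.1, 9.5, 1.8, 2.5),
    length = c(40L, 40L, 25L, 40L),
    source = "experimental")
  templates_path <- file.path(dir, "templates.tsv")
  write_templates(templates, templates_path)
  invisible(list(native = native_path, pool = pool_paths, msa = msa_path,
                 hits = hits_path, templates = templates_path))
}

# random one-letter AA sequence (20 standard letters)
random_aa <- function(n, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  withr::with_seed(as.integer(seed),
                   paste(sample(aa, n, replace = TRUE), collapse = ""))
}

# mutate a fraction of positions (rate in [0,1], capped) to random letters
mutate_seq <- function(s, rate, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- round(min(1, rate) * length(v))
  if (k == 0) return(s)
  withr::with_seed(as.integer(seed), {
    pos <- sample(length(v), k)
    v[pos] <- sample(aa, k, replace = TRUE)
  })
  paste(v, collapse = "")
}
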