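#' Extract a monomer model from an assembly structure
#'
#' Cuts the tertiary structure of one chain out of a predicted multi-chain
#' (quaternary) model, keeping the chain's in-assembly coordinates (no
#' re-centering) and reading per-residue confidence from the B-factor
#' column. The extracted model carries source tag `"assembly_extracted"`.
#' Confidence scores from an assembly predictor and a monomer predictor are
#' not guaranteed to be on comparable scales; the provenance tag surfaces
#' the mix, and no rescaling is applied.
#'
#' @param assembly_path PDB file with at least the requested chain.
#' @param chain_id Chain to extract.
#' @param target_id Target the chain corresponds to (defaults to the file
#'   stem).
#' @param model_id Id for the extracted model (defaults to
#'   `<stem>_<chain>`).
#' @return A [structure_model()].
#' @export
extract_chain <- function(assembly_path, chain_id, target_id = NULL,
                          model_id = NULL) {
  stem <- sub("\\.[^.]*$", "", basename(assembly_path))
  read_model(assembly_path, chain = chain_id,
             model_id = model_id %||% paste0(stem, "_", chain_id),
             target_id = target_id %||% stem,
             source_tag = "assembly_extracted")
}

#' Add assembly-derived models to a monomer pool
#'
#' Extracts the target's chain from each assembly model file and adds the
#' resulting monomer models to the pool. Any cached similarity matrix or QA
#' scores are invalidated by construction (the pool is rebuilt). Model id
#' collisions raise an error.
#'
#' @param pool A [model_pool()].
#' @param assembly_paths Character vector of multi-chain PDB paths (may be
#'   empty, in which case the pool is returned unchanged).
#' @param chain_id Chain to extract from each assembly model.
#' @return The enlarged [model_pool()].
#' @export
integrate_pool <- function(pool, assembly_paths, chain_id) {
  if (length(assembly_paths) == 0) return(pool)
  extracted <- purrr::map(assembly_paths, function(p) {
    extract_chain(p, chain_id, target_id = attr(pool, "target_id"))
  })
  add_models(pool, extracted)
}

#' Compose a submission with assembly preference
#'
#' Orders the final submitted models: for targets that are subunits of an
#' assembly, the top-ranked assembly-derived models fill the first
#' `assembly_slots` positions (fewer when fewer exist), and the remaining
#' slots are filled by the top-ranked single-chain models not yet chosen.
#' With no assembly-derived models this reduces to the plain top-n by
#' score.
#'
#' @param pool A non-empty [model_pool()].
#' @param scores A tibble/data frame with columns `model_id` and `score`
#'   covering every pool model (any QA score may serve as `score`).
#' @param n Total number of models to submit, default 5.
#' @param assembly_slots Leading slots reserved for assembly-derived
#'   models, default 4 (configurable 3--4).
#' @return A [model_pool()] of the selected models in submission order.
#' @export
compose_submission <- function(pool, scores, n = 5, assembly_slots = 4) {
  scores <- tibble::as_tibble(scores)
  if (!all(pool$model_id %in% scores$model_id)) {
    stop("scores must cover every model in the pool", call. = FALSE)
  }
  sc <- stats::setNames(scores$score, scores$model_id)[pool$model_id]
  is_asm <- pool$source_tag == "assembly_extracted"
  asm_ranked <- rank_models(sc[is_asm], pool$model_id[is_asm])
  mono_ranked <- rank_models(sc[!is_asm], pool$model_id[!is_asm])
  n_total <- min(n, nrow(pool))
  head_asm <- utils::head(asm_ranked, min(assembly_slots, n_total))
  rest <- utils::head(c(mono_ranked, setdiff(asm_ranked, head_asm)),
                      n_total - length(head_asm))
  chosen <- c(head_asm, rest)
  models <- pool_models(pool)[chosen]
  out <- model_pool(models)
  out[match(chosen, out$model_id), ]
}

#' Graft a separately folded region into a full-length model
#'
#' Replaces the coordinates and confidences of a residue span in a
#' full-length model with those of a separately folded region model. The
#' region model is first rigidly superposed onto the full model using up to
#' `flank` residues adjacent to each side of the span that exist in both
#' models (falling back to superposing on the span itself when no flank
#' residues are shared), so the replacement preserves the region's global
#' placement while substituting its local geometry. Residues outside the
#' span are untouched; numbering and length are preserved; the result is
#' tagged `"grafted"`.
#'
#' @param full_model A [structure_model()] covering the whole target.
#' @param region_model A [structure_model()] covering (at least) the span.
#' @param span Length-2 integer vector, 1-based inclusive residue-number
#'   interval to replace; must lie inside the full model.
#' @param flank Maximum flank residues per side used for the superposition
#'   (default 10).
#' @return The grafted [structure_model()].
#' @export
graft_region <- function(full_model, region_model, span, flank = 10) {
  stopifnot(length(span) == 2, span[1] <= span[2])
  span_res <- span[1]:span[2]
  if (!all(span_res %in% full_model$resno)) {
    stop("span lies outside the full model's residues", call. = FALSE)
  }
  if (!all(span_res %in% region_model$resno)) {
    stop("region model does not cover the span", call. = FALSE)
  }
  full_res <- full_model$resno
  before <- rev(full_res[full_res < span[1]])
  after <- full_res[full_res > span[2]]
  flank_res <- c(rev(utils::head(before, flank)), utils::head(after, flank))
  flank_res <- flank_res[flank_res %in% region_model$resno]
  fit_res <- if (length(flank_res) >= 3) flank_res else span_res
  P <- ca_coords(region_model)[match(fit_res, region_model$resno), , drop = FALSE]
  Q <- ca_coords(full_model)[match(fit_res, full_model$resno), , drop = FALSE]
  sup <- kabsch_superpose(P, Q)
  region_xyz <- apply_superposition(sup, ca_coords(region_model))
  out <- full_model
  idx_full <- match(span_res, full_model$resno)
  idx_region <- match(span_res, region_model$resno)
  out$x[idx_full] <- region_xyz[idx_region, 1]
  out$y[idx_full] <- region_xyz[idx_region, 2]
  out$z[idx_full] <- region_xyz[idx_region, 3]
  out$plddt[idx_full] <- region_model$plddt[idx_region]
  set_model_meta(out, source_tag = "grafted")
}
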