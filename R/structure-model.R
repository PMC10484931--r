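#' Construct a CA-level structural model
#'
#' A `structure_model` is a tibble with one row per residue and columns
#' `resno` (strictly increasing 1-based residue numbers), `aa` (one-letter
#' amino-acid code), `x`, `y`, `z` (CA coordinates in Angstrom) and `plddt`
#' (per-residue predicted lDDT confidence on the 0--100 scale, the AlphaFold
#' convention for the PDB B-factor column). Identity metadata travels in
#' attributes: `model_id`, `target_id`, `chain_id` and `source_tag`.
#'
#' All similarity metrics in this package are CA-based, so a model carries
#' exactly one point per residue. Cross-model residue correspondence is by
#' residue number (`resno`), never by re-alignment.
#'
#' @param resno Integer vector of residue numbers, strictly increasing.
#' @param aa Character vector of one-letter residue codes (same length).
#' @param coords Numeric matrix (length(resno) x 3) of CA coordinates in
#'   Angstrom, or a data frame with columns x, y, z.
#' @param plddt Numeric vector of per-residue confidence in \[0, 100\].
#' @param model_id,target_id Identifiers for the model and its target.
#' @param chain_id Single chain character (default `"A"`).
#' @param source_tag Provenance tag, e.g. a sampling-method name,
#'   `"assembly_extracted"`, `"refined"` or `"grafted"`.
#'
#' @return A tibble of class `structure_model`.
#' @export
#' @examples
#' m <- structure_model(1:4, rep("A", 4), matrix(rnorm(12), 4, 3),
#'                      plddt = rep(90, 4), model_id = "m1", target_id = "T0")
#' global_plddt(m)
structure_model <- function(resno, aa, coords, plddt,
                            model_id = "model", target_id = "target",
                            chain_id = "A", source_tag = "default") {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(resno)
  if (n < 1) stop("structure_model requires at least one residue", call. = FALSE)
  if (length(aa) != n || nrow(coords) != n || length(plddt) != n) {
    stop("resno, aa, coords and plddt must describe the same residues",
         call. = FALSE)
  }
  resno <- as.integer(resno)
  if (any(diff(resno) <= 0)) {
    stop("residue numbers must be strictly increasing", call. = FALSE)
  }
  plddt <- as.numeric(plddt)
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100)) {
    stop("plddt values must be finite and in [0, 100]", call. = FALSE)
  }
  out <- tibble::tibble(resno = resno, aa = as.character(aa),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        plddt = plddt)
  attr(out, "model_id") <- as.character(model_id)
  attr(out, "target_id") <- as.character(target_id)
  attr(out, "chain_id") <- as.character(chain_id)
  attr(out, "source_tag") <- as.character(source_tag)
  class(out) <- c("structure_model", class(out))
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (target %s, chain %s, source %s): %d residues, mean pLDDT %.2f\n",
              model_id(x), target_id(x), attr(x, "chain_id"),
              source_tag(x), nrow(x), mean(x$plddt)))
  NextMethod()
}

#' Model metadata accessors
#'
#' @param model A `structure_model`.
#' @return A single character string (`model_id`, `target_id`, `source_tag`)
#'   or an N x 3 numeric matrix of CA coordinates (`ca_coords`).
#' @export
model_id <- function(model) attr(model, "model_id")

#' @rdname model_id
#' @export
target_id <- function(model) attr(model, "target_id")

#' @rdname model_id
#' @export
source_tag <- function(model) attr(model, "source_tag")

#' @rdname model_id
#' @export
ca_coords <- function(model) {
  m <- cbind(model$x, model$y, model$z)
  rownames(m) <- model$resno
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace a model's identity metadata
#'
#' @param model A [structure_model()].
#' @param model_id,source_tag,target_id New values; `NULL` leaves a field
#'   unchanged.
#' @return The model with updated attributes.
#' @export
set_model_meta <- function(model, model_id = NULL, source_tag = NULL,
                           target_id = NULL) {
  if (!is.null(model_id)) attr(model, "model_id") <- model_id
  if (!is.null(source_tag)) attr(model, "source_tag") <- source_tag
  if (!is.null(target_id)) attr(model, "target_id") <- target_id
  model
}

#' Read a CA-level structural model from a PDB file
#'
#' Parses ATOM records (via [bio3d::read.pdb()]), keeps one CA atom per
#' residue of the requested chain, and reads per-residue confidence from the
#' B-factor column (columns 61--66), the convention AlphaFold-family
#' predictors use for pLDDT. Residues without a CA atom are skipped with a
#' warning; the first altloc is kept; files with insertion codes are
#' rejected. Three-letter residue names are mapped to one-letter codes,
#' unknown residues to `"X"`.
#'
#' @param path Path to a PDB file containing ATOM records.
#' @param chain Chain identifier; default is the first chain encountered.
#' @param model_id,target_id Optional identifiers; default to the file stem.
#' @param source_tag Provenance tag stored on the model.
#' @return A [structure_model()].
#' @export
read_model <- function(path, chain = NULL, model_id = NULL, target_id = NULL,
                       source_tag = "default") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path, call. = FALSE)
  chains <- unique(atoms$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found in %s (chains present: %s)",
                 chain, path, paste(chains, collapse = ", ")), call. = FALSE)
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (any(!is.na(atoms$insert) & atoms$insert != "")) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  # first altloc only
  alt <- atoms$alt
  keep_alt <- is.na(alt) | alt == "" | alt == "A"
  atoms <- atoms[keep_alt, , drop = FALSE]
  all_res <- unique(atoms$resno)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0) {
    warning(sprintf("skipping %d residue(s) without a CA atom in chain %s: %s",
                    length(missing_ca), chain,
                    paste(utils::head(missing_ca, 5), collapse = ", ")),
            call. = FALSE)
  }
  if (nrow(ca) == 0) stop("no CA atoms for chain ", chain, call. = FALSE)
  ca <- ca[order(ca$resno), , drop = FALSE]
  stem <- sub("\\.[^.]*$", "", basename(path))
  structure_model(
    resno = ca$resno,
    aa = suppressWarnings(bio3d::aa321(ca$resid)),
    coords = cbind(ca$x, ca$y, ca$z),
    plddt = ca$b,
    model_id = model_id %||% stem,
    target_id = target_id %||% stem,
    chain_id = chain,
    source_tag = source_tag
  )
}

#' Write a structural model to a PDB file
#'
#' Emits one fixed-width CA ATOM record per residue, with the per-residue
#' confidence in the B-factor column. Round-tripping through [read_model()]
#' reproduces sequence, residue numbers, coordinates (to 3 decimals) and
#' confidence (to 2 decimals), the precision of the fixed-width format.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model) == 0) stop("cannot write an empty model", call. = FALSE)
  xyz <- as.numeric(t(ca_coords(model)))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = model$resno,
    resid = bio3d::aa123(model$aa),
    chain = attr(model, "chain_id") %||% "A",
    elety = rep("CA", nrow(model)),
    b = model$plddt
  )
  invisible(path)
}

#' Global pLDDT of a model
#'
#' The arithmetic mean of the per-residue confidence values, the global
#' self-estimated quality score used throughout model ranking.
#'
#' @param model A [structure_model()] with at least one residue.
#' @return A number in \[0, 100\].
#' @export
global_plddt <- function(model) {
  if (nrow(model) == 0) stop("model has no residues", call. = FALSE)
  mean(model$plddt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
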