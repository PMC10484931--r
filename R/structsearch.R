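#' Parse a structure-search hit table
#'
#' Reads tab-separated structure-search output (Foldseek-style) into a
#' validated hit tibble. The default dialect maps columns positionally as
#' `query, target, evalue, alntmscore, qstart, qend, tstart, tend, qaln,
#' taln`; a custom dialect (named integer vector of column positions for
#' those keys) can be supplied because tabular search output is
#' configurable. Rows violating the hit invariants --- equal alignment
#' string lengths, no all-gap columns, non-gap counts consistent with the
#' interval coordinates, non-negative e-value --- are rejected with a
#' per-row warning and reported in the `rejected` attribute.
#'
#' @param path Path to a TSV file (no header). An empty file yields an
#'   empty hit table.
#' @param dialect Named integer vector mapping the keys `query_id, hit_id,
#'   evalue, tm, qstart, qend, tstart, tend, qaln, taln` to column
#'   positions; defaults to positions 1--10 in that order.
#' @return A tibble of class `structure_hits` with those ten columns.
#' @export
parse_hits <- function(path, dialect = NULL) {
  keys <- c("query_id", "hit_id", "evalue", "tm",
            "qstart", "qend", "tstart", "tend", "qaln", "taln")
  dialect <- dialect %||% stats::setNames(seq_along(keys), keys)
  unknown <- setdiff(names(dialect), keys)
  if (length(unknown) > 0) {
    stop("unknown dialect key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(keys %in% names(dialect))) {
    stop("dialect must map all of: ", paste(keys, collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(query_id = character(), hit_id = character(),
                          evalue = numeric(), tm = numeric(),
                          qstart = integer(), qend = integer(),
                          tstart = integer(), tend = integer(),
                          qaln = character(), taln = character())
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) return(structure_hits(empty))
  num <- function(x) suppressWarnings(as.numeric(x))
  hits <- tibble::tibble(
    query_id = as.character(raw[[dialect[["query_id"]]]]),
    hit_id = as.character(raw[[dialect[["hit_id"]]]]),
    evalue = num(raw[[dialect[["evalue"]]]]),
    tm = num(raw[[dialect[["tm"]]]]),
    qstart = as.integer(num(raw[[dialect[["qstart"]]]])),
    qend = as.integer(num(raw[[dialect[["qend"]]]])),
    tstart = as.integer(num(raw[[dialect[["tstart"]]]])),
    tend = as.integer(num(raw[[dialect[["tend"]]]])),
    qaln = as.character(raw[[dialect[["qaln"]]]]),
    taln = as.character(raw[[dialect[["taln"]]]])
  )
  reasons <- purrr::map_chr(seq_len(nrow(hits)), function(i) hit_violation(hits[i, ]))
  bad <- reasons != ""
  if (any(bad)) {
    warning(sprintf("rejected %d hit row(s): %s", sum(bad),
                    paste(sprintf("row %d (%s)", which(bad), reasons[bad]),
                          collapse = "; ")), call. = FALSE)
  }
  out <- structure_hits(hits[!bad, , drop = FALSE])
  attr(out, "rejected") <- tibble::tibble(row = which(bad), reason = reasons[bad])
  out
}

structure_hits <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("structure_hits", setdiff(class(tbl), "structure_hits"))
  tbl
}

# "" if the row satisfies the StructureHit invariants, else a reason
hit_violation <- function(h) {
  if (is.na(h$evalue) || h$evalue < 0) return("bad e-value")
  if (any(is.na(c(h$qstart, h$qend, h$tstart, h$tend)))) return("bad coordinates")
  if (is.na(h$qaln) || is.na(h$taln) || nchar(h$qaln) != nchar(h$taln)) {
    return("alignment length mismatch")
  }
  qa <- strsplit(h$qaln, "", fixed = TRUE)[[1]]
  ta <- strsplit(h$taln, "", fixed = TRUE)[[1]]
  if (any(qa == "-" & ta == "-")) return("all-gap column")
  if (sum(qa != "-") != h$qend - h$qstart + 1) return("qaln/qstart/qend inconsistent")
  if (sum(ta != "-") != h$tend - h$tstart + 1) return("taln/tstart/tend inconsistent")
  ""
}

#' Convert a structure-search hit to an A3M row
#'
#' Maps the gapped hit alignment onto the query's match columns: positions
#' outside `[qstart, qend]` and query positions aligned to a target gap
#' become `-`; aligned target letters become uppercase match states; target
#' letters opposite a query gap become lowercase insertions.
#'
#' @param hit One row of a hit table (list or single-row tibble).
#' @param query_length Number of query match columns L; `qend` must not
#'   exceed it.
#' @return A single A3M row string with exactly L match states.
#' @export
hit_to_msa_row <- function(hit, query_length) {
  if (hit$qend > query_length) {
    stop(sprintf("hit qend (%d) exceeds query length (%d)", hit$qend, query_length),
         call. = FALSE)
  }
  qa <- strsplit(hit$qaln, "", fixed = TRUE)[[1]]
  ta <- strsplit(hit$taln, "", fixed = TRUE)[[1]]
  parts <- character(length(qa))
  parts[qa != "-"] <- ifelse(ta[qa != "-"] == "-", "-", toupper(ta[qa != "-"]))
  parts[qa == "-"] <- tolower(ta[qa == "-"])
  paste0(strrep("-", hit$qstart - 1), paste(parts, collapse = ""),
         strrep("-", query_length - hit$qend))
}

#' Augment an MSA with structure-search hits
#'
#' Converts hits to alignment rows in ascending e-value order (capped at
#' `max_hits`, and dropping hits whose query side is all gaps), appends the
#' novel rows to the alignment, and applies the redundancy filter at
#' `id_threshold`. The query is always preserved. Depth can stay unchanged
#' when every incoming row is redundant with the existing alignment.
#'
#' @param x An [msa()].
#' @param hits A hit table (as from [parse_hits()]).
#' @param max_hits Cap on the number of hits converted (default 50), so a
#'   flood of near-identical hits cannot dominate the alignment.
#' @param id_threshold Redundancy threshold for [filter_redundancy()],
#'   default 0.90.
#' @return The augmented, filtered [msa()].
#' @export
augment_msa <- function(x, hits, max_hits = 50, id_threshold = 0.90) {
  stopifnot(inherits(x, "msa"))
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) return(x)
  hits <- hits[nchar(gsub("-", "", hits$qaln)) > 0, , drop = FALSE]
  if (nrow(hits) == 0) return(x)
  hits <- hits[order(hits$evalue, hits$hit_id), , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  L <- match_state_count(x$aln[1])
  rows <- tibble::tibble(
    id = hits$hit_id,
    aln = purrr::map_chr(seq_len(nrow(hits)), function(i) hit_to_msa_row(hits[i, ], L))
  )
  rows <- rows[gsub("-", "", rows$aln) != "", , drop = FALSE]
  filter_redundancy(merge_msas(x, rows), threshold = id_threshold)
}

#' Select top templates from a hit list
#'
#' Top `k` hits by ascending e-value; ties broken by descending TM-score,
#' then lexicographic hit id. Returns fewer than `k` when fewer exist.
#'
#' @param hits A hit table.
#' @param k Number of templates, default 4.
#' @return The selected rows, in rank order.
#' @export
select_templates <- function(hits, k = 4) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) return(structure_hits(hits))
  tm <- ifelse(is.na(hits$tm), -Inf, hits$tm)
  ord <- order(hits$evalue, -tm, hits$hit_id)
  structure_hits(utils::head(hits[ord, , drop = FALSE], k))
}

#' Curate a template database
#'
#' Applies the template-database construction filters: drop structures with
#' resolution above 8 Angstrom, drop chains shorter than 30 residues, then a
#' greedy redundancy pass in input order dropping any record with strictly
#' more than 90% sequence identity to an already-kept record. Identity is
#' computed by global alignment with free end gaps, normalised by the
#' shorter sequence. A missing resolution (`NA`, as for predicted
#' structures) passes the resolution filter, which targets experimental
#' quality.
#'
#' @param records A tibble/data frame with columns `template_id`,
#'   `sequence`, `resolution` (numeric, `NA` allowed), `length`.
#' @param max_resolution Resolution cutoff in Angstrom (default 8; strictly
#'   greater is removed).
#' @param min_length Minimum chain length (default 30; shorter is removed).
#' @param id_threshold Redundancy cutoff (default 0.90; strictly greater is
#'   removed).
#' @return The kept records, with a `removed` attribute recording ids and
#'   reasons.
#' @export
curate_templates <- function(records, max_resolution = 8, min_length = 30,
                             id_threshold = 0.90) {
  records <- tibble::as_tibble(records)
  removed <- tibble::tibble(template_id = character(), reason = character())
  res <- suppressWarnings(as.numeric(records$resolution))
  bad_res <- !is.na(res) & res > max_resolution
  bad_len <- records$length < min_length
  removed <- dplyr::bind_rows(
    removed,
    tibble::tibble(template_id = records$template_id[bad_res],
                   reason = "resolution"),
    tibble::tibble(template_id = records$template_id[bad_len & !bad_res],
                   reason = "length")
  )
  records <- records[!(bad_res | bad_len), , drop = FALSE]
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    kept_seqs <- records$sequence[keep]
    ident <- vapply(kept_seqs, function(s) {
      global_identity(records$sequence[i], s)
    }, numeric(1))
    keep[i] <- all(ident <= id_threshold)
    if (!keep[i]) {
      removed <- dplyr::bind_rows(removed,
        tibble::tibble(template_id = records$template_id[i], reason = "redundancy"))
    }
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

# global free-end-gap alignment identity over the shorter sequence
global_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  alphabet <- unique(c(strsplit(paste0(a, b), "", fixed = TRUE)[[1]], "X"))
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 2
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Read / write template metadata tables
#'
#' @param path TSV path with header columns `template_id`, `sequence`,
#'   `resolution`, `length` (and optionally `source`).
#' @param records Template record tibble.
#' @return `read_templates()` returns a tibble; `write_templates()` returns
#'   `path` invisibly.
#' @export
read_templates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    template_id = "c", sequence = "c", resolution = "d", length = "i",
    .default = "c"), progress = FALSE)
}

#' @rdname read_templates
#' @export
write_templates <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
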