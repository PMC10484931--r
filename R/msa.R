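#' Construct a query-anchored alignment (A3M dialect)
#'
#' An `msa` is a tibble with columns `id` and `aln`; row 1 is the query.
#' Uppercase letters and `-` are match states; lowercase letters are
#' insertions relative to the query. Every row must carry exactly the
#' query's number of match states, and the query itself contains neither
#' gaps nor insertions. Plain FASTA alignments (no lowercase, uniform
#' length) are a degenerate A3M and are accepted as-is.
#'
#' @param ids Character vector of row ids (query first).
#' @param alns Character vector of aligned strings, same length.
#' @return A tibble of class `msa`.
#' @export
msa <- function(ids, alns) {
  if (length(ids) != length(alns) || length(ids) < 1) {
    stop("ids and alns must be non-empty and of equal length", call. = FALSE)
  }
  alns <- as.character(alns)
  q <- alns[1]
  if (grepl("[a-z-]", q)) {
    stop("query row must contain no gaps and no lowercase insertions", call. = FALSE)
  }
  L <- nchar(q)
  mc <- match_state_count(alns)
  bad <- which(mc != L)
  if (length(bad) > 0) {
    stop(sprintf("row(s) %s have %s match states; query has %d",
                 paste(bad, collapse = ", "),
                 paste(unique(mc[bad]), collapse = ", "), L), call. = FALSE)
  }
  out <- tibble::tibble(id = as.character(ids), aln = alns)
  class(out) <- c("msa", class(out))
  out
}

match_state_count <- function(alns) nchar(gsub("[a-z]", "", alns))

# match-state string: insertions removed, uppercase + '-' kept
match_states <- function(alns) gsub("[a-z]", "", alns)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> query %s: depth %d, %d match columns\n",
              x$id[1], nrow(x), nchar(match_states(x$aln[1]))))
  NextMethod()
}

#' Read / write alignments in A3M (or FASTA) format
#'
#' `read_a3m()` parses a FASTA-shaped file into an [msa()]; rows whose
#' match-state count disagrees with the query's raise a format error.
#' `write_a3m()` writes one header and one unwrapped sequence line per row,
#' so a round trip reproduces the alignment text modulo line wrapping.
#'
#' @param path File path.
#' @param x An [msa()].
#' @return `read_a3m()` returns an [msa()]; `write_a3m()` returns `path`
#'   invisibly.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("no sequences in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  msa(ids, as.character(recs))
}

#' @rdname read_a3m
#' @export
write_a3m <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  writeLines(paste0(">", x$id, "\n", x$aln, collapse = "\n"), path, sep = "\n")
  invisible(path)
}

#' Pairwise sequence identity between two aligned rows
#'
#' Identity is computed on match states only (insertions are ignored): the
#' number of match columns where both rows carry the same uppercase letter,
#' divided by the smaller of the two rows' uppercase counts. This mirrors
#' the `-id` normalisation of the standard MSA filtering tool. Rows with no
#' uppercase at all have identity 0.
#'
#' @param a,b Aligned A3M rows with the same number of match states.
#' @return A number in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  ma <- match_states(a)
  mb <- match_states(b)
  if (nchar(ma) != nchar(mb)) {
    stop("rows have different match-state counts", call. = FALSE)
  }
  va <- strsplit(ma, "", fixed = TRUE)[[1]]
  vb <- strsplit(mb, "", fixed = TRUE)[[1]]
  na <- sum(va != "-")
  nb <- sum(vb != "-")
  if (na == 0 || nb == 0) return(0)
  sum(va == vb & va != "-") / min(na, nb)
}

# all-vs-all identity matrix over the match-state rows of an msa
identity_matrix <- function(x) {
  ms <- match_states(x$aln)
  chars <- do.call(rbind, strsplit(ms, "", fixed = TRUE))
  up <- chars != "-"
  n <- nrow(chars)
  counts <- rowSums(up)
  out <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        denom <- min(counts[i], counts[j])
        out[i, j] <- out[j, i] <- if (denom == 0) 0 else
          sum(chars[i, ] == chars[j, ] & up[i, ] & up[j, ]) / denom
      }
    }
  }
  out
}

#' Remove redundant alignment rows
#'
#' Greedy scan in row order: the query is always kept; a later row is
#' dropped iff its identity to some already-kept row is strictly greater
#' than `threshold` (a row at exactly the threshold survives). This is the
#' 90% redundancy filter applied after structure-hit augmentation.
#'
#' @param x An [msa()].
#' @param threshold Identity threshold, default 0.90.
#' @return The filtered [msa()].
#' @export
filter_redundancy <- function(x, threshold = 0.90) {
  stopifnot(inherits(x, "msa"))
  n <- nrow(x)
  if (n <= 1) return(x)
  idm <- identity_matrix(x)
  keep <- logical(n)
  keep[1] <- TRUE
  for (i in 2:n) {
    keep[i] <- all(idm[i, keep] <= threshold)
  }
  msa(x$id[keep], x$aln[keep])
}

#' Alignment depth
#'
#' The raw number of rows, query included. Depth gates the sampling plan:
#' the deep-search MSAs are reserved for targets whose default alignment
#' stays at or below 200 rows.
#'
#' @param x An [msa()].
#' @return An integer >= 1.
#' @export
msa_depth <- function(x) {
  stopifnot(inherits(x, "msa"))
  nrow(x)
}

#' Number of effective sequences (Neff)
#'
#' `Neff = sum_i 1 / n_i`, where `n_i` counts the rows (including row i
#' itself) whose pairwise identity to row i is at least `cluster_threshold`.
#' A single-sequence alignment has Neff 1; fully dissimilar rows each count
#' as one effective sequence. The definition is an inverse-cluster-size sum
#' without length normalisation; any monotone variant preserves the
#' log-Neff ordering this statistic is used for.
#'
#' @param x An [msa()].
#' @param cluster_threshold Identity threshold defining a cluster
#'   neighbourhood, default 0.80.
#' @return A number with `1 <= neff <= msa_depth(x)`.
#' @export
neff <- function(x, cluster_threshold = 0.80) {
  stopifnot(inherits(x, "msa"))
  idm <- identity_matrix(x)
  n_i <- rowSums(idm >= cluster_threshold)
  sum(1 / n_i)
}

#' Append rows to an alignment
#'
#' Base rows come first; extra rows are appended in order, skipping any row
#' whose aligned string exactly equals a row already present. The query is
#' unchanged. Extra rows must carry the base alignment's match-state count.
#'
#' @param base An [msa()].
#' @param extra_rows A tibble/data frame with columns `id` and `aln`, or an
#'   [msa()] whose non-query rows are taken.
#' @return The merged [msa()].
#' @export
merge_msas <- function(base, extra_rows) {
  stopifnot(inherits(base, "msa"))
  if (inherits(extra_rows, "msa")) extra_rows <- extra_rows[-1, ]
  extra_rows <- tibble::as_tibble(extra_rows)
  if (nrow(extra_rows) == 0) return(base)
  L <- match_state_count(base$aln[1])
  mc <- match_state_count(extra_rows$aln)
  if (any(mc != L)) {
    stop("extra rows must have the query's match-state count (", L, ")", call. = FALSE)
  }
  seen <- base$aln
  keep <- !duplicated(extra_rows$aln) & !(extra_rows$aln %in% seen)
  msa(c(base$id, extra_rows$id[keep]), c(base$aln, extra_rows$aln[keep]))
}
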