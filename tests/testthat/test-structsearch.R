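hit_row <- function(qaln = "ACD", taln = "AKD", qstart = 2, qend = 4,
                    tstart = 1, tend = 3, evalue = 1e-5, tm = NA_real_,
                    hit_id = "h1") {
  tibble::tibble(query_id = "q", hit_id = hit_id, evalue = evalue, tm = tm,
                 qstart = qstart, qend = qend, tstart = tstart, tend = tend,
                 qaln = qaln, taln = taln)
}

test_that("hit tables parse positionally and reject invariant violations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q\th1\t1e-10\t0.9\t2\t4\t1\t3\tACD\tAKD",
    "q\th2\t1e-08\t0.7\t1\t3\t1\t3\tACD\tA-D",   # taln nongap 2 != 3 -> reject
    "q\th3\t1e-06\t0.8\t1\t3\t2\t5\tAC-D\tACWD"  # qaln nongap 3 ok with qend 3
  ), f)
  expect_warning(hits <- parse_hits(f), "rejected 1 hit row")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$hit_id, c("h1", "h3"))
  expect_equal(attr(hits, "rejected")$row, 2L)
  expect_equal(hits$qstart[1], 2L)
  expect_equal(hits$tm[1], 0.9)
})

test_that("empty hit files and custom dialects are supported", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(parse_hits(f)), 0)
  # reversed column order via dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("AKD\tACD\t3\t1\t4\t2\t0.9\t1e-10\th1\tq", f2)
  dial <- c(taln = 1L, qaln = 2L, tend = 3L, tstart = 4L, qend = 5L,
            qstart = 6L, tm = 7L, evalue = 8L, hit_id = 9L, query_id = 10L)
  hits <- parse_hits(f2, dialect = dial)
  expect_equal(hits$qaln, "ACD")
  expect_equal(hits$evalue, 1e-10)
  expect_error(parse_hits(f2, dialect = c(dial, bogus = 11L)), "unknown dialect key")
})

test_that("hit-to-row conversion follows the match/insertion mapping rule", {
  expect_equal(hit_to_msa_row(hit_row(), 5), "-AKD-")
  expect_equal(hit_to_msa_row(hit_row(qaln = "A-C", taln = "AWC", qstart = 1,
                                      qend = 2, tend = 3), 3), "AwC-")
  expect_equal(hit_to_msa_row(hit_row(qaln = "ACD", taln = "A-D", qstart = 1,
                                      qend = 3, tend = 2), 3), "A-D")
  expect_error(hit_to_msa_row(hit_row(qend = 7), 5), "exceeds query length")
  # property: always exactly L match states
  for (L in c(5, 8, 12)) {
    row <- hit_to_msa_row(hit_row(qaln = "AC-D", taln = "ACWD", qend = 4,
                                  tend = 4), L)
    expect_equal(nchar(gsub("[a-z]", "", row)), L)
  }
})

test_that("augmentation adds novel rows, filters redundancy and preserves the query", {
  base <- msa(c("q", "r1"), c("ACDEFGHIKL", "ACDEFGHIKT"))
  expect_identical(augment_msa(base, hit_row()[0, ]), base)
  # hit identical to the query is removed by the 90% filter
  self_hit <- hit_row(qaln = "ACDEFGHIKL", taln = "ACDEFGHIKL", qstart = 1,
                      qend = 10, tend = 10)
  expect_equal(msa_depth(augment_msa(base, self_hit)), 2)
  # three mutually novel hits extend depth by 3
  h <- dplyr::bind_rows(
    hit_row(qaln = "ACDEFGHIKL", taln = "TTTTTGHIKL", qstart = 1, qend = 10,
            tend = 10, hit_id = "n1", evalue = 1e-9),
    hit_row(qaln = "ACDEFGHIKL", taln = "ACDEFTTTTT", qstart = 1, qend = 10,
            tend = 10, hit_id = "n2", evalue = 1e-8),
    hit_row(qaln = "ACDEFGHIKL", taln = "WWWWWWWWWW", qstart = 1, qend = 10,
            tend = 10, hit_id = "n3", evalue = 1e-7))
  out <- augment_msa(base, h)
  expect_equal(msa_depth(out), 5)
  expect_equal(out$id[1], "q")
  # audit: no non-query pair above the threshold
  n <- nrow(out)
  for (i in 2:(n - 1)) for (j in (i + 1):n) {
    expect_lte(pairwise_identity(out$aln[i], out$aln[j]), 0.9)
  }
  # max_hits caps the converted hits
  capped <- augment_msa(base, h, max_hits = 1)
  expect_equal(msa_depth(capped), 3)
  expect_true("n1" %in% capped$id) # lowest e-value wins the cap
  # augment-then-filter is idempotent for the same inputs
  expect_identical(augment_msa(out, h), out)
})

test_that("template selection ranks by e-value with tm/id tie-breaks", {
  h <- dplyr::bind_rows(
    hit_row(hit_id = "b", evalue = 1e-5, tm = 0.7),
    hit_row(hit_id = "a", evalue = 1e-5, tm = 0.9),
    hit_row(hit_id = "c", evalue = 1e-7, tm = 0.5))
  sel <- select_templates(h, k = 2)
  expect_equal(sel$hit_id, c("c", "a"))
  expect_equal(select_templates(h, k = 10)$hit_id, c("c", "a", "b"))
  expect_equal(nrow(select_templates(h[0, ], k = 4)), 0)
  # equal e-value and tm: lexicographic id decides
  h2 <- dplyr::bind_rows(hit_row(hit_id = "z", evalue = 1, tm = 0.5),
                         hit_row(hit_id = "y", evalue = 1, tm = 0.5))
  expect_equal(select_templates(h2, k = 1)$hit_id, "y")
})

test_that("template curation applies the three construction filters", {
  seq_a <- strrep("ACDEFGHIKL", 4)  # 40 residues
  seq_b <- paste0(substr(seq_a, 1, 38), "WW") # 95% identical to seq_a
  seq_c <- chartr("ACDEFGHIKL", "LKIHGFEDCA", seq_a) # dissimilar
  recs <- tibble::tibble(
    template_id = c("t_res", "t_short", "t_keep30", "t_a", "t_dup", "t_c", "t_na"),
    sequence = c(seq_a, substr(seq_a, 1, 29), strrep("NQS", 10),
                 seq_a, seq_b, seq_c, paste0(substr(seq_c, 1, 20), strrep("W", 20))),
    resolution = c(9.0, 2.0, 2.0, 2.0, 2.0, 2.0, NA),
    length = c(40L, 29L, 30L, 40L, 40L, 40L, 40L),
    source = c(rep("experimental", 6), "predicted"))
  out <- curate_templates(recs)
  expect_equal(out$template_id, c("t_keep30", "t_a", "t_c", "t_na"))
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$template_id == "t_res"], "resolution")
  expect_equal(removed$reason[removed$template_id == "t_short"], "length")
  expect_equal(removed$reason[removed$template_id == "t_dup"], "redundancy")
  # boundary: exactly 90% identity is kept; resolution exactly 8 is kept
  seq_d <- paste0(substr(seq_a, 1, 36), "WWWW") # 36/40 = 90%
  recs2 <- tibble::tibble(template_id = c("x", "y", "z"),
                          sequence = c(seq_a, seq_d, seq_a),
                          resolution = c(8.0, 2.0, 2.0),
                          length = c(40L, 40L, 40L))
  out2 <- curate_templates(recs2)
  expect_true(all(c("x", "y") %in% out2$template_id))
  expect_false("z" %in% out2$template_id) # identical to kept x
})

test_that("curation output re-audits clean against all three filters", {
  out <- curate_templates(tibble::tibble(
    template_id = paste0("t", 1:6),
    sequence = c(strrep("AC", 20), strrep("AC", 20), strrep("DE", 20),
                 strrep("KL", 16), strrep("WY", 20), strrep("AC", 14)),
    resolution = c(2, 3, 8.5, NA, 1.5, 2),
    length = c(40L, 40L, 40L, 32L, 40L, 28L)))
  expect_true(all(is.na(out$resolution) | out$resolution <= 8))
  expect_true(all(out$length >= 30))
  n <- nrow(out)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      id <- foldrank:::global_identity(out$sequence[i], out$sequence[j])
      expect_lte(id, 0.9)
    }
  }
})
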