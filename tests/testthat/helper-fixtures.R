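# shared toy builders for the test suite

toy_model <- function(resno = 1:4, plddt = rep(90, length(resno)),
                      coords = NULL, id = "m", target = "T", tag = "default") {
  n <- length(resno)
  coords <- coords %||% cbind(seq_len(n), (seq_len(n))^2 / 10, sin(seq_len(n)))
  foldrank::structure_model(resno, rep("A", n), coords, plddt,
                            model_id = id, target_id = target, source_tag = tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pdb_text <- function(path, lines) {
  writeLines(lines, path)
  path
}

# hand-built fixed-width ATOM record (wwPDB columns)
atom_line <- function(serial, elety, resid, chain, resno, x, y, z, b = 90,
                      alt = " ", insert = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
          serial, paste0(" ", elety), alt, resid, chain, resno, insert,
          x, y, z, 1.00, b, substr(elety, 1, 1))
}

toy_msa <- function() {
  foldrank::msa(c("q", "r1", "r2"),
                c("ACDEF", "ACDEG", "AC-EF"))
}
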