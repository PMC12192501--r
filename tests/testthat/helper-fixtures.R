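## fixture builders: everything is generated in code at test time

writeToyFasta <- function(entries, file = tempfile(fileext = ".fasta"),
                          gz = FALSE) {
  con <- if (gz) gzfile(file, "wt") else file(file, "wt")
  if (length(entries))
    writeLines(paste0(">", names(entries), "\n", unname(entries)), con)
  close(con)
  file
}

## minimal UniProt flat-file entry
uniprotEntry <- function(id, seq, os = NULL, ox = NULL) {
  lines <- sprintf("ID   %s               Unreviewed;        %d AA.",
                   id, nchar(seq))
  lines <- c(lines, sprintf("AC   %s;", id))
  if (!is.null(os)) lines <- c(lines, sprintf("OS   %s.", os))
  if (!is.null(ox)) lines <- c(lines, sprintf("OX   NCBI_TaxID=%s;", ox))
  chunks <- substring(seq, seq(1, nchar(seq), 60), # nolint
                      pmin(seq(1, nchar(seq), 60) + 59, nchar(seq)))
  c(lines,
    sprintf("SQ   SEQUENCE   %d AA;  0 MW;  0 CRC64;", nchar(seq)),
    paste0("     ", chunks), "//")
}

writeUniprot <- function(entryLines, file = tempfile(fileext = ".dat"),
                         gz = FALSE) {
  con <- if (gz) gzfile(file, "wt") else file(file, "wt")
  writeLines(unlist(entryLines), con)
  close(con)
  file
}

## independent Hurwitz zeta oracle: direct series summation with the
## analytic integral tail of the remainder
hurwitzZetaSeries <- function(s, a, N = 1e6) {
  k <- 0:(N - 1)
  q <- a + N
  sum((a + k)^(-s)) + q^(1 - s) / (s - 1) + q^(-s) / 2
}
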