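#' Number of distinct symbols in a string
#'
#' The unique alphabet of a component: how many distinguishable symbols
#' actually occur in it. Case is treated as formatting, not content, so
#' input is uppercased first; non-standard residue codes (B, Z, X, U, O)
#' are retained as distinguishable symbols, since Hartley information needs
#' only distinguishability.
#'
#' @param x Character vector of non-empty strings.
#' @return Integer vector of distinct-symbol counts.
#' @examples
#' alphabetSize(c("ABAB", "AAAA")) # 2, 1
#' @export
alphabetSize <- function(x) {
  if (length(x) == 0L) return(integer(0))
  if (any(is.na(x)) || any(!nzchar(x))) stop("strings must be non-empty")
  vapply(strsplit(toupper(x), "", fixed = TRUE),
         function(s) length(unique(s)), integer(1))
}

## normalise sequences and assemble the standard record frame
.makeRecords <- function(ids, seqs, groups, kind) {
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  keep <- nzchar(seqs)
  if (any(!keep)) {
    warning(sprintf("skipped %d record(s) with empty sequence", sum(!keep)))
    ids <- ids[keep]; seqs <- seqs[keep]; groups <- groups[keep]
  }
  if (length(seqs) == 0L)
    return(data.frame(component_id = character(0), length = integer(0),
                      alphabet_size = integer(0), digest = character(0),
                      group_key = character(0), kind = character(0),
                      stringsAsFactors = FALSE))
  data.frame(component_id = ids, length = nchar(seqs),
             alphabet_size = alphabetSize(seqs),
             digest = seqs,   # exact content identity (collision-free)
             group_key = groups, kind = kind, stringsAsFactors = FALSE)
}

#' Read a FASTA protein file into component records
#'
#' One record per FASTA entry. Sequences are uppercased and stripped of
#' whitespace before measuring, so case conventions do not affect lengths,
#' alphabets or content identity. A `species=<label>` tag in the header
#' (the convention used by the synthetic generators) becomes the record's
#' group key; otherwise the group key is `NA`. Gzip-compressed files are
#' accepted transparently.
#'
#' @param file Path to a FASTA file (optionally `.gz`).
#' @return A data frame of component records with columns `component_id`,
#'   `length`, `alphabet_size`, `digest` (the normalised sequence itself,
#'   i.e. exact content identity), `group_key`, `kind` (`"protein"`).
#'   Entries with empty sequences are skipped with a warning.
#' @export
readFasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  ids <- names(set)
  seqs <- as.character(set)
  species <- rep(NA_character_, length(ids))
  hit <- regmatches(ids, regexpr("species=\\S+", ids))
  has <- grepl("species=", ids, fixed = TRUE)
  species[has] <- sub("^species=", "", hit)
  ids <- sub("\\s.*$", "", ids)
  .makeRecords(ids, seqs, species, "protein")
}

#' Read a UniProt/TrEMBL flat file into component records
#'
#' Parses the `ID` / `OS` / `OX` / `SQ` line types of the UniProt flat-file
#' format. The species label is the `OS` line text (continuation lines
#' concatenated, the terminal period trimmed), falling back to the `OX`
#' taxon identifier when `OS` is absent; the sequence is the `SQ` block
#' with spaces stripped. Entries with no sequence block are skipped with a
#' warning; an entry left open at end of file is a format error. Gzip input
#' is accepted.
#'
#' @param file Path to a `.dat` or `.dat.gz` flat file.
#' @param speciesFrom `"OS"` (default) or `"OX"`: which line type defines
#'   species identity for multiplicity counting.
#' @return A data frame of component records (see [readFasta()]).
#' @export
readUniprotFlat <- function(file, speciesFrom = c("OS", "OX")) {
  speciesFrom <- match.arg(speciesFrom)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  ids <- character(0); seqs <- character(0); groups <- character(0)
  id <- NULL; os <- character(0); ox <- NA_character_
  sq <- character(0); inSeq <- FALSE; open <- FALSE
  flush <- function() {
    if (length(sq) == 0L) {
      warning(sprintf("entry '%s' has no SQ block; skipped", id))
      return(invisible())
    }
    osLab <- if (length(os)) sub("\\.$", "", paste(os, collapse = " "))
             else NA_character_
    grp <- if (speciesFrom == "OS" && !is.na(osLab) && nzchar(osLab)) osLab
           else if (!is.na(ox)) ox else osLab
    ids <<- c(ids, id)
    seqs <<- c(seqs, paste(sq, collapse = ""))
    groups <<- c(groups, grp)
  }
  for (ln in lines) {
    code <- substr(ln, 1L, 2L)
    if (code == "ID") {
      id <- sub("^ID\\s+(\\S+).*$", "\\1", ln)
      os <- character(0); ox <- NA_character_; sq <- character(0)
      inSeq <- FALSE; open <- TRUE
    } else if (!open) {
      next
    } else if (code == "OS") {
      os <- c(os, trimws(substr(ln, 6L, nchar(ln))))
    } else if (code == "OX") {
      m <- regmatches(ln, regexpr("NCBI_TaxID=\\d+", ln))
      if (length(m)) ox <- sub("NCBI_TaxID=", "", m)
    } else if (code == "SQ") {
      inSeq <- TRUE
    } else if (code == "//") {
      flush()
      open <- FALSE; inSeq <- FALSE
    } else if (inSeq && code == "  ") {
      sq <- c(sq, gsub("[^A-Za-z]", "", ln))
    }
  }
  if (open) stop("truncated UniProt entry at end of file (missing '//')")
  .makeRecords(ids, seqs, groups, "protein")
}

#' Summarise a set of component records
#'
#' @param records A record data frame from [readFasta()],
#'   [readUniprotFlat()] or a generator.
#' @return List with `nRecords`, `totalLength`, `nGroupKeys` (distinct
#'   non-missing group keys).
#' @export
corpusSummary <- function(records) {
  list(nRecords = nrow(records),
       totalLength = sum(records$length),
       nGroupKeys = length(unique(records$group_key[
         !is.na(records$group_key)])))
}

#' Write component records as TSV
#'
#' @param records A record data frame.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
writeRecords <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
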