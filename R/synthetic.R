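#' Canonical length law for heterogeneous corpora
#'
#' The aggregated length distribution implied by the canonical
#' heterogeneous solution, used as the exact discrete target law of the
#' corpus generator: the probability of a component having length `l` is
#' proportional to the canonical occupancy evaluated at category value `l`
#' with slope parameter `betaTail + 1`, supported on
#' `[peakLength, maxLength]`. With this parameterisation the pdf tail falls
#' as `l^-(betaTail + 1)` and the ccdf measured by the pipeline has slope
#' `-betaTail`, while the feasibility floor at `peakLength` produces the
#' sharp unimodal peak at the onset of the support. The normalisation
#' multiplier is fixed by requiring unit occupancy at `maxLength`, which is
#' what bounds the support above.
#'
#' @param betaTail Target ccdf tail slope magnitude (`> 0`).
#' @param peakLength Smallest feasible length (location of the pdf peak).
#' @param maxLength Length at which the canonical occupancy reaches one
#'   component.
#' @return List: `lengths` (integer support), `pmf`, `prediction` (the
#'   underlying [OccupancyPrediction]).
#' @export
canonicalLengthLaw <- function(betaTail = 3.1, peakLength = 300,
                               maxLength = 45000) {
  stopifnot(betaTail > 0, peakLength >= 1, maxLength > peakLength)
  slope <- betaTail + 1
  alpha <- -.gradFloor() - slope * log(maxLength)
  pred <- canonicalProfile(peakLength:maxLength,
                           CanonicalParams(alpha, slope),
                           variant = "homogeneous")
  occ <- occupancies(pred)
  list(lengths = peakLength:maxLength, pmf = occ / sum(occ),
       prediction = pred)
}

#' Generate a heterogeneous synthetic protein corpus
#'
#' Samples component lengths by inverse-CDF from the exact discrete
#' canonical length law (see [canonicalLengthLaw()]) — not from a
#' continuous approximation, since the downstream fitters are discrete —
#' and assigns each component a unique-alphabet size drawn uniformly from
#' the feasible part of `alphabetRange` (`a <= min(length, a_hi)`).
#' Sequences, built over the 20-letter amino-acid universe so FASTA output
#' is realistic for ingest testing, are materialised only when requested;
#' each sequence contains exactly its assigned number of distinct symbols.
#' The ledger records every sampled value, so downstream measurements can
#' be checked by exact bookkeeping rather than statistics. Output is fully
#' deterministic in the seed.
#'
#' @param n Number of components.
#' @param betaTail,peakLength,maxLength Parameters of the length law.
#' @param alphabetRange Two-element integer `[a_lo, a_hi]`; `a_lo` larger
#'   than the smallest achievable length is a spec error.
#' @param seed Integer seed (required).
#' @param fastaFile Optional path (plain or `.gz`); when given, sequences
#'   are generated and written as FASTA with `species=` header tags.
#' @param species Species label for the records.
#' @return List: `records` (component record data frame; `digest` is `NA`
#'   unless sequences were materialised), `ledger` (sampled lengths and
#'   alphabets plus the generator configuration).
#' @export
genHeterogeneousCorpus <- function(n, betaTail = 3.1, peakLength = 300,
                                   maxLength = 45000,
                                   alphabetRange = c(1L, 20L), seed,
                                   fastaFile = NULL,
                                   species = "SYNTHETIC-HET") {
  stopifnot(n >= 1)
  aLo <- alphabetRange[1]; aHi <- alphabetRange[2]
  if (aLo < 1 || aHi < aLo) stop("invalid 'alphabetRange'")
  if (aLo > peakLength)
    stop(sprintf("infeasible spec: a_lo = %d exceeds the smallest achievable length %d",
                 aLo, peakLength))
  if (aHi > length(.AA20))
    stop("alphabet upper bound exceeds the 20-letter symbol universe")
  law <- canonicalLengthLaw(betaTail, peakLength, maxLength)
  cu <- cumsum(law$pmf)
  out <- .withSeed(seed, {
    lens <- law$lengths[pmin(findInterval(stats::runif(n), cu) + 1L,
                             length(cu))]
    amax <- pmin(lens, aHi)
    alphas <- as.integer(aLo + floor(stats::runif(n) * (amax - aLo + 1)))
    seqs <- NULL
    if (!is.null(fastaFile)) {
      seqs <- vapply(seq_len(n), function(i) {
        a <- alphas[i]; L <- lens[i]
        sym <- .AA20[seq_len(a)]
        s <- c(sym, sym[sample.int(a, L - a, replace = TRUE)])
        paste(s[sample.int(L)], collapse = "")
      }, character(1))
    }
    list(lens = lens, alphas = alphas, seqs = seqs)
  })
  ids <- sprintf("synhet%07d", seq_len(n))
  records <- data.frame(component_id = ids, length = out$lens,
                        alphabet_size = out$alphas,
                        digest = if (is.null(out$seqs)) NA_character_
                                 else out$seqs,
                        group_key = species, kind = "protein",
                        stringsAsFactors = FALSE)
  if (!is.null(fastaFile)) {
    con <- if (grepl("\\.gz$", fastaFile)) gzfile(fastaFile, "wt")
           else file(fastaFile, "wt")
    writeLines(paste0(">", ids, " species=", species, "\n", out$seqs), con)
    close(con)
  }
  list(records = records,
       ledger = list(lengths = out$lens, alphabets = out$alphas,
                     seed = as.integer(seed), betaTail = betaTail,
                     peakLength = peakLength, maxLength = maxLength,
                     alphabetRange = c(aLo, aHi)))
}

#' Generate a homogeneous synthetic multiplicity corpus
#'
#' Creates identical-sequence groups whose multiplicities (numbers of
#' distinct species carrying the exact sequence) follow the configured
#' law on `1..nSpecies`: `"pure-zipf"` draws `P(m) ∝ m^-slope`;
#' `"canonical-droop"` draws from the canonical homogeneous occupancy
#' profile, which droops below the pure power law in the least-populated
#' bins. Draws beyond `nSpecies` cannot occur — the law is truncated at
#' the species count, which is the resampling rule applied in bulk; the
#' truncation is recorded in the ledger. Each group's sequence is
#' replicated into that many distinct synthetic species. With
#' `nSpecies = 1` every multiplicity is 1.
#'
#' @param nGroups Number of identical-sequence groups.
#' @param slope Slope magnitude of the multiplicity law.
#' @param nSpecies Number of synthetic species (the multiplicity cap).
#' @param law `"pure-zipf"` or `"canonical-droop"`.
#' @param seqLength Length of each generated sequence.
#' @param seed Integer seed (required).
#' @param fastaFile Optional FASTA output path (`species=` header tags).
#' @return List: `records` (one row per group x species), `ledger`
#'   (per-group multiplicities, their tabulation, configuration).
#' @export
genMultiplicityFasta <- function(nGroups, slope = 1.33, nSpecies = 200,
                                 law = c("pure-zipf", "canonical-droop"),
                                 seqLength = 50, seed, fastaFile = NULL) {
  law <- match.arg(law)
  stopifnot(nGroups >= 1, nSpecies >= 1, seqLength >= 10)
  msup <- seq_len(nSpecies)
  w <- if (law == "pure-zipf") {
    msup^(-slope)
  } else {
    alpha <- -.gradFloor() - slope * log(nSpecies + 1)
    occ <- .solveOccupancyFast(-alpha - slope * log(msup))
    occ
  }
  pmf <- w / sum(w)
  out <- .withSeed(seed, {
    m <- msup[pmin(findInterval(stats::runif(nGroups), cumsum(pmf)) + 1L,
                   nSpecies)]
    speciesOf <- lapply(m, function(mi) sort(sample.int(nSpecies, mi)))
    list(m = m, speciesOf = speciesOf)
  })
  seqs <- .indexedSequences(seq_len(nGroups), seqLength)
  records <- data.frame(
    component_id = sprintf("synmul%06d_%04d",
                           rep(seq_len(nGroups), out$m),
                           unlist(out$speciesOf)),
    length = seqLength,
    alphabet_size = alphabetSize(seqs[1L]),
    digest = rep(seqs, out$m),
    group_key = sprintf("SPECIES%04d", unlist(out$speciesOf)),
    kind = "protein", stringsAsFactors = FALSE)
  records$alphabet_size <- alphabetSize(records$digest)
  if (!is.null(fastaFile)) {
    con <- if (grepl("\\.gz$", fastaFile)) gzfile(fastaFile, "wt")
           else file(fastaFile, "wt")
    writeLines(paste0(">", records$component_id, " species=",
                      records$group_key, "\n", records$digest), con)
    close(con)
  }
  tab <- table(out$m)
  list(records = records,
       ledger = list(multiplicities = out$m,
                     table = stats::setNames(as.integer(tab),
                                             names(tab)),
                     seed = as.integer(seed), slope = slope,
                     nSpecies = nSpecies, law = law,
                     truncatedAt = nSpecies))
}

## deterministic distinct sequence per group index: the index written as a
## fixed-width (7 digit) base-20 amino-acid code, so sequences are unique by
## construction, preceded by a constant filler
.indexedSequences <- function(idx, seqLength) {
  stopifnot(seqLength >= 8, all(idx < 20^7))
  width <- 7L
  pad <- paste(rep(.AA20, length.out = seqLength - width), collapse = "")
  vapply(idx, function(i) {
    d <- integer(width)
    v <- i
    for (k in width:1) { d[k] <- v %% 20L; v <- v %/% 20L }
    paste0(pad, paste(.AA20[d + 1L], collapse = ""))
  }, character(1))
}

#' Generate a corpus of lexable C-like source files
#'
#' Emits syntactically lexable function definitions whose statement bodies
#' draw identifier tokens from a `vocabSize`-word vocabulary with Zipf-law
#' probabilities of the configured slope (word of rank `r` has probability
#' proportional to `r^-slope`). The structural scaffolding (keywords,
#' punctuation, function names) is deterministic; the ledger records the
#' exact draw count of every vocabulary word, so the lexer and frequency
#' counter can be validated by exact bookkeeping. Files re-tokenize
#' deterministically and identically across runs with the same seed.
#'
#' @param nTokens Number of vocabulary draws.
#' @param vocabSize Vocabulary size `V >= 2`.
#' @param slope Zipf slope magnitude of the vocabulary law.
#' @param nFiles Number of `.c` files to spread the corpus over.
#' @param statementsPerFunction Statements per generated function body.
#' @param seed Integer seed (required).
#' @param dir Output directory (created if needed).
#' @return List: `dir`, `files`, `ledger` (named vocabulary draw counts
#'   and configuration).
#' @export
genCLikeSources <- function(nTokens, vocabSize = 5000, slope = 1.19,
                            nFiles = 20, statementsPerFunction = 100,
                            seed, dir) {
  stopifnot(vocabSize >= 2, nTokens >= 1, nFiles >= 1)
  vocab <- sprintf("v%05d", seq_len(vocabSize))
  pmf <- seq_len(vocabSize)^(-slope)
  pmf <- pmf / sum(pmf)
  idx <- .withSeed(seed,
    findInterval(stats::runif(nTokens), cumsum(pmf)) + 1L)
  idx <- pmin(idx, vocabSize)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fileOf <- rep(seq_len(nFiles), length.out = nTokens)
  files <- character(nFiles)
  for (f in seq_len(nFiles)) {
    words <- vocab[idx[fileOf == f]]
    nFun <- max(1L, ceiling(length(words) / statementsPerFunction))
    funOf <- rep(seq_len(nFun), each = statementsPerFunction,
                 length.out = length(words))
    body <- vapply(seq_len(nFun), function(k) {
      paste0("int fn_", f, "_", k, "(void)\n{\n",
             paste0("  int ", words[funOf == k], " ;\n", collapse = ""),
             "  return 0 ;\n}\n")
    }, character(1))
    files[f] <- file.path(dir, sprintf("gen%03d.c", f))
    writeLines(paste(body, collapse = "\n"), files[f])
  }
  counts <- stats::setNames(tabulate(idx, vocabSize), vocab)
  list(dir = dir, files = files,
       ledger = list(counts = counts, vocabulary = vocab,
                     seed = as.integer(seed), slope = slope,
                     vocabSize = vocabSize, nTokens = nTokens))
}
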