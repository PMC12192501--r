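## Orchestration: the four corpus demonstrations (length distributions,
## multiplicity, token frequency, scale independence), each as a function
## returning a machine-readable report that embeds its configuration, seeds
## and the package version.

.reportHeader <- function(kind, config) {
  list(kind = kind, config = config,
       package = as.character(utils::packageVersion("cohsi")))
}

.lengthsOf <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x)) return(x$length)
  if (is.character(x) && length(x) == 1L) return(readFasta(x)$length)
  stop("cannot interpret input as lengths, records or a FASTA path")
}

#' Length-distribution analysis of a heterogeneous corpus
#'
#' Builds the empirical pdf/ccdf of component lengths, runs the necessary
#' test (log-log OLS on the ccdf over the fit range) and the sufficiency
#' test (discrete power-law MLE at the lower edge of the range plus the KS
#' semiparametric bootstrap), and combines them into a verdict. The
#' sufficiency law is renormalised on the fit region up to the largest
#' observed value, so a prescribed region with a hard upper bound is
#' honoured. A corpus with fewer than three distinct lengths is reported
#' cleanly as degenerate rather than fitted.
#'
#' @param x Numeric lengths, a record data frame, or a FASTA path.
#' @param fitRange Two-element numeric region in data units (default the
#'   post-peak protein region `c(400, 20000)`).
#' @param nBoot Bootstrap replicates (default 200; raise for final
#'   reports).
#' @param seed Integer seed for the bootstrap.
#' @param outDir Optional directory: writes `ccdf.tsv`, `report.json` and
#'   a log-log `ccdf.svg` there.
#' @return Report list: configuration, distribution summary, `slope`,
#'   `adjustedR2`, `exponent`, `ksD`, `p`, `verdict`, ...
#' @export
runLengthAnalysis <- function(x, fitRange = c(400, 20000), nBoot = 200L,
                              seed = 1L, outDir = NULL) {
  values <- .lengthsOf(x)
  if (length(values) == 0L) stop("empty corpus")
  config <- list(analysis = "length", fitRange = fitRange,
                 nBoot = as.integer(nBoot), seed = as.integer(seed),
                 n = length(values))
  if (length(unique(values)) < 3L)
    return(c(.reportHeader("length", config),
             list(verdict = "degenerate",
                  note = "fewer than 3 distinct values; no fit attempted")))
  dist <- empiricalDistribution(values)
  ols <- olsLogLog(dist, range = fitRange)
  xmax <- min(fitRange[2], max(values))
  suff <- tryCatch({
    fit <- fitDiscretePowerLaw(values, xmin = fitRange[1], xmax = xmax)
    boot <- bootstrapGoF(values, fit, nBoot = nBoot, seed = seed)
    list(fit = fit, boot = boot)
  }, error = function(e) list(error = conditionMessage(e)))
  rep <- .assembleReport("length", config, ols, suff)
  if (!is.null(outDir)) .writeAnalysisFiles(outDir, dist, rep)
  rep
}

.assembleReport <- function(kind, config, ols, suff, checkRange = TRUE) {
  if (!is.null(suff$error)) {
    v <- powerLawVerdict(ols, NULL)
    return(c(.reportHeader(kind, config),
             list(slope = ols@slope, intercept = ols@intercept,
                  adjustedR2 = ols@adjustedR2, nPoints = ols@nPoints,
                  sufficiencyError = suff$error,
                  verdict = verdict(v))))
  }
  v <- if (checkRange) powerLawVerdict(ols, suff$boot)
       else .verdictNoRangeCheck(ols, suff$boot)
  c(.reportHeader(kind, config),
    list(slope = ols@slope, intercept = ols@intercept,
         adjustedR2 = ols@adjustedR2, nPoints = ols@nPoints,
         exponent = suff$fit@exponent, xmin = suff$fit@xmin,
         xmax = suff$fit@xmax, nTail = suff$fit@nTail,
         ksD = suff$fit@ksD, p = suff$boot@pValue,
         nBoot = suff$boot@nBoot, bootSeed = suff$boot@seed,
         verdict = verdict(v), annotation = v@annotation))
}

.verdictNoRangeCheck <- function(ols, boot) {
  # necessary test in rank space, sufficiency in count space: the range
  # consistency check does not apply
  if (is.na(boot@pValue)) {
    v <- "inconclusive"; note <- "bootstrap p unavailable"
  } else if (boot@pValue > 0.1) {
    v <- "power-law-not-rejected"; note <- ""
  } else {
    v <- "rejected"
    note <- "possibly out of equilibrium; not a counter-demonstration"
  }
  new("PowerLawVerdict", ols = ols, bootstrap = boot, verdict = v,
      annotation = note)
}

.writeAnalysisFiles <- function(outDir, dist, rep) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is(dist, "EmpiricalDistribution"))
    writeDistribution(dist, file.path(outDir, "ccdf.tsv"))
  writeReport(rep, file.path(outDir, "report.json"))
  tryCatch({
    grDevices::svg(file.path(outDir, "ccdf.svg"))
    plot(dist, main = rep$kind)
    grDevices::dev.off()
  }, error = function(e) invisible(NULL))
}

#' Multiplicity analysis of a homogeneous corpus
#'
#' Groups records into identical-sequence groups, tabulates multiplicities
#' (distinct species per group), fits the necessary test on group counts
#' against multiplicity (log-log), and runs the sufficiency test on the
#' per-group multiplicities with the law renormalised on the fit region up
#' to the largest observed multiplicity. A single-species corpus (all
#' multiplicities 1) is reported as degenerate.
#'
#' @param records Record data frame with `digest` and `group_key`; records
#'   with missing species labels are an error listing the offenders.
#' @param fitRange Multiplicity region (default `c(1, 8000)`).
#' @param counting `"species"` or `"record"` (see [multiplicityTable()]).
#' @inheritParams runLengthAnalysis
#' @return Report list as in [runLengthAnalysis()], plus the multiplicity
#'   table.
#' @export
runMultiplicityAnalysis <- function(records, fitRange = c(1, 8000),
                                    nBoot = 200L, seed = 1L,
                                    counting = "species", outDir = NULL) {
  if (nrow(records) == 0L) stop("empty corpus")
  if (anyNA(records$group_key))
    stop(sprintf("records missing species labels: %s",
                 paste(utils::head(records$component_id[
                   is.na(records$group_key)], 10L), collapse = ", ")))
  tab <- multiplicityTable(records, counting = counting)
  values <- groupMultiplicities(records, counting = counting)
  config <- list(analysis = "multiplicity", fitRange = fitRange,
                 nBoot = as.integer(nBoot), seed = as.integer(seed),
                 counting = counting, nRecords = nrow(records),
                 nGroups = length(values))
  if (length(unique(values)) < 3L)
    return(c(.reportHeader("multiplicity", config),
             list(table = as.data.frame(tab), verdict = "degenerate",
                  note = "fewer than 3 distinct multiplicities; no fit attempted")))
  ols <- olsLogLog(tab, range = fitRange)
  xmax <- min(fitRange[2], max(values))
  suff <- tryCatch({
    fit <- fitDiscretePowerLaw(values, xmin = fitRange[1], xmax = xmax)
    boot <- bootstrapGoF(values, fit, nBoot = nBoot, seed = seed)
    list(fit = fit, boot = boot)
  }, error = function(e) list(error = conditionMessage(e)))
  rep <- .assembleReport("multiplicity", config, ols, suff)
  rep$table <- as.data.frame(tab)
  if (!is.null(outDir)) .writeAnalysisFiles(outDir, tab, rep)
  rep
}

#' Token-frequency analysis in the classic Zipf manner
#'
#' Rank-orders corpus token frequencies, fits the necessary test on
#' frequency against rank over the configured rank region, and runs the
#' sufficiency test on the token counts themselves (cutoff chosen by
#' [selectXmin()], since the prescribed region lives in rank space while
#' the count distribution is what the discrete law models).
#'
#' @param x Token counts (named vector), token data frame(s), or a
#'   directory of C sources (see [tokenFrequencies()]).
#' @param fitRange Rank region (default `c(1, 5000)`).
#' @param vocabulary Optional character vector: restrict the analysis to
#'   these token spellings (used when validating generator recovery, where
#'   the deterministic scaffolding tokens are not part of the law).
#' @inheritParams runLengthAnalysis
#' @return Report list as in [runLengthAnalysis()].
#' @export
runTokenAnalysis <- function(x, fitRange = c(1, 5000), nBoot = 200L,
                             seed = 1L, vocabulary = NULL, outDir = NULL) {
  counts <- if (is.numeric(x) && !is.null(names(x))) x
            else tokenFrequencies(x)
  if (!is.null(vocabulary)) counts <- counts[names(counts) %in% vocabulary]
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty token corpus")
  rf <- rankFrequency(counts)
  config <- list(analysis = "token-frequency", fitRange = fitRange,
                 nBoot = as.integer(nBoot), seed = as.integer(seed),
                 nDistinctTokens = nrow(rf),
                 nTokens = sum(rf$frequency))
  if (length(unique(rf$frequency)) < 3L)
    return(c(.reportHeader("token-frequency", config),
             list(verdict = "degenerate",
                  note = "fewer than 3 distinct frequencies; no fit attempted")))
  ols <- olsLogLog(rf, range = fitRange)
  suff <- tryCatch({
    sel <- selectXmin(as.numeric(rf$frequency))
    boot <- bootstrapGoF(as.numeric(rf$frequency), sel$fit, nBoot = nBoot,
                         seed = seed)
    list(fit = sel$fit, boot = boot)
  }, error = function(e) list(error = conditionMessage(e)))
  rep <- .assembleReport("token-frequency", config, ols, suff,
                         checkRange = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rf, file.path(outDir, "rank_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeReport(rep, file.path(outDir, "report.json"))
  }
  rep
}

#' Scale-independence report across corpus versions
#'
#' Fits the configured analysis slope on each of an ordered set of corpus
#' versions and reports the slope-stability statistic (the maximum
#' pairwise absolute slope difference) together with the largest observed
#' value per version — the canonical solutions predict the normalised
#' shape to be invariant as the corpus grows, while the maximum value
#' grows with total size.
#'
#' For length comparisons the default fit region is the region jointly
#' dense in every version: from just above the common distribution onset
#' to the 95th percentile of the smallest version. Slopes compared over
#' sparsely populated abscissae are dominated by singleton noise rather
#' than by the distribution shape, so the dense region is where a
#' version-to-version slope comparison is meaningful.
#'
#' @param versions Named list of corpora (each as accepted by the
#'   per-analysis function for `kind`); at least 2.
#' @param kind `"length"`, `"multiplicity"` or `"token-frequency"`.
#' @param fitRange Fit region shared by all versions; `NULL` for the
#'   dense-region default described above.
#' @return Report list: per-version `slopes`, `maxValues`,
#'   `maxSlopeDifference`, configuration.
#' @export
runScaleIndependence <- function(versions, kind = "length",
                                 fitRange = NULL) {
  if (length(versions) < 2L)
    stop("need at least 2 corpus versions")
  if (is.null(names(versions)))
    names(versions) <- sprintf("version%02d", seq_along(versions))
  slopes <- numeric(length(versions))
  maxVal <- numeric(length(versions))
  if (kind == "length" && is.null(fitRange)) {
    allVals <- lapply(versions, .lengthsOf)
    lo <- 1.03 * max(vapply(allVals, min, numeric(1)))
    hi <- min(vapply(allVals, function(v)
      unname(stats::quantile(v, 0.95)), numeric(1)))
    if (hi <= lo) { lo <- min(unlist(allVals)); hi <- max(unlist(allVals)) }
    fitRange <- c(lo, hi)
  }
  for (i in seq_along(versions)) {
    if (kind == "length") {
      vals <- .lengthsOf(versions[[i]])
      slopes[i] <- slope(olsLogLog(empiricalDistribution(vals),
                                   range = fitRange))
      maxVal[i] <- max(vals)
    } else if (kind == "multiplicity") {
      tab <- multiplicityTable(versions[[i]])
      if (is.null(fitRange)) fitRange <- range(multiplicities(tab))
      slopes[i] <- slope(olsLogLog(tab, range = fitRange))
      maxVal[i] <- max(multiplicities(tab))
    } else {
      counts <- if (is.numeric(versions[[i]])) versions[[i]]
                else tokenFrequencies(versions[[i]])
      rf <- rankFrequency(counts)
      if (is.null(fitRange)) fitRange <- c(1, nrow(rf))
      slopes[i] <- slope(olsLogLog(rf, range = fitRange))
      maxVal[i] <- max(rf$frequency)
    }
  }
  names(slopes) <- names(versions); names(maxVal) <- names(versions)
  diffs <- abs(outer(slopes, slopes, `-`))
  c(.reportHeader("scale-independence",
                  list(kind = kind, fitRange = fitRange,
                       versions = names(versions))),
    list(slopes = slopes, maxValues = maxVal,
         maxSlopeDifference = max(diffs)))
}

#' Write a report as pretty JSON
#'
#' @param report A report list from one of the `run*` functions.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
writeReport <- function(report, file) {
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(file)
}
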