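#' Empirical pdf and ccdf of positive integer values
#'
#' Builds the probability mass function over the distinct observed values
#' and the inclusive complementary cumulative distribution
#' `ccdf(x) = P(X >= x)`. The inclusive convention keeps the maximum
#' observed value at positive ccdf, which is required for log-log plotting
#' of the extreme tail. Proportions are scale-invariant: duplicating the
#' sample leaves the result unchanged.
#'
#' @param values Non-empty vector of positive values.
#' @return An [EmpiricalDistribution].
#' @examples
#' d <- empiricalDistribution(c(1, 2, 2, 5))
#' probMass(d) # 0.25 0.50 0.25
#' ccdf(d)     # 1.00 0.75 0.25
#' @export
empiricalDistribution <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("'values' must be positive and finite")
  sup <- sort(unique(values))
  cnt <- as.numeric(tabulate(match(values, sup)))
  n <- length(values)
  pmf <- cnt / n
  cc <- rev(cumsum(rev(pmf)))
  cc[1L] <- 1  # guard rounding
  new("EmpiricalDistribution", support = as.numeric(sup), pmf = pmf,
      ccdf = cc, n = as.integer(n))
}

#' @describeIn empiricalDistribution Coerce to a data frame with columns
#'   `value`, `pdf`, `ccdf`.
#' @param x An [EmpiricalDistribution].
#' @param ... Unused.
#' @export
as.data.frame.EmpiricalDistribution <- function(x, ...) {
  data.frame(value = x@support, pdf = x@pmf, ccdf = x@ccdf)
}

#' Write an empirical distribution as TSV
#'
#' @param dist An [EmpiricalDistribution].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
writeDistribution <- function(dist, file) {
  utils::write.table(as.data.frame(dist), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Rank-frequency table in the classic Zipf manner
#'
#' Sorts item counts into descending frequency order; ties are broken by
#' lexicographic item name so rank plots are deterministic.
#'
#' @param counts Named numeric/integer vector of item counts.
#' @return Data frame with columns `rank`, `item`, `frequency`; frequency
#'   is non-increasing in rank.
#' @examples
#' rankFrequency(c(a = 2, b = 1))
#' @export
rankFrequency <- function(counts) {
  if (length(counts) == 0L) stop("'counts' must be non-empty")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  o <- order(-counts, names(counts), method = "radix")
  data.frame(rank = seq_along(counts), item = names(counts)[o],
             frequency = as.numeric(counts[o]), stringsAsFactors = FALSE)
}

#' Protein multiplicity table
#'
#' Groups records by exact sequence content (the digest) and counts, for
#' each group, the number of distinct species (group keys) in which that
#' identical sequence occurs — its multiplicity. The table then counts
#' groups per multiplicity. The same sequence occurring twice within one
#' species contributes multiplicity 1, not 2. Records with a missing group
#' key are counted under a sentinel species label and reported in a
#' warning. Instance counting (`counting = "record"`) is available for
#' sensitivity analysis.
#'
#' @param records A record data frame with `digest` and `group_key`
#'   columns.
#' @param counting `"species"` (distinct group keys, default) or
#'   `"record"` (record instances).
#' @return A [MultiplicityTable].
#' @export
multiplicityTable <- function(records, counting = c("species", "record")) {
  counting <- match.arg(counting)
  if (nrow(records) == 0L) stop("'records' must be non-empty")
  digest <- records$digest
  grp <- records$group_key
  if (anyNA(grp)) {
    warning(sprintf("%d record(s) missing group_key counted under sentinel species",
                    sum(is.na(grp))))
    grp[is.na(grp)] <- "<unknown-species>"
  }
  dt <- data.table::data.table(digest = digest, grp = grp)
  mult <- if (counting == "species") {
    dt[, list(m = data.table::uniqueN(grp)), by = "digest"]$m
  } else {
    dt[, list(m = .N), by = "digest"]$m
  }
  tab <- table(mult)
  new("MultiplicityTable",
      multiplicity = as.integer(names(tab)),
      nGroups = as.integer(tab), counting = counting)
}

#' @describeIn multiplicityTable Multiplicities of the individual
#'   identical-sequence groups (one value per group), the input to the
#'   sufficiency test.
#' @export
groupMultiplicities <- function(records,
                                counting = c("species", "record")) {
  counting <- match.arg(counting)
  grp <- records$group_key
  grp[is.na(grp)] <- "<unknown-species>"
  dt <- data.table::data.table(digest = records$digest, grp = grp)
  if (counting == "species")
    dt[, list(m = data.table::uniqueN(grp)), by = "digest"]$m
  else dt[, list(m = .N), by = "digest"]$m
}

#' @describeIn multiplicityTable Coerce to a data frame with columns
#'   `multiplicity`, `group_count`.
#' @param x A [MultiplicityTable].
#' @param ... Unused.
#' @export
as.data.frame.MultiplicityTable <- function(x, ...) {
  data.frame(multiplicity = x@multiplicity, group_count = x@nGroups)
}

#' Well-populated fit region of a counting curve
#'
#' Returns `c(1, hi)` where `hi` is the largest category whose count is at
#' least `minCount`. Log-log least squares over categories holding only a
#' handful of observations is dominated by Poisson noise rather than by
#' the distribution shape; restricting the necessary test to categories
#' with about ten or more observations keeps the relative count noise
#' below roughly 30 percent per point. At full corpus scale (hundreds of
#' millions of components) this reproduces fit regions like multiplicities
#' 1–8000; at desk scale it adapts to the synthetic corpus size.
#'
#' @param x A [MultiplicityTable] or a rank-frequency data frame from
#'   [rankFrequency()].
#' @param minCount Minimum count per retained category (default 10).
#' @return Two-element numeric fit range.
#' @export
populatedRange <- function(x, minCount = 10) {
  if (is(x, "MultiplicityTable")) {
    keep <- x@nGroups >= minCount
    if (!any(keep)) stop("no category reaches 'minCount'")
    return(c(1, max(x@multiplicity[keep])))
  }
  if (is.data.frame(x) && all(c("rank", "frequency") %in% names(x))) {
    keep <- x$frequency >= minCount
    if (!any(keep)) stop("no rank reaches 'minCount'")
    return(c(1, max(x$rank[keep])))
  }
  stop("'x' must be a MultiplicityTable or rank-frequency data frame")
}

#' Plot methods for log-log renderings
#'
#' `plot` on an [EmpiricalDistribution] draws the ccdf on log-log axes;
#' on a [MultiplicityTable] it draws group counts against multiplicity on
#' log-log axes.
#'
#' @param x The object to plot.
#' @param y Unused.
#' @param ... Passed to [graphics::plot()].
#' @name plot-methods
NULL

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "EmpiricalDistribution", y = "missing"),
          function(x, y, ...) {
  graphics::plot(x@support, x@ccdf, log = "xy", xlab = "value",
                 ylab = "P(X >= x)", ...)
})

#' @rdname plot-methods
#' @export
setMethod("plot", signature(x = "MultiplicityTable", y = "missing"),
          function(x, y, ...) {
  keep <- x@nGroups > 0L
  graphics::plot(x@multiplicity[keep], x@nGroups[keep], log = "xy",
                 xlab = "multiplicity", ylab = "number of groups", ...)
})
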