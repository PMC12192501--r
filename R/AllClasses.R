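#' @import methods
NULL

#' Lagrange multipliers of a canonical solution
#'
#' Holds the pair of multipliers of the constrained variational problem:
#' `alpha` enforces the fixed total size and acts purely as a normalisation,
#' `beta` enforces the fixed total Hartley-Shannon information and equals
#' the magnitude of the power-law slope of the resulting occupancies. Both
#' are dimensionless. Observed power-law systems have `beta` below about 4;
#' that is advisory and not enforced, but `beta < 0` is rejected since the
#' solutions treated here all have non-negative slope magnitude.
#'
#' @slot alpha Numeric scalar, normalisation multiplier.
#' @slot beta Numeric scalar `>= 0`, information multiplier.
#' @export
setClass("CanonicalParams",
         representation(alpha = "numeric", beta = "numeric"))

setValidity("CanonicalParams", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha))
    return("'alpha' must be a finite scalar")
  if (length(object@beta) != 1L || !is.finite(object@beta))
    return("'beta' must be a finite scalar")
  if (object@beta < 0)
    return("'beta' must be >= 0 for the canonical solutions handled here")
  TRUE
})

#' @describeIn CanonicalParams Constructor.
#' @param alpha,beta Finite numeric scalars; `beta >= 0`.
#' @export
CanonicalParams <- function(alpha, beta) {
  new("CanonicalParams", alpha = as.numeric(alpha), beta = as.numeric(beta))
}

setMethod("show", "CanonicalParams", function(object) {
  cat(sprintf("CanonicalParams: alpha = %.6g, beta = %.6g\n",
              object@alpha, object@beta))
})

#' Canonical occupancy prediction
#'
#' The solution of the stationarity equation over a set of category values:
#' for each category value `x` the predicted occupancy `t(x)` solving
#' `occupancyGradient(t) = -alpha - beta ln x`, with categories whose
#' right-hand side falls below `33/78` reported as unoccupied (`t = 0`).
#' `variant` records whether the categories are unique-alphabet sizes of
#' ordered strings (`"heterogeneous"`) or rank/multiplicity classes of
#' unordered collections (`"homogeneous"`). For the heterogeneous variant a
#' feasibility clip may additionally zero categories whose predicted
#' occupancy falls below the alphabet size (a string cannot hold more
#' distinct symbols than its length).
#'
#' @slot categories Strictly positive, strictly ascending numeric vector.
#' @slot occupancies Non-negative finite numeric vector, same length.
#' @slot params A [CanonicalParams] object.
#' @slot variant `"heterogeneous"` or `"homogeneous"`.
#' @slot feasibilityClip Logical scalar; was the `a <= t` clip applied?
#' @slot total Numeric scalar, the sum of the occupancies.
#' @export
setClass("OccupancyPrediction",
         representation(categories = "numeric", occupancies = "numeric",
                        params = "CanonicalParams", variant = "character",
                        feasibilityClip = "logical", total = "numeric"))

setValidity("OccupancyPrediction", function(object) {
  k <- length(object@categories)
  if (length(object@occupancies) != k)
    return("'categories' and 'occupancies' must have the same length")
  if (k == 0L) return("prediction must have at least one category")
  if (any(object@categories <= 0) || is.unsorted(object@categories,
                                                 strictly = TRUE))
    return("'categories' must be strictly positive and strictly ascending")
  if (any(!is.finite(object@occupancies)) || any(object@occupancies < 0))
    return("'occupancies' must be finite and non-negative")
  if (!object@variant %in% c("heterogeneous", "homogeneous"))
    return("'variant' must be 'heterogeneous' or 'homogeneous'")
  if (abs(sum(object@occupancies) - object@total) >
      1e-6 * max(object@total, 1))
    return("'total' must equal the sum of the occupancies")
  TRUE
})

setMethod("show", "OccupancyPrediction", function(object) {
  occ <- sum(object@occupancies > 0)
  cat(sprintf(
    "OccupancyPrediction (%s): %d categories (%d occupied), total T = %.6g\n",
    object@variant, length(object@categories), occ, object@total))
  cat(sprintf("  alpha = %.6g, beta = %.6g%s\n", object@params@alpha,
              object@params@beta,
              if (object@feasibilityClip) ", feasibility-clipped" else ""))
})

#' Empirical distribution of positive integer values
#'
#' Probability mass and inclusive complementary cumulative distribution
#' (`ccdf(x) = P(X >= x)`) over the distinct observed values. The inclusive
#' convention guarantees the largest observed value retains positive ccdf,
#' which is what makes the extreme tail visible on log-log axes.
#'
#' @slot support Ascending positive values.
#' @slot pmf Probability mass per support value, sums to 1.
#' @slot ccdf `P(X >= x)` per support value; non-increasing, starts at 1.
#' @slot n Integer, number of observations.
#' @export
setClass("EmpiricalDistribution",
         representation(support = "numeric", pmf = "numeric",
                        ccdf = "numeric", n = "integer"))

setValidity("EmpiricalDistribution", function(object) {
  k <- length(object@support)
  if (k == 0L) return("empty distribution")
  if (length(object@pmf) != k || length(object@ccdf) != k)
    return("'support', 'pmf' and 'ccdf' must have equal lengths")
  if (any(object@support <= 0) || is.unsorted(object@support,
                                              strictly = TRUE))
    return("'support' must be positive and strictly ascending")
  if (abs(sum(object@pmf) - 1) > 1e-12)
    return("'pmf' must sum to 1 within 1e-12")
  if (any(diff(object@ccdf) > 1e-12))
    return("'ccdf' must be non-increasing")
  if (abs(object@ccdf[1] - 1) > 1e-12)
    return("'ccdf' must equal 1 at the smallest support value")
  TRUE
})

setMethod("show", "EmpiricalDistribution", function(object) {
  cat(sprintf(
    "EmpiricalDistribution: %d observations, %d distinct values in [%g, %g]\n",
    object@n, length(object@support), min(object@support),
    max(object@support)))
})

#' Protein multiplicity table
#'
#' Counts of identical-sequence groups by multiplicity, where the
#' multiplicity of a group is the number of distinct species (group keys) in
#' which that exact sequence occurs. Instance counting (number of records
#' rather than distinct species) is available for sensitivity analysis and
#' recorded in `counting`.
#'
#' @slot multiplicity Ascending positive integers.
#' @slot nGroups Number of identical-sequence groups at each multiplicity.
#' @slot counting `"species"` (default) or `"record"`.
#' @export
setClass("MultiplicityTable",
         representation(multiplicity = "integer", nGroups = "integer",
                        counting = "character"))

setValidity("MultiplicityTable", function(object) {
  if (length(object@multiplicity) != length(object@nGroups))
    return("'multiplicity' and 'nGroups' must have equal lengths")
  if (any(object@multiplicity <= 0L) ||
      is.unsorted(object@multiplicity, strictly = TRUE))
    return("'multiplicity' must be positive and strictly ascending")
  if (any(object@nGroups < 0L)) return("'nGroups' must be non-negative")
  if (!object@counting %in% c("species", "record"))
    return("'counting' must be 'species' or 'record'")
  TRUE
})

setMethod("show", "MultiplicityTable", function(object) {
  cat(sprintf(
    "MultiplicityTable (%s counting): %d groups, multiplicities %d..%d\n",
    object@counting, sum(object@nGroups), min(object@multiplicity),
    max(object@multiplicity)))
})

#' Log-log ordinary least squares fit (necessary test)
#'
#' @slot slope Fitted slope of `ln y` on `ln x` (the reported beta, signed).
#' @slot intercept Fitted intercept.
#' @slot adjustedR2 Adjusted R squared (standard small-sample correction).
#' @slot fitRange Two-element numeric, `[lo, hi]` in data units.
#' @slot nPoints Number of support points used.
#' @export
setClass("OLSFit",
         representation(slope = "numeric", intercept = "numeric",
                        adjustedR2 = "numeric", fitRange = "numeric",
                        nPoints = "integer"))

setValidity("OLSFit", function(object) {
  if (length(object@fitRange) != 2L || object@fitRange[2] <= object@fitRange[1])
    return("'fitRange' must be [lo, hi] with hi > lo")
  if (object@adjustedR2 > 1 + 1e-12) return("adjusted R2 cannot exceed 1")
  TRUE
})

setMethod("show", "OLSFit", function(object) {
  cat(sprintf(
    "OLSFit: slope = %.4f, intercept = %.4f, adj. R2 = %.3f (%d points in [%g, %g])\n",
    object@slope, object@intercept, object@adjustedR2, object@nPoints,
    object@fitRange[1], object@fitRange[2]))
})

#' Discrete power-law maximum-likelihood fit
#'
#' Fit of the zeta-normalised discrete power law
#' `p(x) ∝ x^(-exponent)` on `x in [xmin, xmax]` (Hurwitz-zeta normalised;
#' `xmax = Inf` for the untruncated law). `ksD` is the sup-norm distance
#' between the empirical and fitted tail CDFs.
#'
#' @slot exponent MLE of the exponent, `> 1`.
#' @slot xmin Positive integer lower cutoff.
#' @slot xmax Upper cutoff (`Inf` when untruncated).
#' @slot nTail Number of data points `>= xmin` used in the fit.
#' @slot ksD Kolmogorov-Smirnov statistic in `[0, 1]`.
#' @slot logLik Maximised log-likelihood.
#' @export
setClass("PowerLawFit",
         representation(exponent = "numeric", xmin = "numeric",
                        xmax = "numeric", nTail = "integer", ksD = "numeric",
                        logLik = "numeric"))

setValidity("PowerLawFit", function(object) {
  if (object@exponent <= 1) return("'exponent' must exceed 1")
  if (object@xmin < 1) return("'xmin' must be >= 1")
  if (object@nTail < 2L) return("'nTail' must be >= 2")
  if (object@ksD < 0 || object@ksD > 1) return("'ksD' must lie in [0, 1]")
  TRUE
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: exponent = %.4f, xmin = %g%s, n_tail = %d, KS D = %.4f\n",
    object@exponent, object@xmin,
    if (is.finite(object@xmax)) sprintf(", xmax = %g", object@xmax) else "",
    object@nTail, object@ksD))
})

#' Semiparametric bootstrap goodness-of-fit result (sufficiency test)
#'
#' `pValue` is exactly the fraction of bootstrap replicates whose KS
#' statistic is at least the observed one; a value above 0.1 means
#' power-law behaviour cannot be rejected.
#'
#' @slot pValue Bootstrap p-value in `[0, 1]`.
#' @slot nBoot Number of replicates.
#' @slot seed Integer seed that generated the replicates.
#' @slot observedKS Observed KS statistic.
#' @slot replicateKS Numeric vector of replicate KS statistics.
#' @slot fit The [PowerLawFit] the bootstrap assessed.
#' @export
setClass("BootstrapResult",
         representation(pValue = "numeric", nBoot = "integer",
                        seed = "integer", observedKS = "numeric",
                        replicateKS = "numeric", fit = "PowerLawFit"))

setValidity("BootstrapResult", function(object) {
  if (object@nBoot < 1L) return("'nBoot' must be positive")
  if (length(object@replicateKS) != object@nBoot)
    return("'replicateKS' must hold one KS value per replicate")
  if (is.finite(object@observedKS)) {
    p <- mean(object@replicateKS >= object@observedKS)
    if (abs(object@pValue - p) > 1e-15)
      return("'pValue' must equal the fraction of replicate KS >= observed")
  }
  TRUE
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: p = %.4f (%d replicates, seed %d, KS D = %.4f)\n",
              object@pValue, object@nBoot, object@seed, object@observedKS))
})

#' Joint power-law verdict
#'
#' Combines the necessary (log-log OLS) and sufficiency (bootstrap) tests
#' into one machine-readable report. A rejection is annotated as possibly
#' out of equilibrium: conservation of information is a weak constraint and
#' departures from the equilibrium distribution are expected, so rejection
#' is never read as a counter-demonstration of the underlying theory.
#'
#' @slot ols The [OLSFit] necessary test.
#' @slot bootstrap The [BootstrapResult] sufficiency test.
#' @slot verdict One of `"power-law-not-rejected"`, `"rejected"`,
#'   `"inconclusive"`.
#' @slot annotation Free-text qualification of the verdict.
#' @export
setClass("PowerLawVerdict",
         representation(ols = "OLSFit", bootstrap = "BootstrapResult",
                        verdict = "character", annotation = "character"))

setMethod("show", "PowerLawVerdict", function(object) {
  cat("PowerLawVerdict:", object@verdict, "\n")
  show(object@ols)
  show(object@bootstrap)
  if (nzchar(object@annotation)) cat("  note:", object@annotation, "\n")
})
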