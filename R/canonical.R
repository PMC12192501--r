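#' Hartley-Shannon information of a string
#'
#' The information content of a message of `N` symbols drawn from a unique
#' alphabet of `P` equally likely symbols: the natural log of the number of
#' possible arrangements, `N * ln(P)`. Only distinguishability of the
#' symbols is required; no intrinsic meaning enters, which is why the same
#' measure applies to amino acids and to programming-language tokens.
#'
#' @param N Positive integer length(s).
#' @param P Positive integer unique-alphabet size(s).
#' @return `N * log(P)` (natural log), recycled in the usual way.
#' @examples
#' hartleyInformation(4, 2) # 4 ln 2
#' hartleyInformation(7, 1) # 0: a single-symbol message carries nothing
#' @export
hartleyInformation <- function(N, P) {
  if (any(!is.finite(N)) || any(N < 1) || any(N != floor(N)))
    stop("'N' must contain positive integers")
  if (any(!is.finite(P)) || any(P < 1) || any(P != floor(P)))
    stop("'P' must contain positive integers")
  N * log(P)
}

#' @describeIn hartleyInformation Information of literal strings: the length
#'   and distinct-symbol count are extracted from the content.
#' @param x Character vector of non-empty strings.
#' @export
hartleyInformationOf <- function(x) {
  if (any(is.na(x)) || any(!nzchar(x))) stop("strings must be non-empty")
  hartleyInformation(nchar(x), alphabetSize(x))
}

.rhsFor <- function(categoryValues, params) {
  -params@alpha - params@beta * log(categoryValues)
}

#' Canonical occupancy of a heterogeneous (ordered-string) category
#'
#' Solves `occupancyGradient(t) = -alpha - beta * ln(a)` for a category of
#' ordered strings whose unique alphabet size is `a`; the information
#' gradient of such a category is `ln a`, with the alphabet treated as a
#' fixed parameter of the category. For large `t` the solution approaches
#' the pure power-law envelope `exp(-alpha) * a^(-beta)` from below (the
#' droop correction is positive), and categories whose right-hand side falls
#' below `33/78` are unoccupied.
#'
#' @param a Alphabet size(s), `>= 1` (real-valued categories permitted).
#' @param params A [CanonicalParams] object.
#' @return Predicted occupancies, `0` for unoccupied categories.
#' @export
heterogeneousOccupancy <- function(a, params) {
  stopifnot(is(params, "CanonicalParams"))
  if (any(!is.finite(a)) || any(a < 1)) stop("'a' must be >= 1")
  .solveOccupancyFast(.rhsFor(a, params))
}

#' Canonical occupancy of a homogeneous (unordered) category
#'
#' Solves `occupancyGradient(t) = -alpha - beta * ln(x)` for an unordered
#' category with value `x` (a rank or multiplicity class). Identical in
#' mechanics to the heterogeneous case; the physical reading differs. The
#' deficit relative to the pure power law `exp(-alpha) * x^(-beta)` grows as
#' `t` approaches 1, which is the droop in the least-populated bins of the
#' Zipf-like solution.
#'
#' @param x Category value(s), `>= 1`.
#' @param params A [CanonicalParams] object.
#' @return Predicted occupancies, `0` for unoccupied categories.
#' @export
homogeneousOccupancy <- function(x, params) {
  stopifnot(is(params, "CanonicalParams"))
  if (any(!is.finite(x)) || any(x < 1)) stop("'x' must be >= 1")
  .solveOccupancyFast(.rhsFor(x, params))
}

#' Canonical occupancy profile over a category grid
#'
#' Evaluates the canonical solution over a vector of category values and
#' packages it as an [OccupancyPrediction]. For the heterogeneous variant,
#' `feasibilityClip = TRUE` (the default) zeroes categories whose predicted
#' occupancy falls below the alphabet size: a string cannot contain more
#' distinct symbols than its length, so such contributions are clipped.
#'
#' @param categoryValues Strictly positive, strictly ascending numeric
#'   vector (alphabet sizes or rank/multiplicity classes).
#' @param params A [CanonicalParams] object.
#' @param variant `"heterogeneous"` or `"homogeneous"`.
#' @param feasibilityClip Logical; apply the `a <= t` clip (heterogeneous
#'   only).
#' @return An [OccupancyPrediction].
#' @examples
#' p <- canonicalProfile(1:50, CanonicalParams(-8, 1.3), "homogeneous")
#' head(occupancies(p))
#' @export
canonicalProfile <- function(categoryValues, params,
                             variant = c("heterogeneous", "homogeneous"),
                             feasibilityClip = NULL) {
  variant <- match.arg(variant)
  stopifnot(is(params, "CanonicalParams"))
  if (is.null(feasibilityClip)) feasibilityClip <- variant == "heterogeneous"
  occ <- .solveOccupancyFast(.rhsFor(categoryValues, params))
  if (variant == "homogeneous" && feasibilityClip)
    stop("the feasibility clip applies to the heterogeneous variant only")
  if (feasibilityClip) occ[occ < categoryValues] <- 0
  new("OccupancyPrediction", categories = as.numeric(categoryValues),
      occupancies = occ, params = params, variant = variant,
      feasibilityClip = feasibilityClip, total = sum(occ))
}

#' Normalise a prediction to a prescribed total size
#'
#' Adjusts the normalisation multiplier `alpha` (leaving `beta` untouched)
#' until the occupancies sum to `total` within a relative tolerance of
#' `1e-8`. Because the stationarity equation contains no reference to the
#' total size, the normalised shape `t_i / T` is asymptotically invariant
#' under `T -> 10 T`; the droop correction introduces only a finite-size
#' deviation of order `1 / (2 t_i)` per category. Idempotent: normalising
#' twice to the same total changes nothing.
#'
#' @param pred An [OccupancyPrediction] with at least one occupied category.
#' @param total Positive target total size.
#' @return A new [OccupancyPrediction] with `sum(occupancies) == total` to
#'   relative tolerance `1e-8`.
#' @export
normalizeTotal <- function(pred, total) {
  stopifnot(is(pred, "OccupancyPrediction"))
  if (length(total) != 1L || !is.finite(total) || total <= 0)
    stop("'total' must be a positive scalar")
  beta <- pred@params@beta
  cat0 <- pred@categories
  sumFor <- function(alpha) {
    occ <- .solveOccupancyFast(-alpha - beta * log(cat0))
    if (pred@feasibilityClip) occ[occ < cat0] <- 0
    sum(occ)
  }
  f <- function(alpha) sumFor(alpha) - total
  a0 <- pred@params@alpha
  lo <- a0; hi <- a0; step <- 1
  while (f(lo) < 0) { lo <- lo - step; step <- step * 2 }
  step <- 1
  while (f(hi) > 0) { hi <- hi + step; step <- step * 2 }
  if (lo == hi) {
    alphaStar <- lo
  } else {
    alphaStar <- stats::uniroot(f, lower = lo, upper = hi,
                                tol = .Machine$double.eps^0.5 *
                                  max(abs(lo), abs(hi), 1))$root
  }
  ## polish: d log(sum) / d alpha ~ -1, so fixed-point steps on log scale
  ## converge quadratically-enough to push the total inside 1e-9 relative
  for (i in 1:50) {
    s <- sumFor(alphaStar)
    if (s > 0 && abs(s - total) <= 1e-9 * total) break
    if (s <= 0) break
    alphaStar <- alphaStar + log(s / total)
  }
  out <- canonicalProfile(cat0, CanonicalParams(alphaStar, beta),
                          variant = pred@variant,
                          feasibilityClip = if (pred@variant ==
                                                "heterogeneous")
                            pred@feasibilityClip else FALSE)
  if (abs(out@total - total) > 1e-8 * total)
    stop(sprintf(
      "could not normalise to total %g within relative 1e-8 (reached %g); %s",
      total, out@total,
      "the feasibility clip makes the total discontinuous at this scale"))
  out
}

#' Export an occupancy prediction as TSV
#'
#' Writes columns `category`, `occupancy`, `normalized_share`.
#'
#' @param pred An [OccupancyPrediction].
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
writePrediction <- function(pred, file) {
  stopifnot(is(pred, "OccupancyPrediction"))
  df <- data.frame(category = pred@categories,
                   occupancy = pred@occupancies,
                   normalized_share = pred@occupancies / pred@total)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
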