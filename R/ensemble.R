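## ---- minimal exact integer arithmetic -------------------------------------
## Limb representation: numeric vector of base-1e7 digits, little-endian.
## Multiplication/division by small integers (here <= the system size T) keeps
## every intermediate below 2^53, so arithmetic on doubles is exact.

.BIGBASE <- 1e7

.bigOne <- function() 1

.bigMulSmall <- function(b, m) {
  carry <- 0
  for (i in seq_along(b)) {
    v <- b[i] * m + carry
    b[i] <- v %% .BIGBASE
    carry <- v %/% .BIGBASE
  }
  while (carry > 0) {
    b <- c(b, carry %% .BIGBASE)
    carry <- carry %/% .BIGBASE
  }
  b
}

.bigDivSmall <- function(b, d) {
  rem <- 0
  for (i in rev(seq_along(b))) {
    v <- rem * .BIGBASE + b[i]
    b[i] <- v %/% d
    rem <- v %% d
  }
  if (rem != 0) stop("inexact big-integer division (internal error)")
  while (length(b) > 1L && b[length(b)] == 0) b <- b[-length(b)]
  b
}

.bigToString <- function(b) {
  s <- sprintf("%.0f", b[length(b)])
  if (length(b) > 1L)
    s <- paste0(s, paste(sprintf("%07.0f", rev(b[-length(b)])),
                         collapse = ""))
  s
}

.bigPowSmall <- function(m, k) {
  b <- .bigOne()
  for (i in seq_len(k)) b <- .bigMulSmall(b, m)
  b
}

## exact multinomial coefficient T! / prod(t_i!) as limb vector, built as a
## running product of binomials so every intermediate is an integer
.bigMultinomial <- function(t) {
  b <- .bigOne()
  n <- 0
  for (ti in t) {
    if (ti == 0) next
    for (r in seq_len(ti)) {
      n <- n + 1
      b <- .bigMulSmall(b, n)
      b <- .bigDivSmall(b, r)
    }
  }
  b
}

## compare two limb vectors: -1, 0, 1
.bigCompare <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

## ---- ensemble enumeration --------------------------------------------------

#' Enumerate all compositions of T into M parts
#'
#' Produces every vector of `M` non-negative integers summing to `T`,
#' each exactly once, as the rows of an integer matrix (lexicographic in the
#' first coordinate). This is the ergodic ensemble of all possible systems
#' of the same fixed size, against which canonical predictions are
#' validated by brute force.
#'
#' @param T Positive integer total size.
#' @param M Positive integer number of categories.
#' @param guard Maximum number of compositions permitted
#'   (`choose(T + M - 1, M - 1)`, default `1e7`); exceeding it is an error
#'   reporting the count that would be produced.
#' @return Integer matrix with `choose(T + M - 1, M - 1)` rows, `M` columns.
#' @examples
#' enumerateCompositions(4, 2) # 5 compositions
#' @export
enumerateCompositions <- function(T, M, guard = 1e7) {
  if (length(T) != 1L || T < 1 || T != floor(T)) stop("'T' must be a positive integer")
  if (length(M) != 1L || M < 1 || M != floor(M)) stop("'M' must be a positive integer")
  count <- choose(T + M - 1, M - 1)
  if (count > guard)
    stop(sprintf("enumeration of %g compositions exceeds the guard (%g)",
                 count, guard))
  rec <- function(total, parts) {
    if (parts == 1L) return(matrix(as.integer(total), 1L, 1L))
    do.call(rbind, lapply(total:0, function(k)
      cbind(as.integer(k), rec(total - k, parts - 1L))))
  }
  out <- rec(as.integer(T), as.integer(M))
  dimnames(out) <- NULL
  out
}

#' Exact multinomial weight of a composition
#'
#' The number of distinguishable arrangements realising an occupancy vector:
#' `Omega = T! / prod(t_i!)`, with empty categories contributing `0! = 1`.
#' The value is computed in exact integer arithmetic (internal limb
#' representation, so it stays exact far beyond 2^53) and returned both as a
#' decimal string and as a log (via [logFactorialExact()]).
#'
#' @param t Non-negative integer occupancy vector.
#' @return List with elements `weight` (decimal string), `value` (numeric,
#'   `Inf` if the exact value overflows a double), and `logWeight`.
#' @examples
#' multinomialWeight(c(2, 2))$weight # "6"
#' @export
multinomialWeight <- function(t) {
  if (any(!is.finite(t)) || any(t < 0) || any(t != floor(t)))
    stop("'t' must be a vector of non-negative integers")
  b <- .bigMultinomial(as.integer(t))
  s <- .bigToString(b)
  Tt <- sum(t)
  logw <- logFactorialExact(Tt) - sum(logFactorialExact(t))
  list(weight = s, value = as.numeric(s), logWeight = logw)
}

## log-weights of all rows of a composition matrix, via a cumulative
## log-factorial lookup
.logWeights <- function(comps) {
  T <- sum(comps[1L, ])
  lf <- c(0, cumsum(log(seq_len(max(T, 1)))))
  lf[T + 1L] - rowSums(matrix(lf[comps + 1L], nrow = nrow(comps)))
}

#' Modal composition(s) of a (possibly constrained) ensemble
#'
#' Enumerates all compositions of `T` into `M` categories, optionally
#' restricts to those whose total information `sum(t_i * ln(x_i))` lies
#' within `tol` of `targetInfo`, and returns the composition(s) with maximal
#' multinomial weight. Near-ties in log space are resolved by exact integer
#' comparison, and genuine ties are reported in full.
#'
#' @param T,M,guard As in [enumerateCompositions()].
#' @param categoryValues Optional ascending positive category values `x_i`
#'   whose logs are the per-element information contents; required when
#'   `targetInfo` is given.
#' @param targetInfo Optional real target total information.
#' @param tol Tolerance band for the information constraint; defaults to
#'   half the smallest distinct increment `|ln x_i - ln x_j|`, since integer
#'   compositions rarely hit a real-valued target exactly.
#' @return List: `modal` (integer matrix of tied maxima), `logWeight`,
#'   `nFeasible`, `tol` (NA when unconstrained). If the feasible set is
#'   empty, `modal` has zero rows and `nFeasible` is 0.
#' @examples
#' modalComposition(4, 2)$modal # (2, 2)
#' @export
modalComposition <- function(T, M, categoryValues = NULL, targetInfo = NULL,
                             tol = NULL, guard = 1e7) {
  comps <- enumerateCompositions(T, M, guard)
  if (!is.null(targetInfo)) {
    if (is.null(categoryValues))
      stop("'categoryValues' is required with an information constraint")
    if (length(categoryValues) != M)
      stop("'categoryValues' must have length M")
    if (is.null(tol)) tol <- .defaultInfoTol(categoryValues)
    if (tol <= 0) stop("'tol' must be positive")
    info <- as.numeric(comps %*% log(categoryValues))
    keep <- abs(info - targetInfo) <= tol
    if (!any(keep))
      return(list(modal = comps[0L, , drop = FALSE], logWeight = NA_real_,
                  nFeasible = 0L, tol = tol))
    comps <- comps[keep, , drop = FALSE]
  } else {
    tol <- NA_real_
  }
  lw <- .logWeights(comps)
  best <- max(lw)
  cand <- which(lw >= best - 1e-9)
  if (length(cand) > 1L) {
    bigs <- lapply(cand, function(i) .bigMultinomial(comps[i, ]))
    ref <- bigs[[1L]]
    for (b in bigs[-1L]) if (.bigCompare(b, ref) > 0) ref <- b
    cand <- cand[vapply(bigs, function(b) .bigCompare(b, ref) == 0,
                        logical(1))]
  }
  list(modal = comps[cand, , drop = FALSE], logWeight = max(lw[cand]),
       nFeasible = nrow(comps), tol = tol)
}

.defaultInfoTol <- function(categoryValues) {
  lx <- sort(unique(log(categoryValues)))
  if (length(lx) < 2L) return(0.5)
  min(diff(lx)) / 2
}

#' Deviation of the enumerated modal composition from the canonical solution
#'
#' Validation bridge between brute-force enumeration and the canonical
#' stationarity solution: the canonical homogeneous profile over
#' `categoryValues` is normalised to total `T`, its total information is
#' taken as the constraint target, the modal composition of the constrained
#' ensemble is found by enumeration, and the maximum relative deviation
#' `max_i |t_modal - t_canonical| / max(t_canonical, 1)` is reported (the
#' minimum over tied maxima). As `T` grows with the constraint shape held
#' fixed, this deviation shrinks: the canonical solution is the
#' overwhelmingly most likely configuration.
#'
#' @param T,M,guard As in [enumerateCompositions()].
#' @param beta Information multiplier of the canonical comparison solution.
#' @param categoryValues Ascending positive category values (default
#'   `1:M`).
#' @param tol Information tolerance band (default as in
#'   [modalComposition()]).
#' @return List: `deviation`, `modal` (matrix), `canonical` (numeric),
#'   `targetInfo`, `tol`.
#' @export
compareToCanonical <- function(T, M, beta, categoryValues = seq_len(M),
                               tol = NULL, guard = 1e7) {
  start <- canonicalProfile(categoryValues, CanonicalParams(0, beta),
                            variant = "homogeneous")
  canon <- normalizeTotal(start, T)
  tc <- occupancies(canon)
  if (M == 1L)
    return(list(deviation = 0, modal = matrix(as.integer(T), 1L, 1L),
                canonical = tc, targetInfo = sum(tc * log(categoryValues)),
                tol = NA_real_))
  target <- sum(tc * log(categoryValues))
  constrained <- beta > 0
  mc <- modalComposition(T, M,
                         categoryValues = if (constrained) categoryValues,
                         targetInfo = if (constrained) target,
                         tol = tol, guard = guard)
  if (nrow(mc$modal) == 0L)
    stop("no feasible composition within the information tolerance band")
  dev <- min(apply(mc$modal, 1L, function(tm)
    max(abs(tm - tc) / pmax(tc, 1))))
  list(deviation = dev, modal = mc$modal, canonical = tc,
       targetInfo = target, tol = mc$tol)
}

#' Export an enumerated ensemble as TSV
#'
#' Writes one row per composition: the occupancies, the exact weight, the
#' log weight, and (when a constraint is supplied) a feasibility flag.
#'
#' @inheritParams modalComposition
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
writeEnsemble <- function(T, M, file, categoryValues = NULL,
                          targetInfo = NULL, tol = NULL, guard = 1e5) {
  comps <- enumerateCompositions(T, M, guard)
  w <- apply(comps, 1L, function(t) multinomialWeight(t)$weight)
  df <- data.frame(composition = apply(comps, 1L, paste, collapse = ","),
                   weight = w, logWeight = .logWeights(comps))
  if (!is.null(targetInfo)) {
    if (is.null(tol)) tol <- .defaultInfoTol(categoryValues)
    info <- as.numeric(comps %*% log(categoryValues))
    df$feasible <- abs(info - targetInfo) <= tol
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
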