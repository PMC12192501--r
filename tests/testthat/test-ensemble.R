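test_that("composition enumeration matches stars and bars", {
  c42 <- enumerateCompositions(4, 2)
  expect_equal(nrow(c42), 5L)
  expect_true(all(rowSums(c42) == 4L))
  expect_equal(nrow(unique(c42)), 5L)
  expect_equal(enumerateCompositions(7, 1), matrix(7L, 1L, 1L))
  for (T in c(1, 4, 7, 10)) {
    for (M in 1:4) {
      expect_equal(nrow(enumerateCompositions(T, M)),
                   choose(T + M - 1, M - 1))
    }
  }
  expect_error(enumerateCompositions(100, 6, guard = 1000), "exceeds the guard")
})

test_that("multinomial weight matches brute-force arrangement counting", {
  # brute force: all 2^4 colourings of 4 slots, count those with two of each
  slots <- expand.grid(rep(list(1:2), 4))
  expect_equal(sum(rowSums(slots == 1) == 2), 6)
  expect_equal(multinomialWeight(c(2, 2))$value, 6)
  expect_equal(multinomialWeight(c(2, 2))$weight, "6")
  expect_equal(multinomialWeight(c(4, 0))$value, 1)
  expect_equal(multinomialWeight(c(2, 2))$logWeight, log(6))
  # total arrangements across all compositions: M^T
  c42 <- enumerateCompositions(4, 2)
  expect_equal(sum(apply(c42, 1, function(t) multinomialWeight(t)$value)),
               2^4)
})

test_that("exact integer arithmetic holds far beyond double precision", {
  # frozen oracle values computed with arbitrary-precision integers
  expect_identical(multinomialWeight(c(20, 20, 20))$weight,
                   "577831214478475823831865900")
  expect_identical(multinomialWeight(c(33, 17, 10))$weight,
                   "742433593269223396440900")
  expect_identical(multinomialWeight(c(40, 0))$weight, "1")
})

test_that("weights over every composition conserve M^T exactly", {
  for (M in 1:4) {
    for (T in c(3, 8, 12)) {
      comps <- enumerateCompositions(T, M)
      total <- sum(apply(comps, 1, function(t) multinomialWeight(t)$value))
      expect_identical(total, M^T)
    }
  }
})

test_that("unconstrained modal compositions are balanced", {
  expect_equal(modalComposition(4, 2)$modal, matrix(c(2L, 2L), 1L))
  expect_equal(modalComposition(6, 3)$modal,
               matrix(c(2L, 2L, 2L), 1L))
  expect_equal(modalComposition(2, 2)$modal, matrix(c(1L, 1L), 1L))
  for (T in c(5, 9, 13)) {
    for (M in 2:4) {
      modal <- modalComposition(T, M)$modal
      expect_true(all(apply(modal, 1,
                            function(t) max(t) - min(t) <= 1L)))
    }
  }
})

test_that("ties in the modal set are reported in full", {
  # T = 3, M = 2: (2,1) and (1,2) both have weight 3
  modal <- modalComposition(3, 2)$modal
  expect_equal(nrow(modal), 2L)
  expect_setequal(apply(modal, 1, paste, collapse = ","),
                  c("2,1", "1,2"))
})

test_that("a linear information constraint tilts the modal composition", {
  # ascending per-element information ln(x): fixing total information below
  # the balanced value forces occupancies non-increasing in the category
  x <- c(1, exp(1), exp(2))
  T <- 24
  balancedInfo <- sum(T / 3 * log(x))
  out <- modalComposition(T, 3, categoryValues = x,
                          targetInfo = 0.6 * balancedInfo, tol = 0.5)
  expect_gt(nrow(out$modal), 0L)
  expect_true(all(apply(out$modal, 1, function(t) all(diff(t) <= 0))))
})

test_that("an unreachable information band reports no feasible composition", {
  out <- modalComposition(6, 2, categoryValues = c(1, 2),
                          targetInfo = 100, tol = 0.1)
  expect_equal(out$nFeasible, 0L)
  expect_equal(nrow(out$modal), 0L)
})

test_that("canonical comparison behaves at the edges", {
  expect_equal(compareToCanonical(25, 1, beta = 1)$deviation, 0)
  # beta = 0: flat canonical vs balanced modal, discreteness-level deviation
  out <- compareToCanonical(30, 3, beta = 0)
  expect_lt(out$deviation, 1.5 / 10)  # |t_m - 10|/10 at most ~1/T scale
  # deviation is a non-negative max-relative measure
  out2 <- compareToCanonical(30, 3, beta = 1)
  expect_gte(out2$deviation, 0)
  expect_equal(sum(out2$canonical), 30, tolerance = 1e-6)
})

test_that("ensembles export as TSV with feasibility flags", {
  f <- tempfile(fileext = ".tsv")
  writeEnsemble(4, 2, f, categoryValues = c(1, 2), targetInfo = 2 * log(2),
                tol = 0.4)
  got <- read.delim(f, colClasses = c(weight = "character"))
  expect_equal(nrow(got), 5L)
  expect_true(is.logical(got$feasible))
  expect_equal(sum(as.numeric(got$weight)), 16)
})
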