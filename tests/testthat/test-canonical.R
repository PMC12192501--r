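test_that("Hartley information follows N log P", {
  expect_equal(hartleyInformation(4, 2), 4 * log(2))
  expect_identical(hartleyInformation(7, 1), 0)
  expect_equal(hartleyInformationOf("ABAB"), hartleyInformation(4, 2))
  expect_error(hartleyInformation(0, 2), "positive")
  expect_error(hartleyInformation(4, 0), "positive")
  expect_error(hartleyInformationOf(""), "non-empty")
})

test_that("canonical parameter validity is enforced", {
  expect_s4_class(CanonicalParams(-3, 1.5), "CanonicalParams")
  expect_error(CanonicalParams(NA, 1), "finite")
  expect_error(CanonicalParams(0, -0.5), ">= 0")
})

test_that("heterogeneous occupancy honours envelope and monotonicity", {
  p <- CanonicalParams(-9, 1.4)
  a <- 1:40
  occ <- heterogeneousOccupancy(a, p)
  env <- exp(-p@alpha) * a^(-p@beta)
  expect_true(all(occ <= env))
  expect_true(all(diff(occ[occ > 0]) < 0))
  # beta = 0: the information term vanishes, occupancy is flat
  flat <- heterogeneousOccupancy(c(1, 5, 20), CanonicalParams(-6, 0))
  expect_equal(flat[1], flat[2])
  expect_equal(flat[2], flat[3])
})

test_that("homogeneous droop grows towards the sparse tail", {
  # choose parameters so occupancies span from ~thousints down to ~2
  p <- CanonicalParams(-occupancyGradient(2000), 1.2)
  x <- 1:5000
  occ <- homogeneousOccupancy(x, p)
  env <- exp(-p@alpha) * x^(-p@beta)
  deficit <- 1 - occ / env
  iSparse <- which.min(abs(occ - 2))
  iDense <- which.min(abs(occ - 1000))
  expect_gt(deficit[iSparse], deficit[iDense])
  # x = 1 reduces to the pure normalisation equation
  expect_equal(homogeneousOccupancy(1, p),
               solveOccupancy(-p@alpha), tolerance = 1e-9)
})

test_that("feasibility clip zeroes categories with t below their alphabet", {
  # occupancy at large alphabet falls below a, so those categories clip
  p <- CanonicalParams(-occupancyGradient(50), 1.5)
  pred <- canonicalProfile(1:60, p, "heterogeneous")
  occ <- occupancies(pred)
  raw <- heterogeneousOccupancy(1:60, p)
  clipped <- raw < 1:60
  expect_true(any(clipped))
  expect_true(all(occ[clipped] == 0))
  expect_equal(occ[!clipped], raw[!clipped])
})

test_that("normalisation hits the target total and is idempotent", {
  p0 <- canonicalProfile(1:100, CanonicalParams(0, 1.3), "homogeneous")
  pn <- normalizeTotal(p0, 5e4)
  expect_equal(totalSize(pn), 5e4, tolerance = 1e-8)
  expect_equal(sum(occupancies(pn)), 5e4, tolerance = 1e-8)
  again <- normalizeTotal(pn, 5e4)
  expect_equal(occupancies(again), occupancies(pn), tolerance = 1e-9)
  expect_error(normalizeTotal(pn, -1), "positive")
})

test_that("normalised shape is scale-independent for well-occupied systems", {
  base <- canonicalProfile(1:100, CanonicalParams(0, 1.5), "homogeneous")
  a <- normalizeTotal(base, 1e12)
  b <- normalizeTotal(base, 1e13)
  shareA <- occupancies(a) / totalSize(a)
  shareB <- occupancies(b) / totalSize(b)
  expect_lt(max(abs(shareA - shareB) / shareA), 1e-6)
})

test_that("predictions export as TSV with normalised shares", {
  pred <- canonicalProfile(1:10, CanonicalParams(-5, 1), "homogeneous")
  f <- tempfile(fileext = ".tsv")
  writePrediction(pred, f)
  got <- read.delim(f)
  expect_named(got, c("category", "occupancy", "normalized_share"))
  expect_equal(got$occupancy, occupancies(pred))
  expect_equal(sum(got$normalized_share), 1, tolerance = 1e-12)
})
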