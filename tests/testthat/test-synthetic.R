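test_that("the canonical length law is a proper discrete distribution", {
  law <- canonicalLengthLaw(betaTail = 3.1, peakLength = 300,
                            maxLength = 45000)
  expect_equal(sum(law$pmf), 1, tolerance = 1e-12)
  expect_equal(law$lengths[1], 300L)
  expect_true(all(diff(law$pmf) < 0))  # mode at the feasibility onset
  # pure power-law check in the envelope region: pmf ratio ~ (l1/l2)^(beta+1)
  r <- law$pmf[law$lengths == 400] / law$pmf[law$lengths == 4000]
  expect_equal(log(r), 4.1 * log(10), tolerance = 0.01)
})

test_that("heterogeneous corpus generation is deterministic and ledgered", {
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  g1 <- genHeterogeneousCorpus(200, seed = 42, fastaFile = f1,
                               peakLength = 50, maxLength = 2000)
  g2 <- genHeterogeneousCorpus(200, seed = 42, fastaFile = f2,
                               peakLength = 50, maxLength = 2000)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$records, g2$records)
  g3 <- genHeterogeneousCorpus(200, seed = 43, peakLength = 50,
                               maxLength = 2000)
  expect_false(identical(g1$ledger$lengths, g3$ledger$lengths))
})

test_that("generator ledger equals the ingested measurements exactly", {
  f <- tempfile(fileext = ".fasta.gz")
  g <- genHeterogeneousCorpus(400, seed = 7, fastaFile = f,
                              peakLength = 60, maxLength = 3000)
  rec <- readFasta(f)
  expect_equal(nrow(rec), 400L)
  expect_identical(table(rec$length), table(g$ledger$lengths))
  expect_identical(rec$length, g$ledger$lengths)
  expect_identical(rec$alphabet_size, g$ledger$alphabets)
  expect_true(all(rec$alphabet_size <= rec$length))
})

test_that("infeasible heterogeneous specs are rejected", {
  expect_error(genHeterogeneousCorpus(10, seed = 1, peakLength = 10,
                                      alphabetRange = c(15, 20)),
               "infeasible spec")
  expect_error(genHeterogeneousCorpus(10, seed = 1,
                                      alphabetRange = c(1, 25)),
               "symbol universe")
})

test_that("multiplicity generator bookkeeping matches the measured table", {
  g <- genMultiplicityFasta(500, slope = 1.33, nSpecies = 40, seed = 3)
  tab <- multiplicityTable(g$records)
  led <- table(g$ledger$multiplicities)
  expect_identical(as.integer(led), groupCounts(tab))
  expect_identical(as.integer(names(led)), multiplicities(tab))
  # FASTA round trip preserves the grouping
  f <- tempfile(fileext = ".fasta")
  g2 <- genMultiplicityFasta(120, slope = 1.33, nSpecies = 15, seed = 9,
                             fastaFile = f)
  rec <- readFasta(f)
  t1 <- multiplicityTable(rec)
  t2 <- multiplicityTable(g2$records)
  expect_identical(multiplicities(t1), multiplicities(t2))
  expect_identical(groupCounts(t1), groupCounts(t2))
})

test_that("a single species forces every multiplicity to one", {
  g <- genMultiplicityFasta(50, slope = 1.33, nSpecies = 1, seed = 2)
  expect_true(all(g$ledger$multiplicities == 1L))
  tab <- multiplicityTable(g$records)
  expect_equal(multiplicities(tab), 1L)
  expect_equal(groupCounts(tab), 50L)
})

test_that("canonical-droop multiplicity law droops below pure Zipf", {
  gZ <- genMultiplicityFasta(4000, slope = 1.2, nSpecies = 50, seed = 11,
                             law = "pure-zipf")
  gD <- genMultiplicityFasta(4000, slope = 1.2, nSpecies = 50, seed = 11,
                             law = "canonical-droop")
  # the droop suppresses the highest multiplicity classes
  expect_lt(max(gD$ledger$multiplicities), 51L)
  expect_lte(mean(gD$ledger$multiplicities),
             mean(gZ$ledger$multiplicities))
})

test_that("generated C sources lex cleanly with exact ledger bookkeeping", {
  dir <- file.path(tempdir(), "csrc-test")
  unlink(dir, recursive = TRUE)
  g <- genCLikeSources(5000, vocabSize = 50, slope = 1.19, nFiles = 4,
                       seed = 13, dir = dir)
  freqs <- tokenFrequencies(dir)
  vocabFreqs <- freqs[names(freqs) %in% g$ledger$vocabulary]
  led <- g$ledger$counts[g$ledger$counts > 0]
  expect_identical(as.integer(vocabFreqs[names(led)]),
                   unname(as.integer(led)))
  # functions extract from every file
  sp <- extractFunctions(tokenizeC(file = g$files[1]))
  expect_gt(nrow(sp), 0L)
  # deterministic bytes
  dir2 <- file.path(tempdir(), "csrc-test2")
  unlink(dir2, recursive = TRUE)
  g2 <- genCLikeSources(5000, vocabSize = 50, slope = 1.19, nFiles = 4,
                        seed = 13, dir = dir2)
  expect_identical(readLines(g$files[2]), readLines(g2$files[2]))
})
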