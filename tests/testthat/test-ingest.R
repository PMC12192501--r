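test_that("FASTA records carry lengths, alphabets and exact content identity", {
  f <- writeToyFasta(c(p1 = "MKV", p2 = "MKVAA"))
  rec <- readFasta(f)
  expect_equal(rec$length, c(3L, 5L))
  expect_equal(rec$alphabet_size, c(3L, 4L))  # MKV; MKVA(A)
  expect_equal(rec$component_id, c("p1", "p2"))
  expect_true(all(rec$alphabet_size <= rec$length))
  # lowercase input normalises to the same digest
  g <- writeToyFasta(c(p1 = "mkv"))
  expect_identical(readFasta(g)$digest[1], rec$digest[1])
})

test_that("empty FASTA input and empty sequences are handled", {
  f <- writeToyFasta(character(0))
  rec <- readFasta(f)
  expect_equal(nrow(rec), 0L)
  expect_equal(corpusSummary(rec)$nRecords, 0L)
  g <- writeToyFasta(c(ok = "MKV", bad = "", ok2 = "AA"))
  expect_warning(rec2 <- readFasta(g), "empty sequence")
  expect_equal(rec2$component_id, c("ok", "ok2"))
})

test_that("gzip FASTA yields identical records and species tags parse", {
  plain <- writeToyFasta(c("a species=SPX" = "MKVW", "b species=SPY" = "ML"))
  zipped <- writeToyFasta(c("a species=SPX" = "MKVW", "b species=SPY" = "ML"),
                          file = tempfile(fileext = ".fasta.gz"), gz = TRUE)
  r1 <- readFasta(plain); r2 <- readFasta(zipped)
  expect_identical(r1, r2)
  expect_equal(r1$group_key, c("SPX", "SPY"))
  expect_equal(r1$component_id, c("a", "b"))
})

test_that("UniProt flat entries parse with OS/OX species fallback", {
  f <- writeUniprot(list(
    uniprotEntry("P00001", "MKVLAWS", os = "Escherichia coli", ox = "562"),
    uniprotEntry("P00002", "MKVLAWSX", os = "Homo sapiens", ox = "9606")))
  rec <- readUniprotFlat(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$group_key, c("Escherichia coli", "Homo sapiens"))
  expect_equal(rec$length, c(7L, 8L))
  # OS absent -> OX taxon id
  g <- writeUniprot(list(uniprotEntry("P00003", "MMMK", ox = "1234")))
  expect_equal(readUniprotFlat(g)$group_key, "1234")
  # OX preference when requested
  expect_equal(readUniprotFlat(f, speciesFrom = "OX")$group_key,
               c("562", "9606"))
})

test_that("UniProt sequences spanning several SQ lines are reassembled", {
  seq <- paste(rep("ACDEFGHIKL", 13), collapse = "")  # 130 aa, 3 SQ lines
  f <- writeUniprot(list(uniprotEntry("P1", seq, os = "Test sp")))
  rec <- readUniprotFlat(f)
  expect_equal(rec$length, 130L)
  expect_identical(rec$digest, seq)
})

test_that("UniProt format errors are reported", {
  noSq <- c("ID   P1   Unreviewed;   5 AA.", "OS   X y.", "//")
  f <- writeUniprot(list(noSq, uniprotEntry("P2", "MKV", os = "Z z")))
  expect_warning(rec <- readUniprotFlat(f), "no SQ block")
  expect_equal(rec$component_id, "P2")
  truncated <- uniprotEntry("P3", "MKV", os = "Q q")
  truncated <- truncated[-length(truncated)]  # drop the terminator
  g <- writeUniprot(list(truncated))
  expect_error(readUniprotFlat(g), "truncated")
})

test_that("gzip UniProt input matches plain input", {
  ent <- list(uniprotEntry("P10", "MKVLMKVL", os = "Some species"))
  p <- writeUniprot(ent)
  z <- writeUniprot(ent, file = tempfile(fileext = ".dat.gz"), gz = TRUE)
  expect_identical(readUniprotFlat(p), readUniprotFlat(z))
})

test_that("alphabet size counts distinct symbols", {
  expect_equal(alphabetSize(c("ABAB", "AAAA")), c(2L, 1L))
  pangram <- paste(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   collapse = "")
  expect_equal(alphabetSize(pangram), 20L)
  expect_error(alphabetSize(""), "non-empty")
})

test_that("reading the same stream twice is deterministic", {
  f <- writeToyFasta(c(a = "MKVW", b = "MLPQ", c = "MKVW"))
  r1 <- readFasta(f); r2 <- readFasta(f)
  expect_identical(r1, r2)
  s1 <- corpusSummary(r1)
  expect_equal(s1$totalLength, 12L)
})
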