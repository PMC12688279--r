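test_that("FASTA reading normalizes case, maps U to T, preserves order", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1 some description", "acgu", ">c2", "GGNNA"), f)
    s <- readFasta(f)
    expect_identical(ids(s), c("c1", "c2"))
    expect_identical(unname(sequences(s)), c("ACGT", "GGNNA"))
})

test_that("FASTA reader raises typed errors on bad input", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
    expect_error(readFasta(f), class = "duplicateIdentifierError")
    writeLines(c(">a", "ACGT", ">b", "AXGT"), f)
    expect_error(readFasta(f), class = "alphabetError")
    expect_error(readFasta(f), "'b'")
    writeLines(character(), f)
    expect_error(readFasta(f), class = "formatError")
})

test_that("FASTA round trip reproduces records modulo wrapping", {
    d <- tinyDataset()
    f <- withr::local_tempfile(fileext = ".fa")
    writeFasta(d$seqs, f, width = 17L)
    back <- readFasta(f)
    expect_identical(sequences(back), sequences(d$seqs))
})

test_that("association matrix IO: dialect detection, round trip, errors", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("\td1\td2", "c1\t1\t0", "c2\t0\t1"), f)
    A <- readAssociationMatrix(f)
    expect_identical(dim(valuesMatrix(A)), c(2L, 2L))
    expect_equal(mean(valuesMatrix(A)), 0.5)
    # comma dialect auto-detected
    fc <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(",d1,d2", "c1,1,0", "c2,0,1"), fc)
    expect_equal(valuesMatrix(readAssociationMatrix(fc)), valuesMatrix(A))
    # writes tab; round trip is the identity
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeAssociationMatrix(A, f2)
    expect_true(grepl("\t", readLines(f2)[1]))
    expect_equal(valuesMatrix(readAssociationMatrix(f2)), valuesMatrix(A))
    # non-binary cell located; ragged and empty bodies rejected
    writeLines(c("\td1\td2", "c1\t1\t2", "c2\t0\t1"), f)
    err <- expect_error(readAssociationMatrix(f), class = "valueError")
    expect_match(conditionMessage(err), "c1")
    expect_match(conditionMessage(err), "d2")
    writeLines(c("\td1\td2", "c1\t1", "c2\t0\t1"), f)
    expect_error(readAssociationMatrix(f), class = "formatError")
    writeLines("\td1\td2", f)
    expect_error(readAssociationMatrix(f), class = "dimensionError")
})

test_that("fingerprint IO round-trips and rejects non-binary bits", {
    d <- tinyDataset()
    f <- withr::local_tempfile(fileext = ".tsv")
    writeFingerprints(d$fps, f)
    back <- readFingerprints(f)
    expect_identical(unname(valuesMatrix(back)),
                     unname(valuesMatrix(d$fps)))
    writeLines(c("\tb1\tb2", "d1\t1\t3"), f)
    expect_error(readFingerprints(f), class = "valueError")
})

test_that("ranking tables enforce ordering and round-trip byte-identically", {
    expect_error(RankingTable("dox", c("a", "b"), c(0.9, 0.91)),
                 class = "orderingError")
    rt <- RankingTable("dox", sprintf("c%02d", 1:20),
                       seq(0.99, by = -0.01, length.out = 20),
                       verified = c(rep(TRUE, 15), rep(NA, 5)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeRanking(rt, f)
    lines <- readLines(f)
    expect_length(lines, 21L)            # header + 20 data lines
    expect_identical(lines[1], "rank\tcircRNA\tscore\tverified")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeRanking(readRanking(f, "dox"), f2)
    expect_identical(readLines(f2), lines)
})

test_that("model configuration round-trips through YAML", {
    cfg <- modelConfig(encoder.layers = 2, mask.alpha = 0.35,
                       loss.tauMin = 0.2, ablation.useGat = FALSE)
    f <- withr::local_tempfile(fileext = ".yaml")
    writeModelConfig(cfg, f)
    back <- readModelConfig(f)
    expect_equal(back@encoder, cfg@encoder)
    expect_equal(back@mask, cfg@mask)
    expect_equal(back@loss, cfg@loss)
    expect_equal(back@ablation, cfg@ablation)
})
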