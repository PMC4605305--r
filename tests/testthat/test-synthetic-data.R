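test_that("probe libraries satisfy their invariants at several sizes", {
    for (n in c(1, 10, 250)) {
        lib <- makeProbeLibrary(n, seed = 7)
        expect_s4_class(lib, "ProbeLibrary")
        expect_equal(nrow(lib), n)
        expect_false(anyDuplicated(lib$event_id) > 0)
        expect_false(anyDuplicated(c(lib$long_junction_seq,
                                     lib$short_junction_seq)) > 0)
        expect_true(all(lib$long_junction_seq != lib$short_junction_seq))
        expect_true(all(grepl("^[ACGT]+$", lib$long_junction_seq)))
        expect_equal(unique(nchar(lib$long_junction_seq)), 40)
    }
})

test_that("probe library generation is deterministic given the seed", {
    expect_identical(makeProbeLibrary(100, seed = 3),
                     makeProbeLibrary(100, seed = 3))
    expect_false(identical(makeProbeLibrary(100, seed = 3),
                           makeProbeLibrary(100, seed = 4)))
})

test_that("ProbeLibrary validity rejects broken inputs", {
    expect_error(ProbeLibrary(c("a", "a"), c("g", "g"),
                              c("ACGT", "AAAA"), c("TTTT", "CCCC")),
                 "unique")
    expect_error(ProbeLibrary("a", "g", "ACGT", "ACGT"), "differ")
    expect_error(ProbeLibrary("a", "g", "ACGU", "AAAA"), "A/C/G/T")
    expect_error(ProbeLibrary(c("a", "b"), c("g", "h"),
                              c("ACGT", "ACGTAA"), c("TTTT", "CCCCGG")),
                 "common length")
})

test_that("sample sheets carry unique equal-length barcodes and conditions", {
    ss <- makeSampleSheet(c("WT_U", "WT_S", "PSF_KD_S", "TRAP150_KD_U"),
                          replicates = 3, seed = 5)
    expect_equal(nrow(ss), 12)
    expect_false(anyDuplicated(ss$barcode) > 0)
    expect_equal(unique(nchar(ss$barcode)), 8)
    expect_setequal(unique(ss$condition),
                    c("WT_U", "WT_S", "PSF_KD_S", "TRAP150_KD_U"))
    expect_equal(ss$genotype[ss$condition == "TRAP150_KD_U"][1],
                 "TRAP150_KD")
    expect_error(RaslSamples("WT", "U", 1, "ACGN"), "A/C/G/T")
    expect_error(RaslSamples(c("WT", "WT"), c("U", "U"), c(1, 1),
                             c("AAAA", "CCCC")),
                 "unique")
    expect_error(RaslSamples("MUT", "U", 1, "AAAA"), "genotype")
})

test_that("simulated counts respect degenerate true PSI and sum structure", {
    lib <- tiny_library(n = 6)
    ss <- tiny_samples()
    tp <- matrix(c(rep(100, 6), rep(0, 6), rep(50, 6)), 6, 3,
                 dimnames = list(NULL, c("WT_U", "WT_S", "PSF_KD_S")))
    cs <- simulateCounts(lib, ss, tp, mean_depth = 50, seed = 9)
    wt_u <- SummarizedExperiment::colData(cs)$condition == "WT_U"
    wt_s <- SummarizedExperiment::colData(cs)$condition == "WT_S"
    expect_true(all(shortCounts(cs)[, wt_u] == 0))   # psi 100
    expect_true(all(longCounts(cs)[, wt_s] == 0))    # psi 0
    expect_true(all(longCounts(cs) + shortCounts(cs) == totalCounts(cs)))
    expect_identical(
        longCounts(simulateCounts(lib, ss, tp, mean_depth = 50, seed = 9)),
        longCounts(cs))
})

test_that("simulateCounts rejects out-of-range PSI and missing conditions", {
    lib <- tiny_library()
    ss <- tiny_samples()
    expect_error(simulateCounts(lib, ss, 120, seed = 1), "\\[0, 100\\]")
    tp <- matrix(50, nrow(lib), 1, dimnames = list(NULL, "WT_U"))
    expect_error(simulateCounts(lib, ss, tp, seed = 1), "PSF_KD_S")
})

test_that("replicate PSI recovers the truth as depth grows", {
    # binomial SE at depth 1e4 and psi 88 is ~0.33 pp, so the 3-replicate
    # condition mean lands within 1 pp; at depth 1e5 every one of 100
    # events is within 0.5 pp
    lib <- makeProbeLibrary(1, seed = 2, junction_length = 12)
    ss <- makeSampleSheet("WT_S", replicates = 3, seed = 2)
    cs <- simulateCounts(lib, ss, 88, mean_depth = 1e4, dispersion = Inf,
                         seed = 21)
    m <- conditionMeans(computePsi(cs))
    expect_lt(abs(m$WT_S - 88), 1)

    lib2 <- makeProbeLibrary(100, seed = 3, junction_length = 12)
    ss1 <- makeSampleSheet("WT_S", replicates = 1, seed = 3)
    set.seed(31)
    truth <- runif(100, 1, 99)
    cs2 <- simulateCounts(lib2, ss1,
                          matrix(truth, 100, 1,
                                 dimnames = list(NULL, "WT_S")),
                          mean_depth = 1e5, dispersion = Inf, seed = 32)
    psi_hat <- psiValues(computePsi(cs2))[, 1]
    expect_lt(max(abs(psi_hat - truth)), 0.5)
})

test_that("emitted reads have the right cardinality, prefix and quality", {
    lib <- manual_library()
    ss <- manual_samples()
    long <- matrix(c(3L, 0L, 0L, 2L), 2, 2)
    short <- matrix(c(0L, 1L, 4L, 0L), 2, 2)
    cs <- RaslCountSet(long, short, lib, ss)
    reads <- emitReads(cs)
    expect_length(reads, sum(long) + sum(short))
    # every read is barcode + an exact library junction at error rate 0
    junctions <- c(lib$long_junction_seq, lib$short_junction_seq)
    expect_true(all(substr(reads, 5, 12) %in% junctions))
    evA_long_s1 <- reads[startsWith(names(reads), "WT_U_rep1:evA:long")]
    expect_length(evA_long_s1, 3)
    expect_true(all(startsWith(evA_long_s1, "ACGT")))

    fq <- tempfile(fileext = ".fastq")
    emitReads(cs, path = fq)
    lines <- readLines(fq)
    expect_length(lines, 4 * length(reads))
    expect_true(all(lines[seq(4, length(lines), by = 4)] ==
                        strrep("I", 12)))
})

test_that("read emission with substitution noise perturbs the right fraction", {
    lib <- tiny_library(n = 10, junction_length = 30)
    ss <- tiny_samples(conditions = "WT_S", replicates = 1)
    cs <- simulateCounts(lib, ss, 50, mean_depth = 200, seed = 6)
    clean <- emitReads(cs, seed = 7)
    noisy <- emitReads(cs, error_rate = 0.02, seed = 7)
    expect_equal(length(clean), length(noisy))
    mm <- mapply(function(a, b)
        sum(charToRaw(a) != charToRaw(b)), clean, noisy)
    rate_hat <- sum(mm) / (length(clean) * nchar(clean[[1]]))
    expect_gt(rate_hat, 0.01)
    expect_lt(rate_hat, 0.03)
})

test_that("the packaged PSF-dependence fixture matches its published values", {
    fx <- psfEventFixture()
    expect_equal(nrow(fx), 39)
    expect_equal(unname(as.vector(as.matrix(
        fx[fx$event_id == "LEF1", c("WT_U", "WT_S", "PSF_KD_S")]))),
        c(36L, 88L, 48L))
    expect_equal(unname(as.vector(as.matrix(
        fx[fx$event_id == "OPA1", c("WT_U", "WT_S", "PSF_KD_S")]))),
        c(52L, 33L, 75L))
    # the SNHG3-RCC1 locus contributes two distinct events
    snhg <- fx[fx$gene_symbol == "SNHG3-RCC1", ]
    expect_equal(nrow(snhg), 2)
    expect_setequal(snhg$event_id, c("SNHG3-RCC1.a", "SNHG3-RCC1.b"))
    expect_false(anyDuplicated(fx$event_id) > 0)
})
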