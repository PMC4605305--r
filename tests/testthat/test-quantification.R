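test_that("PSI is the long-isoform read percentage, undefined at zero depth", {
    lib <- manual_library()
    ss <- manual_samples()
    long <- matrix(c(88L, 1L, 0L, 0L), 2, 2)
    short <- matrix(c(12L, 3L, 50L, 0L), 2, 2)
    psi <- psiValues(computePsi(RaslCountSet(long, short, lib, ss)))
    expect_equal(psi["evA", "WT_U_rep1"], 88)
    expect_equal(psi["evB", "WT_U_rep1"], 25)
    expect_equal(psi["evA", "WT_S_rep1"], 0)
    expect_true(is.na(psi["evB", "WT_S_rep1"]))   # 0/0 coverage
})

test_that("swapping isoform orientation complements PSI to 100", {
    lib <- tiny_library(n = 25)
    ss <- tiny_samples()
    cs <- simulateCounts(lib, ss, 37, mean_depth = 30, seed = 81)
    fwd <- psiValues(computePsi(cs))
    swapped <- RaslCountSet(shortCounts(cs), longCounts(cs),
                            ProbeLibrary(lib$event_id, lib$gene_symbol,
                                         lib$short_junction_seq,
                                         lib$long_junction_seq), ss)
    rev <- psiValues(computePsi(swapped))
    defined <- !is.na(fwd)
    expect_equal(fwd[defined] + rev[defined],
                 rep(100, sum(defined)))
})

test_that("the coverage filter keeps events at mean >= threshold, inclusive", {
    lib <- makeProbeLibrary(3, seed = 91, junction_length = 10)
    ss <- makeSampleSheet(c("WT_S", "PSF_KD_S"), replicates = 3, seed = 91)
    # event 1: mean exactly 10; event 2: mean 59/6 ~ 9.83; event 3: rich
    long <- rbind(c(10L, 10L, 10L, 10L, 10L, 10L),
                  c(0L, 0L, 0L, 0L, 0L, 59L),
                  c(30L, 30L, 30L, 30L, 30L, 30L))
    short <- matrix(0L, 3, 6)
    cs <- RaslCountSet(long, short, lib, ss)
    kept <- filterLowCoverage(cs, 10)
    expect_setequal(rownames(kept), lib$event_id[c(1, 3)])
    expect_identical(rownames(filterLowCoverage(cs, 0)), rownames(cs))
})

test_that("the coverage filter is monotone in its threshold", {
    lib <- tiny_library(n = 40)
    ss <- tiny_samples()
    cs <- simulateCounts(lib, ss, 50, mean_depth = 12, dispersion = 2,
                         seed = 92)
    prev <- rownames(filterLowCoverage(cs, 0))
    for (th in c(5, 10, 15, 25)) {
        cur <- rownames(filterLowCoverage(cs, th))
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("delta PSI follows the first-minus-second sign convention", {
    fx <- psfEventFixture()
    dp <- deltaPsi(fx, "WT_S", "PSF_KD_S")
    expect_equal(dp$delta_psi[dp$event_id == "LEF1"], 40)
    expect_equal(dp$delta_psi[dp$event_id == "OPA1"], -42)
    expect_true(all(abs(dp$delta_psi) <= 100))
    self <- deltaPsi(fx, "WT_S", "WT_S")
    expect_true(all(self$delta_psi == 0))
    expect_error(deltaPsi(fx, "WT_S", "TRAP150_KD_U"), "TRAP150_KD_U")
})

test_that("the Welch test matches its closed form and stats::t.test", {
    # hand-computed oracle for (10,11,12) vs (30,31,32):
    # means 11/31, variances 1/1, se^2 = 2/3, t = -20/sqrt(2/3), df = 4
    t_stat <- -20 / sqrt(2 / 3)
    p_oracle <- 2 * pt(t_stat, df = 4)
    expect_equal(testPsiDifference(c(10, 11, 12), c(30, 31, 32)), p_oracle)
    # cross-check against stats::t.test over random replicate sets
    set.seed(101)
    for (i in 1:25) {
        a <- runif(sample(2:5, 1), 0, 100)
        b <- runif(sample(2:5, 1), 0, 100)
        expect_equal(testPsiDifference(a, b),
                     t.test(a, b, var.equal = FALSE)$p.value)
    }
})

test_that("degenerate Welch inputs have defined answers", {
    expect_equal(testPsiDifference(c(10, 10, 10), c(10, 10, 10)), 1)
    expect_equal(testPsiDifference(c(10, 11, 12), c(10, 11, 12)), 1)
    expect_equal(testPsiDifference(c(10, 10, 10), c(20, 20, 20)), 0)
    expect_true(is.na(testPsiDifference(5, c(1, 2, 3))))
    expect_true(is.na(testPsiDifference(c(5, NA), c(1, 2, 3))))
})

test_that("per-event testing runs over a RaslPsiSet and flags untestables", {
    lib <- tiny_library(n = 8)
    ss <- tiny_samples(replicates = 3)
    tp <- matrix(c(rep(50, 8), rep(50, 8), rep(20, 8)), 8, 3,
                 dimnames = list(NULL, c("WT_U", "WT_S", "PSF_KD_S")))
    cs <- simulateCounts(lib, ss, tp, mean_depth = 400, seed = 103)
    psi <- computePsi(cs)
    p <- psiDifferenceTest(psi, "WT_S", "PSF_KD_S")
    expect_length(p, 8)
    expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
    expect_true(median(p) < 0.05)   # 30-point true shift at depth 400
    expect_error(psiDifferenceTest(psi, "WT_S", "TRAP150_KD_U"),
                 "TRAP150_KD_U")
})

test_that("condition means average only the defined replicates", {
    lib <- manual_library()
    ss <- RaslSamples(genotype = rep("WT", 3), stimulation = rep("S", 3),
                      replicate = 1:3,
                      barcode = c("AAAA", "CCCC", "GGGG"))
    long <- rbind(c(80L, 60L, 0L), c(10L, 10L, 10L))
    short <- rbind(c(20L, 40L, 0L), c(30L, 30L, 30L))
    psi <- computePsi(RaslCountSet(long, short, lib, ss))
    m <- conditionMeans(psi)
    expect_equal(unname(m$WT_S[1]), 70)   # zero-coverage replicate excluded
    expect_equal(unname(m$WT_S[2]), 25)
    expect_equal(unname(replicatesUsed(psi)[, "WT_S"]), c(2L, 3L))
})
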