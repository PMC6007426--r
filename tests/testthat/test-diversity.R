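# Diversity and differentiation estimators against closed forms, brute
# force, and an independently written Weir-Cockerham implementation.

test_that("sliding windows follow the closed-form count and bounds", {
    w <- makeWindows(c(sc1 = 25000L))
    expect_equal(length(w), 4L)
    expect_equal(start(w), c(1L, 5001L, 10001L, 15001L))
    expect_equal(width(w), rep(10000L, 4))
    # scaffolds of exactly the minimum length yield nothing
    expect_equal(length(makeWindows(c(sc1 = 10000L))), 0L)
    set.seed(2)
    lens <- setNames(sample.int(80000L, 30L), paste0("s", 1:30))
    w <- makeWindows(lens)
    cnt <- table(factor(as.character(seqnames(w)), names(lens)))
    closed <- ifelse(lens > 10000L, pmax(0L, (lens - 10000L) %/% 5000L + 1L),
                     0L)
    expect_equal(as.integer(cnt), as.integer(closed))
})

test_that("per-site pi equals the mean pairwise difference, exhaustively", {
    expect_equal(piSite(4, 2), 2 * 2 * 2 / (4 * 3))
    expect_equal(piSite(6, 0), 0)
    expect_equal(piSite(6, 6), 0)
    expect_true(is.na(piSite(1, 0)))
    for (n in 2:12) for (j in 0:n) {
        hap <- c(rep(1, j), rep(0, n - j))
        pairs <- combn(n, 2)
        brute <- mean(abs(hap[pairs[1, ]] - hap[pairs[2, ]]))
        expect_equal(piSite(n, j), brute)
    }
})

test_that("site allele counts follow the diploid conventions", {
    co <- toyCohort(rbind(c(0L, 1L, 2L), c(NA, NA, NA)))
    ac <- siteAlleleCounts(co)
    expect_equal(ac$nHap, c(6L, 0L))
    expect_equal(ac$altCount, c(3L, 0L))
    expect_equal(ac$hetCount, c(1L, 0L))
    set.seed(4)
    gt <- matrix(sample(c(0:2, NA), 200, TRUE), 20, 10)
    ac <- siteAlleleCounts(toyCohort(gt))
    for (i in 1:20) {
        g <- gt[i, ][!is.na(gt[i, ])]
        expect_equal(ac$nHap[i], 2L * length(g))
        expect_equal(ac$altCount[i], sum(g))
        expect_equal(ac$hetCount[i], sum(g == 1))
    }
})

test_that("Weir-Cockerham components reproduce the hand-worked case", {
    # two populations of 4 diploids fixed for opposite alleles
    gt <- matrix(c(rep(2L, 4), rep(0L, 4)), 1, 8)
    comp <- wcComponents(toyCohort(gt), list(1:4, 5:8))
    expect_equal(comp$a, 0.5)
    expect_equal(comp$b, 0)
    expect_equal(comp$c, 0)
    # identical genotype arrays: no among-population variance
    gt2 <- matrix(rep(c(0L, 1L, 1L, 2L), 2), 1, 8)
    comp2 <- wcComponents(toyCohort(gt2), list(1:4, 5:8))
    expect_lte(comp2$a, 0)
})

test_that("Weir-Cockerham components match the independent oracle", {
    set.seed(9)
    n <- 1000L
    gt <- matrix(sample(c(0:2, NA), n * 12, TRUE,
                        prob = c(.4, .25, .25, .1)), n, 12)
    co <- toyCohort(gt, pos = seq_len(n))
    pops <- list(1:5, 6:9, 10:12)
    comp <- wcComponents(co, pops)
    oracle <- t(vapply(seq_len(n), function(i) wc_oracle(gt[i, ], pops),
                       numeric(3)))
    expect_equal(comp$a, oracle[, 1], tolerance = 1e-12)
    expect_equal(comp$b, oracle[, 2], tolerance = 1e-12)
    expect_equal(comp$c, oracle[, 3], tolerance = 1e-12)
})

test_that("windowed FST is the ratio of sums and handles edge windows", {
    # all sites fixed-different -> theta-hat = 1
    gt <- matrix(rep(c(rep(2L, 3), rep(0L, 3)), 5), 5, 6, byrow = TRUE)
    co <- toyCohort(gt, pos = c(10L, 20L, 30L, 40L, 50L))
    w <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 10000))
    expect_equal(windowFst(co, list(1:3, 4:6), w), 1)
    # identical allele frequencies -> theta-hat <= 0
    gt2 <- matrix(rep(c(0L, 1L, 2L, 0L, 1L, 2L), 5), 5, 6, byrow = TRUE)
    co2 <- toyCohort(gt2, pos = c(10L, 20L, 30L, 40L, 50L))
    expect_lte(windowFst(co2, list(1:3, 4:6), w), 0)
    # window with no sites is undefined
    w2 <- GenomicRanges::GRanges("sc1", IRanges::IRanges(5001, 15000))
    expect_true(is.na(windowFst(co, list(1:3, 4:6), w2)))
})

test_that("ratio-of-sums differs from mean-of-ratios and is order-invariant", {
    set.seed(12)
    gt <- matrix(sample(0:2, 40 * 10, TRUE), 40, 10)
    co <- toyCohort(gt, pos = seq_len(40) * 10L)
    pops <- list(1:5, 6:10)
    w <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 10000))
    comp <- wcComponents(co, pops)
    den <- comp$a + comp$b + comp$c
    ok <- !is.na(den) & den != 0
    ratio_of_sums <- sum(comp$a[ok]) / sum(den[ok])
    mean_of_ratios <- mean((comp$a / den)[ok])
    expect_equal(windowFst(co, pops, w), ratio_of_sums, tolerance = 1e-12)
    expect_false(isTRUE(all.equal(ratio_of_sums, mean_of_ratios)))
    # permuting site order changes nothing
    perm <- sample(40)
    co_perm <- toyCohort(gt[perm, ], pos = (seq_len(40) * 10L)[perm])
    expect_equal(windowFst(co_perm, pops, w), ratio_of_sums,
                 tolerance = 1e-12)
    # the genome-wide estimator equals one whole-genome window
    expect_equal(globalFst(co, pops), ratio_of_sums, tolerance = 1e-12)
})

test_that("windowed pi divides summed site diversity by window length", {
    gt <- matrix(c(1L, 1L, 0L, 0L), 1, 4)   # n=8, j=2
    co <- toyCohort(gt, pos = 500L)
    w <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 10000))
    expect_equal(windowPi(co, 1:4, w), piSite(8, 2) / 10000)
    # window with no SNPs -> 0
    w2 <- GenomicRanges::GRanges("sc1", IRanges::IRanges(20001, 30000))
    expect_equal(windowPi(co, 1:4, w2), 0)
})

test_that("Z-standardization matches hand arithmetic and is idempotent", {
    zs <- zStandardize(c(0.1, 0.2, 0.3))
    expect_equal(zs$z, c(-1, 0, 1))
    expect_equal(zs$mu, 0.2)
    expect_equal(zs$sigma, 0.1)
    # an extreme window on the genome-wide scale of the emulated study:
    # FST 0.69 against mu = 0.1154, sigma = 0.0678
    expect_equal((0.69 - 0.1154) / 0.0678, 8.47493, tolerance = 1e-5)
    z2 <- zStandardize(zs$z)
    expect_equal(z2$z, zs$z, tolerance = 1e-12)
    expect_error(zStandardize(c(1, 1, 1)), "zero")
    expect_error(zStandardize(c(1, NA)), "2 defined")
})

test_that("per-sample heterozygosity counts and ratios are correct", {
    gt <- cbind(rep(0L, 4), c(1L, 1L, 1L, 2L))
    st <- sampleHetStats(toyCohort(gt))
    expect_equal(st$perSample$nSnp, c(0L, 4L))
    expect_equal(st$perSample$hetHomRatio, c(NA, 3))
})

test_that("equilibrium FST decreases with symmetric migration rate", {
    Ms <- c(0.5, 2, 8)
    fst <- vapply(Ms, function(M) {
        mig <- array(0, c(2, 2, 1)); mig[1, 2, 1] <- M; mig[2, 1, 1] <- M
        m <- epochModel(0, matrix(1, 2, 1), mig)
        set.seed(100 + round(10 * M))
        gts <- lapply(1:150, function(i) simulateLocus(m, c(10, 10), 2))
        gt <- do.call(rbind, gts)
        gt <- gt[, seq(1, 20, 2)] + gt[, seq(2, 20, 2)]
        co <- toyCohort(gt, pos = seq_len(nrow(gt)))
        globalFst(co, list(1:5, 6:10))
    }, numeric(1))
    expect_true(all(diff(fst) < 0))
    expect_lt(cor(Ms, fst, method = "spearman"), 0)
})
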