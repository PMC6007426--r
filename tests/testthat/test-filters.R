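# QC filters checked against stated thresholds and brute-force oracles.

test_that("SNP hard filter applies the six strict inequalities", {
    qc <- list(QUAL = c(31, 31, 29), QD = c(6, 4, 6), FS = c(10, 10, 10),
               MQ = c(50, 50, 50), MQRankSum = c(0, 0, 0),
               ReadPosRankSum = c(0, 0, 0))
    co <- toyCohort(matrix(1L, 3, 2), qc = qc)
    res <- filterSnpsHard(co)
    expect_equal(nrow(res$cohort), 1L)      # QD=4 and QUAL=29 removed
    expect_equal(res$report$tested, 3L)
    expect_equal(res$report$passed + res$report$failed, res$report$tested)
})

test_that("INDEL hard filter applies its four criteria and spares SNPs", {
    co <- toyCohort(matrix(1L, 3, 1),
                    ref = c("AT", "AT", "A"), alt = c("A", "A", "G"),
                    qc = list(QUAL = c(100, 100, 5), QD = c(10, 10, 1),
                              FS = c(250, 50, 500),
                              ReadPosRankSum = c(-1, -1, -30)))
    res <- filterIndelsHard(co)
    # FS=250 INDEL removed; passing INDEL kept; SNP untouched by this filter
    expect_equal(nrow(res$cohort), 2L)
    expect_equal(sum(variantClass(res$cohort) == "SNP"), 1L)
})

test_that("hard filters match a brute-force oracle on random annotations", {
    set.seed(11)
    n <- 40L
    qc <- list(QUAL = round(runif(n, 20, 50), 1),
               QD = round(runif(n, 0, 10), 1),
               FS = round(runif(n, 0, 300), 1),
               MQ = round(runif(n, 30, 50), 1),
               MQRankSum = round(runif(n, -20, 5), 1),
               ReadPosRankSum = round(runif(n, -30, 5), 1))
    indel <- seq_len(n) > 20
    co <- toyCohort(matrix(1L, n, 2), ref = ifelse(indel, "AT", "A"),
                    alt = ifelse(indel, "A", "G"), qc = qc)
    keep_snp <- with(qc, QUAL > 30 & QD > 5 & FS < 60 & MQ > 40 &
                         MQRankSum > -12.5 & ReadPosRankSum > -8)
    keep_ind <- with(qc, QUAL > 30 & QD > 5 & FS < 200 &
                         ReadPosRankSum > -20)
    expected <- ifelse(indel, keep_ind, keep_snp)
    got <- filterIndelsHard(filterSnpsHard(co)$cohort)$cohort
    expect_equal(nrow(got), sum(expected))
    expect_equal(start(rowRanges(got)),
                 start(rowRanges(co))[expected])
    # idempotence
    again <- filterIndelsHard(filterSnpsHard(got)$cohort)$cohort
    expect_equal(nrow(again), nrow(got))
})

test_that("records lacking an annotation pass by default, drop on request", {
    co <- toyCohort(matrix(1L, 2, 1),
                    qc = list(QUAL = c(50, 50), QD = c(NA, 10),
                              FS = c(1, 1), MQ = c(50, 50),
                              MQRankSum = c(0, 0),
                              ReadPosRankSum = c(0, 0)))
    expect_warning(res <- filterSnpsHard(co), "QD")
    expect_equal(nrow(res$cohort), 2L)
    res2 <- suppressWarnings(filterSnpsHard(co, missingPasses = FALSE))
    expect_equal(nrow(res2$cohort), 1L)
})

test_that("clustered SNPs are removed when more than 3 share a 10-bp span", {
    co <- toyCohort(matrix(1L, 4, 1), pos = c(100L, 102L, 104L, 108L))
    res <- filterSnpClusters(co)
    expect_equal(nrow(res$cohort), 0L)      # 4 SNPs spanning 9 bp
    co3 <- toyCohort(matrix(1L, 3, 1), pos = c(100L, 105L, 109L))
    expect_equal(nrow(filterSnpClusters(co3)$cohort), 3L)
})

test_that("cluster removal equals the O(n^2) interval oracle", {
    set.seed(5)
    pos <- sort(sample.int(1000L, 200L))
    co <- toyCohort(matrix(1L, 200, 1), pos = pos)
    res <- filterSnpClusters(co)
    bad <- vapply(pos, function(p) {
        any(vapply((p - 9L):p, function(x)
            sum(pos >= x & pos <= x + 9L) > 3L, logical(1)))
    }, logical(1))
    expect_equal(start(rowRanges(res$cohort)), pos[!bad])
    # idempotent
    expect_equal(nrow(filterSnpClusters(res$cohort)$cohort),
                 nrow(res$cohort))
})

test_that("alternate-depth filter keeps the equality boundary", {
    gt <- matrix(c(1L, 1L, 0L), 3, 1)
    dp <- matrix(c(20L, 20L, 20L), 3, 1)
    adAlt <- matrix(c(10, 5, 0), 3, 1)
    co <- toyCohort(gt, dp = dp, adAlt = adAlt, adRef = dp - adAlt)
    res <- filterAlleleDepth(co)
    # site 1: alt depth 10 == 0.5 * 20 -> kept; site 2: 5 < 10 -> removed;
    # site 3: no carrier -> passed through
    expect_equal(start(rowRanges(res$cohort)),
                 start(rowRanges(co))[c(1, 3)])
})

test_that("alternate-depth filter matches its brute-force oracle", {
    set.seed(21)
    n <- 60L; ns <- 5L
    gt <- matrix(sample(c(0:2, NA), n * ns, TRUE), n, ns)
    dp <- matrix(rpois(n * ns, 10) + 1L, n, ns)
    adAlt <- matrix(rbinom(n * ns, as.vector(dp), runif(n * ns)), n, ns)
    co <- toyCohort(gt, dp = dp, adAlt = adAlt, adRef = dp - adAlt)
    res <- filterAlleleDepth(co)
    keep <- vapply(seq_len(n), function(i) {
        car <- which(!is.na(gt[i, ]) & gt[i, ] > 0)
        if (!length(car)) return(TRUE)
        sum(adAlt[i, car]) >= 0.5 * sum(dp[i, car])
    }, logical(1))
    expect_equal(nrow(res$cohort), sum(keep))
    expect_warning(filterAlleleDepth(toyCohort(gt)), "skipped")
})

test_that("structure-site filter excludes MAF and call-rate boundaries", {
    # 10 diploids; alt count 2/20 => MAF exactly 0.1 -> removed
    gt1 <- matrix(0L, 1, 10); gt1[1, 1:2] <- 1L
    expect_equal(nrow(filterStructureSites(toyCohort(gt1))$cohort), 0L)
    # call rate exactly 0.9 (9/10 called) -> removed even with high MAF
    gt2 <- matrix(c(rep(1L, 9), NA), 1, 10)
    expect_equal(nrow(filterStructureSites(toyCohort(gt2))$cohort), 0L)
    # passing site
    gt3 <- matrix(c(rep(1L, 5), rep(0L, 5)), 1, 10)
    expect_equal(nrow(filterStructureSites(toyCohort(gt3))$cohort), 1L)
})

test_that("structure-site survivors match the oracle on random data", {
    set.seed(31)
    n <- 80L; ns <- 10L
    gt <- matrix(sample(c(0:2, NA), n * ns, TRUE,
                        prob = c(.45, .25, .2, .1)), n, ns)
    co <- toyCohort(gt)
    res <- filterStructureSites(co)
    keep <- vapply(seq_len(n), function(i) {
        x <- gt[i, ]; called <- sum(!is.na(x))
        if (called == 0) return(FALSE)
        af <- sum(x, na.rm = TRUE) / (2 * called)
        min(af, 1 - af) > 0.1 && called / ns > 0.9
    }, logical(1))
    expect_equal(nrow(res$cohort), sum(keep))
})

test_that("filter chaining reports tested(k+1) == passed(k)", {
    co <- randomCohort(120L, 6L, seed = 3L)
    res <- filterVariants(co, steps = c("snp_hard", "indel_hard", "cluster",
                                        "depth"))
    rep <- res$report
    expect_equal(rep$tested[-1], rep$passed[-nrow(rep)])
    expect_equal(rep$passed[nrow(rep)], nrow(res$cohort))
})
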