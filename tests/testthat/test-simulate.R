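# Generator contracts: determinism, structure, neutral theory, sweep and
# diagnostic injection, demographic direction of heterozygosity.

test_that("genealogy summaries match coalescent expectations", {
    m <- epochModel(0, matrix(1, 1, 1))
    st <- simulateGenealogyStats(m, 2, nReps = 4000L, seed = 1)
    se <- sd(st$tmrca) / sqrt(nrow(st))
    expect_lt(abs(mean(st$tmrca) - 1), 3 * se)   # E[T2] = 2N generations
    # two demes without migration cannot coalesce before the join time
    m2 <- epochModel(c(0, 0.7), matrix(1, 2, 2),
                     remap = cbind(c(1L, 2L), c(1L, 1L)))
    st2 <- simulateGenealogyStats(m2, c(1, 1), nReps = 500L, seed = 2)
    expect_true(all(st2$tmrca >= 0.7))
})

test_that("mutation dropping follows E[S] = theta * a_n and E[pi] = theta", {
    m <- epochModel(0, matrix(1, 1, 1))
    # E[S] for n = 10 haplotypes
    theta <- 5
    set.seed(3)
    S <- replicate(1500, nrow(simulateLocus(m, 10, theta)))
    an <- sum(1 / (1:9))
    se <- sd(S) / sqrt(length(S))
    expect_lt(abs(mean(S) - theta * an), 3 * se)
    # E[pairwise difference per site] = theta per site
    set.seed(4)
    L <- 1000; th_site <- 0.02
    d <- replicate(600, {
        g <- simulateLocus(m, 2, th_site * L)
        if (nrow(g) == 0) 0 else sum(g[, 1] != g[, 2])
    })
    se <- sd(d / L) / sqrt(length(d))
    expect_lt(abs(mean(d / L) - th_site), 3 * se)
    expect_equal(nrow(simulateLocus(m, 10, 0)), 0L)   # theta = 0
})

test_that("between-population divergence adds the split time", {
    # split at T = 0.5: E[cross-pop difference per site] = theta * (1 + T)
    m <- epochModel(c(0, 0.5), matrix(1, 2, 2),
                    remap = cbind(c(1L, 2L), c(1L, 1L)))
    set.seed(5)
    L <- 1000; th_site <- 0.02
    d <- replicate(600, {
        g <- simulateLocus(m, c(1, 1), th_site * L)
        if (nrow(g) == 0) 0 else sum(g[, 1] != g[, 2])
    })
    se <- sd(d / L) / sqrt(length(d))
    expect_lt(abs(mean(d / L) - th_site * 1.5), 3 * se)
})

test_that("the folded spectrum of a constant-size population is neutral", {
    m <- epochModel(0, matrix(1, 1, 1))
    n <- 10
    set.seed(6)
    # one SNP per genealogy so the chi-square sees independent sites
    g <- do.call(rbind, lapply(1:800, function(i) {
        x <- simulateLocus(m, n, 1.5)
        if (nrow(x) == 0) NULL else x[sample.int(nrow(x), 1), , drop = FALSE]
    }))
    j <- rowSums(g)
    fold <- pmin(j, n - j)
    counts <- tabulate(fold, n %/% 2)
    eta <- vapply(1:(n %/% 2), function(i)
        (1 / i + 1 / (n - i)) / (1 + (i == n - i)), numeric(1))
    p <- chisq.test(counts, p = eta / sum(eta))$p.value
    expect_gt(p, 0.001)
})

test_that("the same seed reproduces the simulation byte for byte", {
    cfg <- function() simulationConfig(popTable = smallPopTable(),
                                       nScaffolds = 2L,
                                       scaffoldLength = 40000L, seed = 77L)
    s1 <- simulateCohort(cfg()); s2 <- simulateCohort(cfg())
    p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
    writeVcfCohort(s1$cohort, p1); writeVcfCohort(s2$cohort, p2)
    expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
    # a unit sweep factor is a no-op on the random stream and the output
    cfg1 <- simulationConfig(popTable = smallPopTable(), nScaffolds = 2L,
                             scaffoldLength = 40000L, seed = 77L,
                             sweeps = data.frame(scaffold = "scaffold01",
                                                 start = 0L, end = 20000L,
                                                 factor = 1))
    s3 <- simulateCohort(cfg1)
    expect_equal(genotypes(s3$cohort), genotypes(s1$cohort))
})

test_that("cohort structure matches the configuration", {
    pt <- smallPopTable()[c(1, 3), ]   # one wild, one meat population
    pt$nDiploid <- c(2L, 2L)
    cfg <- simulationConfig(popTable = pt, nScaffolds = 1L,
                            scaffoldLength = 100000L, seed = 12L)
    sim <- simulateCohort(cfg)
    expect_equal(ncol(sim$cohort), 4L)
    expect_equal(length(sim$truth$windows), 10L)
    expect_gte(nrow(sim$cohort), 0L)
    expect_equal(sort(unique(populations(sim$cohort))), c("MDN", "PK"))
    # no missingness when the rate is zero
    cfg0 <- simulationConfig(popTable = pt, nScaffolds = 1L,
                            scaffoldLength = 50000L, missingness = 0,
                            seed = 12L)
    expect_false(anyNA(genotypes(simulateCohort(cfg0)$cohort)))
    # windows are exchangeable: permuting rows leaves window stats alone
    co <- sim$cohort
    set.seed(1)
    perm <- sample(nrow(co))
    co2 <- VariantCohort(genotypes(co)[perm, ], rowRanges(co)[perm])
    w <- makeWindows(scaffoldLengths(co))
    expect_equal(windowPi(co2, 1:4, w), windowPi(co, 1:4, w))
})

test_that("QC annotations are synthesized in passing ranges, or failing", {
    sim <- mediumSim()
    f <- filterVariants(sim$cohort)
    expect_equal(nrow(f$cohort), nrow(sim$cohort))   # all pass by design
    cfgF <- simulationConfig(popTable = smallPopTable(), nScaffolds = 1L,
                             scaffoldLength = 50000L, qcFailRate = 0.3,
                             seed = 13L)
    simF <- simulateCohort(cfgF)
    fF <- filterVariants(simF$cohort)
    expect_lt(nrow(fF$cohort), nrow(simF$cohort))
})

test_that("a domestication-shaped model lowers domestic diversity", {
    sim <- mediumSim()
    co <- sim$cohort
    wild <- sampleIndices(co, group = "wild")
    dom <- setdiff(seq_len(ncol(co)), wild)
    w <- sim$truth$windows
    piW <- windowPi(co, wild, w)
    piD <- windowPi(co, dom, w)
    expect_gt(mean(piW) / mean(piD), 1)
    # bottlenecked populations also show lower het/hom ratios
    hs <- sampleHetStats(co)$perPopulation
    wildPops <- c("MDN", "MDZ")
    expect_gt(mean(hs$hetHomRatio[hs$population %in% wildPops]),
              mean(hs$hetHomRatio[!hs$population %in% wildPops]))
})

test_that("sweep injection reduces domestic diversity in the swept span", {
    sw <- data.frame(scaffold = "scaffold01", start = 0L, end = 125000L,
                     factor = 10)
    cfg <- simulationConfig(popTable = smallPopTable(), nScaffolds = 2L,
                            scaffoldLength = 125000L, windowBp = 5000L,
                            sweeps = sw, seed = 31L)
    sim <- simulateCohort(cfg)
    co <- sim$cohort
    dom <- setdiff(seq_len(ncol(co)),
                   sampleIndices(co, group = "wild"))
    w <- sim$truth$windows
    lab <- S4Vectors::mcols(w)$label
    piD <- windowPi(co, dom, w)
    expect_equal(sum(lab == "sweep"), 25L)
    p <- suppressWarnings(
        wilcox.test(piD[lab == "sweep"], piD[lab == "neutral"],
                    alternative = "less"))$p.value
    expect_lt(p, 0.01)
})

test_that("diagnostic injection shifts off occupied positions with a note", {
    cfgA <- simulationConfig(popTable = smallPopTable(), nScaffolds = 1L,
                             scaffoldLength = 30000L, seed = 41L)
    simA <- simulateCohort(cfgA)
    taken <- start(rowRanges(simA$cohort))[1]
    cfgB <- simulationConfig(popTable = smallPopTable(), nScaffolds = 1L,
                             scaffoldLength = 30000L, seed = 41L,
                             diagnostic = list(scaffold = "scaffold01",
                                               positions = taken,
                                               scheme = "plumage",
                                               group = "white"))
    expect_message(simB <- simulateCohort(cfgB), "shifted")
    newPos <- start(simB$truth$diagnostics)
    expect_false(newPos == taken)
    # neutral data yields essentially no diagnostic hits
    white <- sampleIndices(simA$cohort, group = "white", scheme = "plumage")
    other <- setdiff(seq_len(ncol(simA$cohort)), white)
    dv <- diagnosticVariants(simA$cohort, white, other, minCalled = 6L)
    expect_lte(length(dv), 2L)
})

test_that("simulation files land on disk in the documented formats", {
    sim <- mediumSim()
    prefix <- file.path(tempdir(), "simout")
    paths <- writeSimulation(sim, prefix)
    expect_true(all(file.exists(paths)))
    pm <- readPopmap(paths[["popmap"]])
    expect_equal(nrow(pm), ncol(sim$cohort))
    genes <- readGeneTrack(paths[["genes"]])
    expect_gt(length(genes), 0L)
    truth <- jsonlite::read_json(paths[["truth"]])
    expect_equal(length(truth$windows), length(sim$truth$windows))
})
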