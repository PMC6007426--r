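# Scenario construction, expected spectra, composite likelihood, AIC,
# unit scaling, bootstrap.

test_that("scenarios validate parameter completeness and event order", {
    dm <- duckDomesticationModel()
    ep <- compileEpochs(dm$model)
    # event order backwards: breed divergence, domestication, size change
    expect_equal(ep$epochStart,
                 c(0, dm$model@params[["TDIV"]], dm$model@params[["TDOM"]],
                   dm$model@params[["TA"]]))
    expect_equal(ep$remap[, 2], c(1L, 2L, 2L))   # eggdp joins meat
    expect_equal(ep$remap[, 3], c(1L, 1L, 1L))   # domestic joins wild
    p <- dm$model@params
    # ordering guards
    bad <- p; bad["TDIV"] <- bad[["TDOM"]] + 0.001
    expect_error(buildModel("model2", bad), "TDIV < TDOM")
    p3 <- c(p[c("nuA", "nuW", "nuM", "nuE", "TA", "MWM", "MWE")],
            TM = 0.008, TE = 0.012)
    expect_error(buildModel("model3", p3), "meat")
    expect_silent(buildModel("model4", p3))
    expect_error(buildModel("model1", p[c("nuA", "nuW")]), "missing")
    # model1 is the trifurcation: one fewer time parameter than model2
    m1 <- buildModel("model1", c(p[c("nuA", "nuW", "nuM", "nuE", "TA",
                                     "MWM", "MWE")], TDOM = p[["TDOM"]]))
    expect_equal(length(m1@params), length(dm$model@params) - 2L)
    expect_equal(length(compileEpochs(m1)$epochStart), 3L)
})

test_that("expected folded SFS matches the standard neutral closed form", {
    m <- epochModel(0, matrix(1, 1, 1))
    sfs <- expectedSfs(m, 4, nReps = 50000L, seed = 2)
    # unfolded xi_i ~ 1/i folds to (8/11, 3/11) for n = 4
    expect_equal(as.vector(sfs@mass[!sfs@mask]), c(8, 3) / 11,
                 tolerance = 0.02)
    expect_equal(sum(sfs@mass[!sfs@mask]), 1, tolerance = 1e-12)
})

test_that("a two-population split at time zero is the pooled panmictic SFS", {
    m <- epochModel(c(0, 1e-9), matrix(1, 2, 2),
                    remap = cbind(c(1L, 2L), c(1L, 1L)))
    joint <- expectedSfs(m, c(4, 4), nReps = 60000L, seed = 3)
    # pool the joint spectrum by total minor-allele count
    tot <- outer(0:4, 0:4, "+")
    pooled <- vapply(1:4, function(k)
        sum(joint@mass[tot == k][!joint@mask[tot == k]]), numeric(1))
    m1 <- epochModel(0, matrix(1, 1, 1))
    pan <- expectedSfs(m1, 8, nReps = 60000L, seed = 4)
    expect_equal(pooled, as.vector(pan@mass[!pan@mask]),
                 tolerance = 0.02)
})

test_that("composite log-likelihood follows the Poisson cell formula", {
    # single informative cell with obs = 2 and model mass 2:
    # 2 ln 2 - 2 - ln 2! = -1.30685
    mk <- function(mass) {
        arr <- array(c(0, mass, 0), 3)
        mask <- array(c(TRUE, FALSE, TRUE), 3)
        new("FoldedSFS", mass = arr, mask = mask, projections = 2L,
            popNames = "p", nSkipped = 0L)
    }
    cl <- compositeLogLik(mk(2), mk(1))
    expect_equal(cl$theta, 2)
    expect_equal(cl$loglik, 2 * log(2) - 2 - lgamma(3), tolerance = 1e-12)
    expect_equal(cl$loglik, -1.3068528, tolerance = 1e-6)
    expect_error(compositeLogLik(mk(2),
        new("FoldedSFS", mass = array(0, c(3, 3)),
            mask = array(TRUE, c(3, 3)), projections = c(2L, 2L),
            popNames = c("a", "b"), nSkipped = 0L)), "mismatch")
})

test_that("the likelihood is self-maximizing at the observed proportions", {
    set.seed(10)
    m <- epochModel(0, matrix(1, 1, 1))
    truth <- expectedSfs(m, 8, nReps = 40000L, seed = 5)
    obs <- truth
    obs@mass[!obs@mask] <- truth@mass[!truth@mask] * 5000
    ll_truth <- compositeLogLik(obs, truth)$loglik
    for (i in 1:10) {
        pert <- truth
        p <- truth@mass[!truth@mask] * exp(runif(sum(!truth@mask), -0.5, 0.5))
        pert@mass[!pert@mask] <- p / sum(p)
        expect_lte(compositeLogLik(obs, pert)$loglik, ll_truth)
    }
})

test_that("AIC ranking is arithmetic and parsimony-respecting", {
    mkfit <- function(scen, k, ll)
        new("DemographicFit",
            model = new("DemographicModel", scenario = scen,
                        params = setNames(rep(0.01, k), paste0("p", 1:k)),
                        popNames = "x"),
            free = paste0("p", 1:k), loglik = ll, aic = 2 * k - 2 * ll,
            theta = 1, converged = TRUE, nEval = 1L)
    f1 <- mkfit("model1", 5, -100)
    expect_equal(f1@aic, 210)
    cmp <- compareAic(list(f1, mkfit("model2", 4, -100)))
    expect_equal(cmp$scenario[1], "model2")
    expect_equal(cmp$deltaAIC, c(0, 2))
})

test_that("real-unit scaling follows theta algebra and round-trips", {
    out <- toRealUnits(c(nuW = 1, TDOM = 0), theta = 4000, mu = 1.191e-9,
                       L = 1e9)
    expect_equal(out$Nref[1], 4000 / (4 * 1.191), tolerance = 1e-9)
    expect_equal(out$real[out$parameter == "TDOM"], 0)
    # sizes, times, migration round-trip through the scaling
    Nref <- 1e5
    dm <- duckDomesticationModel(Nref = Nref)
    tab <- toRealUnits(dm$model, Nref = Nref)
    rp <- dm$realParams
    expect_equal(tab$real[tab$parameter == "nuD0"],
                 rp[["NeDomBottleneck"]], tolerance = 1e-12)
    expect_equal(tab$real[tab$parameter == "TDOM"],
                 rp[["TDomesticationYr"]], tolerance = 1e-12)
    expect_equal(tab$real[tab$parameter == "MWE"],
                 rp[["migrantsWildFromEggDp"]], tolerance = 1e-12)
    # inverse mapping
    for (kind in c("size", "time")) {
        v <- 12345.6
        s <- toScaledUnits(v, kind, Nref)
        back <- if (kind == "size") s * Nref else s * 2 * Nref
        expect_equal(back, v, tolerance = 1e-12)
    }
    s <- toScaledUnits(3.92, "migration", Nref,
                       nuRecipient = dm$model@params[["nuW"]])
    expect_equal(s * dm$model@params[["nuW"]] / 2, 3.92, tolerance = 1e-12)
})

test_that("a one-parameter fit recovers the generating value", {
    dm <- duckDomesticationModel()
    truthSfs <- expectedSfs(dm$model, c(8, 8, 8), nReps = 30000L, seed = 21)
    obs <- truthSfs
    obs@mass[!obs@mask] <- truthSfs@mass[!truthSfs@mask] * 1e5
    pf <- profileFit(dm$model, obs, "TDOM", c(0.002, 0.05),
                     nReps = 10000L, seed = 33)
    expect_equal(pf$estimate, dm$model@params[["TDOM"]], tolerance = 0.05)
    # bounds excluding the truth pin the estimate at the boundary
    fit <- fitModel(dm$model, obs, "TDOM",
                    lower = c(TDOM = 0.03), upper = c(TDOM = 0.08),
                    nReps = 5000L, seed = 33, restarts = 2L, maxit = 40L)
    expect_equal(fit@model@params[["TDOM"]], 0.03, tolerance = 0.15)
    expect_equal(fit@aic, 2 * 1 - 2 * fit@loglik)
})

test_that("scaffold bootstrap is seeded and flags degenerate designs", {
    sim <- mediumSim()
    co <- sim$cohort
    pops <- list(wild = sampleIndices(co, group = "wild"),
                 meat = sampleIndices(co, group = "meat"),
                 eggdp = sampleIndices(co, group = c("egg", "dual-purpose")))
    dm <- duckDomesticationModel()
    args <- list(cohort = co, popIndices = pops, projections = c(8, 8, 8),
                 model = dm$model, free = "TDOM",
                 lower = c(TDOM = 1e-3), upper = c(TDOM = 0.08),
                 nBoot = 3L, seed = 11L, nReps = 1500L, restarts = 1L,
                 maxit = 25L)
    b1 <- do.call(bootstrapCi, args)
    b2 <- do.call(bootstrapCi, args)
    expect_equal(b1$replicates, b2$replicates)
    expect_lte(b1$ci$lower, b1$ci$upper)
    oneScaffold <- co[as.character(seqnames(rowRanges(co))) ==
                      "scaffold01", ]
    args$cohort <- oneScaffold; args$nBoot <- 2L
    expect_warning(do.call(bootstrapCi, args), "degenerate")
})
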