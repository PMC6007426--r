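# Fixtures are built in code; no binary data.

# Small explicit cohort: gt is variants x samples (0/1/2/NA), pos 1-based.
toyCohort <- function(gt, pos = seq_len(nrow(gt)) * 100L, scaffold = "sc1",
                      slen = 1e6L, ref = NULL, alt = NULL, qc = NULL,
                      adRef = NULL, adAlt = NULL, dp = NULL) {
    gt <- as.matrix(gt)
    n <- nrow(gt)
    if (is.null(colnames(gt)))
        colnames(gt) <- paste0("S", seq_len(ncol(gt)))
    if (is.null(ref)) ref <- rep("A", n)
    if (is.null(alt)) alt <- rep("G", n)
    scaffold <- rep(scaffold, length.out = n)
    sl <- setNames(rep(slen, length(unique(scaffold))), unique(scaffold))
    gr <- GenomicRanges::GRanges(
        scaffold, IRanges::IRanges(pos, width = 1L),
        seqinfo = GenomeInfoDb::Seqinfo(names(sl), unname(sl)))
    mc <- S4Vectors::DataFrame(REF = ref, ALT = alt)
    if (!is.null(qc)) for (nm in names(qc)) mc[[nm]] <- qc[[nm]]
    S4Vectors::mcols(gr) <- mc
    VariantCohort(gt, gr, adRef = adRef, adAlt = adAlt, dp = dp)
}

# Random cohort with QC annotations and depths for round-trip tests.
randomCohort <- function(n = 100L, ns = 6L, seed = 1L) {
    set.seed(seed)
    gt <- matrix(sample(c(0:2, NA), n * ns, TRUE,
                        prob = c(.4, .3, .2, .1)), n, ns)
    indel <- runif(n) < 0.2
    ref <- ifelse(indel, "AT", "A")
    alt <- ifelse(indel, "A", "G")
    dp <- matrix(rpois(n * ns, 8) + 1L, n, ns)
    adAlt <- matrix(rbinom(n * ns, as.vector(dp), 0.5), n, ns)
    adAlt[is.na(gt)] <- NA; dp2 <- dp; dp2[is.na(gt)] <- NA
    toyCohort(gt, pos = sort(sample.int(1e5, n)),
              ref = ref, alt = alt,
              qc = list(QUAL = round(runif(n, 20, 900), 2),
                        QD = round(runif(n, 0, 35), 2),
                        FS = round(runif(n, 0, 250), 2),
                        MQ = round(runif(n, 20, 60), 2),
                        MQRankSum = round(runif(n, -15, 3), 2),
                        ReadPosRankSum = round(runif(n, -25, 3), 2),
                        DP = as.numeric(rowSums(dp))),
              adRef = dp - adAlt, adAlt = adAlt, dp = dp2)
}

# Nine-population map mirroring the emulated study design: two wild
# mallard populations and seven domesticated (three meat, three egg, one
# dual-purpose).
studyPopmap <- function(nTotal = NULL) {
    pt <- data.frame(
        population = c("MDN", "MDZ", "PK", "CV", "ML", "JD", "SM", "SX",
                       "GY"),
        n = c(8L, 14L, 8L, 8L, 8L, 8L, 8L, 8L, 8L),
        group_production = c("wild", "wild", "meat", "meat", "meat", "egg",
                             "egg", "egg", "dual-purpose"),
        group_plumage = c("nonwhite", "nonwhite", "white", "white", "white",
                          "nonwhite", "nonwhite", "nonwhite", "nonwhite"))
    data.frame(sample = unlist(mapply(function(p, k)
                   paste0(p, "_", seq_len(k)), pt$population, pt$n)),
               population = rep(pt$population, pt$n),
               group_production = rep(pt$group_production, pt$n),
               group_plumage = rep(pt$group_plumage, pt$n),
               row.names = NULL)
}

# Reduced 6-population table for simulations (24 diploids).
smallPopTable <- function() {
    data.frame(
        population = c("MDN", "MDZ", "PK", "CV", "JD", "GY"),
        deme = c("wild", "wild", "meat", "meat", "eggdp", "eggdp"),
        nDiploid = c(4L, 4L, 4L, 4L, 4L, 4L),
        group_production = c("wild", "wild", "meat", "meat", "egg",
                             "dual-purpose"),
        group_plumage = c("nonwhite", "nonwhite", "white", "white",
                          "nonwhite", "nonwhite"),
        stringsAsFactors = FALSE)
}

# Medium simulated cohort, built once per test run and reused.
.fixture_env <- new.env()
mediumSim <- function() {
    if (is.null(.fixture_env$medium)) {
        cfg <- simulationConfig(popTable = smallPopTable(), nScaffolds = 4L,
                                scaffoldLength = 120000L, missingness = 0.02,
                                seed = 424242L)
        .fixture_env$medium <- simulateCohort(cfg)
    }
    .fixture_env$medium
}

expect_same_cohort <- function(a, b) {
    expect_equal(unname(genotypes(a)), unname(genotypes(b)))
    expect_equal(colnames(a), colnames(b))
    expect_equal(as.character(GenomicRanges::seqnames(rowRanges(a))),
                 as.character(GenomicRanges::seqnames(rowRanges(b))))
    expect_equal(GenomicRanges::start(rowRanges(a)),
                 GenomicRanges::start(rowRanges(b)))
    ma <- S4Vectors::mcols(rowRanges(a)); mb <- S4Vectors::mcols(rowRanges(b))
    for (f in c("REF", "ALT", "varClass", "indelLen", "QUAL", "QD", "FS",
                "MQ", "MQRankSum", "ReadPosRankSum"))
        if (f %in% colnames(ma))
            expect_equal(as.vector(ma[[f]]), as.vector(mb[[f]]),
                         info = f, tolerance = 1e-12)
}

# Independent per-site Weir & Cockerham (1984) components, scalar loops,
# written directly from the published formulas.
wc_oracle <- function(gtRow, popIdx) {
    r <- length(popIdx)
    n <- p <- h <- numeric(r)
    for (i in seq_len(r)) {
        g <- gtRow[popIdx[[i]]]
        g <- g[!is.na(g)]
        n[i] <- length(g)
        if (n[i] == 0) return(c(NA, NA, NA))
        p[i] <- sum(g) / (2 * n[i])
        h[i] <- mean(g == 1)
    }
    nbar <- mean(n)
    if (nbar <= 1) return(c(NA, NA, NA))
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) return(c(NA, NA, NA))
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
}

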