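# Per-site and windowed diversity statistics: nucleotide diversity,
# Weir & Cockerham (1984) variance components and theta-hat, sliding
# windows, Z-standardization, per-sample heterozygosity.

#' Sliding windows over scaffolds
#'
#' Half-open windows \code{[k*step, k*step + size)} (0-based) lying wholly
#' within the scaffold, only for scaffolds strictly longer than
#' \code{minScaffold} bp. Returned as 1-based \code{GRanges} (the
#' conversion between conventions happens here and only here).
#'
#' @param scaffoldLengths named integer vector of scaffold lengths (bp).
#' @param size window size in bp.
#' @param step window shift in bp.
#' @param minScaffold scaffolds of at most this length yield no windows.
#' @return \code{GRanges} of windows, with seqlengths set.
#' @export
makeWindows <- function(scaffoldLengths, size = 10000L, step = 5000L,
                        minScaffold = 10000L) {
    stopifnot(all(scaffoldLengths > 0, na.rm = TRUE))
    sl <- scaffoldLengths[!is.na(scaffoldLengths) &
                          scaffoldLengths > minScaffold]
    sl <- sl[sl >= size]
    starts0 <- lapply(unname(sl), function(L) seq.int(0L, L - size,
                                                      by = step))
    gr <- GRanges(rep(names(sl), lengths(starts0)),
                  IRanges(unlist(starts0) + 1L, width = size))
    GenomeInfoDb::seqlevels(gr) <- names(scaffoldLengths)
    suppressWarnings(seqlengths(gr) <- unname(scaffoldLengths))
    gr
}

#' Per-site allele counts
#'
#' @param cohort a \code{VariantCohort}.
#' @param samples column indices (default: all samples).
#' @return data.frame: \code{nHap} (2 x called diploids), \code{altCount},
#'   \code{hetCount} per variant.
#' @export
siteAlleleCounts <- function(cohort, samples = NULL) {
    gt <- genotypes(cohort)
    if (!is.null(samples)) gt <- gt[, samples, drop = FALSE]
    called <- rowSums(!is.na(gt))
    data.frame(nHap = 2L * called,
               altCount = rowSums(gt, na.rm = TRUE),
               hetCount = rowSums(gt == 1L, na.rm = TRUE))
}

#' Per-site nucleotide diversity
#'
#' \eqn{\pi = 2 j (n - j) / (n (n - 1))} for \code{j} alternate alleles
#' among \code{n} called haplotypes; equals the mean pairwise difference
#' over all haplotype pairs. Undefined (\code{NA}) for \code{n < 2}.
#'
#' @param n called haplotype count(s).
#' @param j alternate allele count(s).
#' @return numeric vector of per-site diversity.
#' @export
piSite <- function(n, j) {
    ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
}

#' Windowed nucleotide diversity per bp
#'
#' Sums per-site \eqn{\pi} over SNPs in each window and divides by the full
#' window length in bp (monomorphic and uncalled bases contribute zero;
#' mirrors the per-window convention of VCFtools' \code{--window-pi}).
#'
#' @param cohort a \code{VariantCohort}.
#' @param samples column indices of the group.
#' @param windows \code{GRanges} from \code{\link{makeWindows}}.
#' @return numeric vector, per-bp diversity per window.
#' @export
windowPi <- function(cohort, samples, windows) {
    snp <- variantClass(cohort) == "SNP"
    ac <- siteAlleleCounts(cohort, samples)
    ps <- piSite(ac$nHap, ac$altCount)
    ps[!snp | is.na(ps)] <- 0
    hits <- findOverlaps(rowRanges(cohort), windows)
    tot <- rep(0, length(windows))
    if (length(hits)) {
        sums <- rowsum(ps[S4Vectors::queryHits(hits)],
                       S4Vectors::subjectHits(hits))
        tot[as.integer(rownames(sums))] <- sums[, 1]
    }
    tot / width(windows)
}

#' Weir-Cockerham variance components per site
#'
#' Computes the among-population (a), among-individual (b) and
#' within-individual (c) components of the Weir & Cockerham (1984)
#' \eqn{\hat\theta} estimator at every site, for \code{r >= 2} populations
#' given as sample-index lists. Sites where any population has no called
#' diploid are undefined (\code{NA}).
#'
#' @param cohort a \code{VariantCohort}.
#' @param popIndices list of >= 2 integer vectors of sample columns.
#' @return data.frame with columns \code{a}, \code{b}, \code{c}.
#' @export
wcComponents <- function(cohort, popIndices) {
    r <- length(popIndices)
    stopifnot(r >= 2)
    gt <- genotypes(cohort)
    nv <- nrow(gt)
    n <- p <- h <- matrix(0, nv, r)
    for (i in seq_len(r)) {
        sub <- gt[, popIndices[[i]], drop = FALSE]
        ni <- rowSums(!is.na(sub))
        n[, i] <- ni
        p[, i] <- ifelse(ni > 0, rowSums(sub, na.rm = TRUE) / (2 * ni), NA)
        h[, i] <- ifelse(ni > 0, rowSums(sub == 1L, na.rm = TRUE) / ni, NA)
    }
    ok <- rowSums(n == 0) == 0
    nbar <- rowSums(n) / r
    nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
    pbar <- rowSums(n * p) / (r * nbar)
    s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(n * h) / (r * nbar)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
    a <- nbar / nc * (s2 - inner / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    bad <- !ok | nbar <= 1 | nc <= 0
    a[bad] <- b[bad] <- cc[bad] <- NA_real_
    data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' \eqn{\hat\theta} per window as the ratio of sums
#' \eqn{\sum a / \sum (a+b+c)} over sites in the window (not the mean of
#' per-site ratios). Windows with zero denominator or no defined site are
#' \code{NA}. Negative estimates are retained.
#'
#' @param cohort a \code{VariantCohort}.
#' @param popIndices list of sample-index vectors (>= 2 populations/groups).
#' @param windows \code{GRanges} of windows.
#' @return numeric vector of \eqn{\hat\theta} per window.
#' @export
windowFst <- function(cohort, popIndices, windows) {
    comp <- wcComponents(cohort, popIndices)
    den <- comp$a + comp$b + comp$c
    ok <- !is.na(den)
    hits <- findOverlaps(rowRanges(cohort), windows)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    use <- ok[q]
    sumA <- sumD <- rep(0, length(windows))
    got <- rep(FALSE, length(windows))
    if (any(use)) {
        sa <- rowsum(comp$a[q[use]], s[use])
        sdn <- rowsum(den[q[use]], s[use])
        idx <- as.integer(rownames(sa))
        sumA[idx] <- sa[, 1]; sumD[idx] <- sdn[, 1]; got[idx] <- TRUE
    }
    ifelse(got & sumD != 0, sumA / sumD, NA_real_)
}

#' Genome-wide Weir-Cockerham FST
#'
#' Ratio of sums over all retained sites.
#'
#' @inheritParams windowFst
#' @return scalar \eqn{\hat\theta}.
#' @export
globalFst <- function(cohort, popIndices) {
    comp <- wcComponents(cohort, popIndices)
    den <- comp$a + comp$b + comp$c
    ok <- !is.na(den)
    if (!any(ok) || sum(den[ok]) == 0) return(NA_real_)
    sum(comp$a[ok]) / sum(den[ok])
}

#' Z-standardize a vector of window statistics
#'
#' \eqn{z_i = (x_i - \mu)/\sigma} with \eqn{\mu,\sigma} the empirical mean
#' and (sample) standard deviation over defined values; both are returned
#' so thresholds can be reported on the original scale.
#'
#' @param values numeric vector (NAs allowed, preserved in output).
#' @return list: \code{z}, \code{mu}, \code{sigma}.
#' @export
zStandardize <- function(values) {
    v <- values[!is.na(values)]
    if (length(v) < 2) stop("need at least 2 defined values")
    mu <- mean(v); sigma <- sd(v)
    if (sigma == 0) stop("zero standard deviation")
    list(z = (values - mu) / sigma, mu = mu, sigma = sigma)
}

#' Per-sample and per-population heterozygosity summaries
#'
#' Counts heterozygous and homozygous-alternate genotypes per sample and
#' summarizes per population (bottlenecked populations show lower het/hom
#' ratios).
#'
#' @param cohort a \code{VariantCohort} (populations attached for the
#'   per-population summary).
#' @return list: \code{perSample} and (when available) \code{perPopulation}
#'   data.frames.
#' @export
sampleHetStats <- function(cohort) {
    gt <- genotypes(cohort)
    het <- colSums(gt == 1L, na.rm = TRUE)
    hom <- colSums(gt == 2L, na.rm = TRUE)
    ps <- data.frame(sample = colnames(gt), nSnp = het + hom,
                     het = het, homAlt = hom,
                     hetHomRatio = ifelse(hom > 0, het / hom, NA_real_),
                     stringsAsFactors = FALSE)
    out <- list(perSample = ps)
    if ("population" %in% colnames(colData(cohort))) {
        pop <- colData(cohort)$population
        agg <- aggregate(ps[, c("nSnp", "het", "homAlt")],
                         by = list(population = pop), FUN = mean)
        agg$hetHomRatio <- ifelse(agg$homAlt > 0, agg$het / agg$homAlt,
                                  NA_real_)
        out$perPopulation <- agg
    }
    out
}

#' Windowed diversity/differentiation table for a two-group contrast
#'
#' Computes, per sliding window: SNP count, per-bp \eqn{\pi} in each group,
#' Weir-Cockerham \eqn{\hat\theta}, its Z-score over defined windows, and
#' \eqn{\log_2(\pi_A/\pi_B)}.
#'
#' @param cohort a \code{VariantCohort}.
#' @param groupA,groupB sample column indices of the two groups (A is
#'   conventionally the wild group so that positive log-ratios mean
#'   diversity loss in B).
#' @param windows \code{GRanges} from \code{\link{makeWindows}}.
#' @return the \code{windows} GRanges with added metadata columns
#'   \code{nSites, piA, piB, fst, zFst, log2Ratio}; the Z-score mean/sd are
#'   in \code{metadata(result)$zFst}.
#' @export
windowDiversityStats <- function(cohort, groupA, groupB, windows) {
    snp <- rowRanges(cohort)[variantClass(cohort) == "SNP"]
    hits <- findOverlaps(snp, windows)
    nSites <- tabulate(S4Vectors::subjectHits(hits), length(windows))
    piA <- windowPi(cohort, groupA, windows)
    piB <- windowPi(cohort, groupB, windows)
    fst <- windowFst(cohort, list(groupA, groupB), windows)
    zs <- zStandardize(fst)
    lr <- log2Ratio(piA, piB)
    out <- windows
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        nSites = nSites, piA = piA, piB = piB, fst = fst, zFst = zs$z,
        log2Ratio = lr)
    S4Vectors::metadata(out)$zFst <- list(mu = zs$mu, sigma = zs$sigma)
    out
}
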