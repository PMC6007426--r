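# Variant QC filters.
#
# The hard thresholds reproduce a standard GATK-style stringent filter set:
# SNPs require QUAL > 30, QD > 5, FS < 60, MQ > 40, MQRankSum > -12.5 and
# ReadPosRankSum > -8; INDELs require QUAL > 30, QD > 5, FS < 200 and
# ReadPosRankSum > -20.  All inequalities are strict.  Records lacking an
# annotation pass that criterion by default (annotation presence depends on
# the upstream caller), switchable to drop.

.filter_report <- function(name, keep) {
    data.frame(filter = name, tested = length(keep),
               passed = sum(keep), failed = sum(!keep),
               stringsAsFactors = FALSE)
}

.apply_thresholds <- function(cohort, rows, spec, missingPasses) {
    keep <- rep(TRUE, length(rows))
    for (nm in names(spec)) {
        v <- qcAnnotation(cohort, nm)[rows]
        ok <- spec[[nm]](v)
        ok[is.na(v)] <- missingPasses
        if (any(is.na(v)) && missingPasses)
            warning(sum(is.na(v)), " record(s) lack ", nm,
                    "; kept for that criterion", call. = FALSE)
        keep <- keep & ok
    }
    keep
}

#' Hard-filter SNPs on site QC annotations
#'
#' Keeps SNPs with QUAL > 30, QD > 5, FS < 60, MQ > 40, MQRankSum > -12.5
#' and ReadPosRankSum > -8 (all strict). Non-SNP records pass through
#' untouched.
#'
#' @param cohort a \code{VariantCohort}.
#' @param missingPasses keep records lacking an annotation for that
#'   criterion (default) or drop them.
#' @return list: filtered \code{cohort} and a one-row \code{report}.
#' @export
filterSnpsHard <- function(cohort, missingPasses = TRUE) {
    rows <- which(variantClass(cohort) == "SNP")
    spec <- list(QUAL = function(x) x > 30, QD = function(x) x > 5,
                 FS = function(x) x < 60, MQ = function(x) x > 40,
                 MQRankSum = function(x) x > -12.5,
                 ReadPosRankSum = function(x) x > -8)
    keep <- .apply_thresholds(cohort, rows, spec, missingPasses)
    drop <- rows[!keep]
    full <- rep(TRUE, nrow(cohort)); full[drop] <- FALSE
    list(cohort = if (length(drop)) cohort[-drop, ] else cohort,
         report = .filter_report("snp_hard", full))
}

#' Hard-filter INDELs on site QC annotations
#'
#' Keeps INDELs with QUAL > 30, QD > 5, FS < 200 and ReadPosRankSum > -20
#' (all strict). Non-INDEL records pass through untouched.
#'
#' @inheritParams filterSnpsHard
#' @return list: filtered \code{cohort} and \code{report}.
#' @export
filterIndelsHard <- function(cohort, missingPasses = TRUE) {
    rows <- which(variantClass(cohort) == "INDEL")
    spec <- list(QUAL = function(x) x > 30, QD = function(x) x > 5,
                 FS = function(x) x < 200,
                 ReadPosRankSum = function(x) x > -20)
    keep <- .apply_thresholds(cohort, rows, spec, missingPasses)
    drop <- rows[!keep]
    full <- rep(TRUE, nrow(cohort)); full[drop] <- FALSE
    list(cohort = if (length(drop)) cohort[-drop, ] else cohort,
         report = .filter_report("indel_hard", full))
}

#' Remove clustered SNPs
#'
#' A SNP is a presumed alignment artifact when more than \code{maxSnps}
#' SNPs fall inside any window of \code{windowBp} consecutive bases
#' containing it; every SNP of such a cluster is removed (sliding, not
#' disjoint, windows). INDELs are neither counted nor removed.
#'
#' @param cohort a \code{VariantCohort}.
#' @param windowBp cluster window size in bp.
#' @param maxSnps largest SNP count per window that is still acceptable.
#' @return list: filtered \code{cohort} and \code{report}.
#' @export
filterSnpClusters <- function(cohort, windowBp = 10L, maxSnps = 3L) {
    rows <- which(variantClass(cohort) == "SNP")
    keep <- rep(TRUE, length(rows))
    if (length(rows)) {
        sc <- as.character(seqnames(rowRanges(cohort)))[rows]
        pos <- start(rowRanges(cohort))[rows]
        for (s in unique(sc)) {
            i <- which(sc == s)
            p <- pos[i]            # sorted by construction
            n <- length(p)
            # j-th SNP ends a window [p[j]-windowBp+1, p[j]]; count SNPs inside
            lo <- findInterval(p - windowBp, p) + 1L  # first index with pos > p-windowBp
            cnt <- seq_len(n) - lo + 1L
            bad <- logical(n)
            over <- which(cnt > maxSnps)
            for (j in over) bad[lo[j]:j] <- TRUE
            keep[i] <- !bad
        }
    }
    drop <- rows[!keep]
    full <- rep(TRUE, nrow(cohort)); full[drop] <- FALSE
    list(cohort = if (length(drop)) cohort[-drop, ] else cohort,
         report = .filter_report("snp_cluster", full))
}

#' Filter variants whose alternate-allele read support is weak
#'
#' Drops a variant when the alternate-allele depth, summed over samples
#' carrying the variant (het or hom-alt), is less than half the total site
#' depth summed over the same carriers (boundary kept at equality). Sites
#' lacking AD/DP assays pass through with a warning.
#'
#' @param cohort a \code{VariantCohort} with \code{adAlt}/\code{dp} assays.
#' @param perSample apply the rule per carrier sample instead (drop the
#'   variant if any carrier fails); the aggregate rule is the default.
#' @return list: filtered \code{cohort} and \code{report}.
#' @export
filterAlleleDepth <- function(cohort, perSample = FALSE) {
    n <- nrow(cohort)
    if (!all(c("adAlt", "dp") %in% assayNames(cohort))) {
        warning("no AD/DP assays; allele-depth filter skipped", call. = FALSE)
        return(list(cohort = cohort,
                    report = .filter_report("allele_depth", rep(TRUE, n))))
    }
    gt <- genotypes(cohort)
    carrier <- !is.na(gt) & gt > 0
    aa <- assay(cohort, "adAlt"); dpm <- assay(cohort, "dp")
    aa[!carrier | is.na(aa)] <- 0
    dpc <- dpm; dpc[!carrier | is.na(dpc)] <- 0
    if (perSample) {
        ok <- aa >= 0.5 * dpc | !carrier
        keep <- rowSums(!ok) == 0
    } else {
        keep <- rowSums(aa) >= 0.5 * rowSums(dpc)
    }
    informative <- rowSums(carrier & !is.na(dpm)) > 0
    keep[!informative] <- TRUE
    list(cohort = cohort[keep, ],
         report = .filter_report("allele_depth", keep))
}

#' Site filter for population-structure analyses
#'
#' Keeps SNPs with minor allele frequency strictly above \code{mafGt} and a
#' genotype call rate strictly above \code{callRateGt} across all samples;
#' INDELs are removed (structure analyses are SNP-based).
#'
#' @param cohort a \code{VariantCohort}.
#' @param mafGt minor-allele-frequency lower bound (exclusive).
#' @param callRateGt call-rate lower bound (exclusive).
#' @return list: filtered \code{cohort} and \code{report}.
#' @export
filterStructureSites <- function(cohort, mafGt = 0.1, callRateGt = 0.9) {
    gt <- genotypes(cohort)
    called <- rowSums(!is.na(gt))
    ac <- rowSums(gt, na.rm = TRUE)
    nhap <- 2 * called
    af <- ifelse(nhap > 0, ac / nhap, NA_real_)
    maf <- pmin(af, 1 - af)
    keep <- variantClass(cohort) == "SNP" &
        !is.na(maf) & maf > mafGt &
        called / ncol(gt) > callRateGt
    list(cohort = cohort[keep, ],
         report = .filter_report("structure_sites", keep))
}

#' Chain QC filters and collect their reports
#'
#' Applies, in order: SNP hard filter, INDEL hard filter, SNP cluster
#' removal, allele-depth filter. Reports chain so that the tested count of
#' each step equals the survivor count of the previous one.
#'
#' @param cohort a \code{VariantCohort}.
#' @param steps subset/order of \code{c("snp_hard","indel_hard","cluster","depth")}.
#' @return list: filtered \code{cohort} and the row-bound \code{report}.
#' @export
filterVariants <- function(cohort,
                           steps = c("snp_hard", "indel_hard", "cluster",
                                     "depth")) {
    reports <- list()
    for (s in steps) {
        res <- switch(s,
            snp_hard = filterSnpsHard(cohort),
            indel_hard = filterIndelsHard(cohort),
            cluster = filterSnpClusters(cohort),
            depth = filterAlleleDepth(cohort),
            stop("unknown filter step: ", s))
        cohort <- res$cohort
        reports[[s]] <- res$report
    }
    list(cohort = cohort, report = do.call(rbind, reports))
}
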