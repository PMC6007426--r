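# Joint outlier calling of selective-sweep windows, region merging, gene
# annotation, and group-diagnostic fixed-difference variants.

#' Log2 diversity ratio
#'
#' \eqn{\log_2(\pi_A/\pi_B)}; undefined (\code{NA}) where the denominator
#' diversity is zero, or where the numerator is zero (log of zero).
#'
#' @param piA,piB non-negative per-window diversities.
#' @return numeric vector.
#' @export
log2Ratio <- function(piA, piB) {
    stopifnot(all(piA >= 0, na.rm = TRUE), all(piB >= 0, na.rm = TRUE))
    out <- ifelse(!is.na(piB) & piB > 0, log2(piA / piB), NA_real_)
    out[is.infinite(out)] <- NA_real_
    out
}

.upper_threshold <- function(x, q) {
    # nearest-rank upper-tail threshold: the floor(q*N)-th largest defined
    # value; selection is inclusive (>=), so ties widen the selected set
    v <- sort(x[!is.na(x)], decreasing = TRUE)
    k <- max(1L, floor(q * length(v)))
    v[k]
}

#' Joint top-quantile outlier windows
#'
#' Selects windows in the upper \code{q} tail of both the Z(FST)
#' distribution and the \eqn{\log_2} diversity-ratio distribution
#' (empirical nearest-rank thresholds over defined windows, inclusive at
#' the threshold).
#'
#' @param stats \code{GRanges} from \code{\link{windowDiversityStats}}.
#' @param q upper-tail fraction (0.05 for top 5\%, 0.01 for top 1\%).
#' @return list: \code{selected} (logical over windows), \code{zThreshold},
#'   \code{ratioThreshold}, \code{n} (defined-window counts).
#' @export
jointOutliers <- function(stats, q = 0.05) {
    z <- S4Vectors::mcols(stats)$zFst
    lr <- S4Vectors::mcols(stats)$log2Ratio
    nz <- sum(!is.na(z)); nr <- sum(!is.na(lr))
    if (min(nz, nr) < 1 / q)
        warning("fewer than 1/q defined windows; thresholds are unstable",
                call. = FALSE)
    zt <- .upper_threshold(z, q)
    rt <- .upper_threshold(lr, q)
    sel <- !is.na(z) & !is.na(lr) & z >= zt & lr >= rt
    list(selected = sel, zThreshold = zt, ratioThreshold = rt,
         n = c(z = nz, ratio = nr))
}

#' Merge selected windows into sweep regions
#'
#' Overlapping or book-ended selected windows on one scaffold are merged;
#' each region keeps the peak Z(FST) and peak log2 ratio of its windows.
#'
#' @param stats window \code{GRanges} with \code{zFst}/\code{log2Ratio}.
#' @param selected logical vector over \code{stats}.
#' @return \code{GRanges} of regions with \code{peakZFst},
#'   \code{peakLog2Ratio} and \code{nWindows} metadata.
#' @export
mergeRegions <- function(stats, selected) {
    sel <- stats[selected]
    if (length(sel) == 0) {
        out <- GRanges()
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            peakZFst = numeric(0), peakLog2Ratio = numeric(0),
            nWindows = integer(0))
        return(out)
    }
    regions <- reduce(granges(sel), min.gapwidth = 1L)
    hits <- findOverlaps(sel, regions)
    s <- S4Vectors::subjectHits(hits); qh <- S4Vectors::queryHits(hits)
    pk <- function(v) vapply(split(v[qh], s), max, numeric(1), na.rm = TRUE)
    S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
        peakZFst = unname(pk(S4Vectors::mcols(sel)$zFst)),
        peakLog2Ratio = unname(pk(S4Vectors::mcols(sel)$log2Ratio)),
        nWindows = as.integer(table(factor(s, seq_along(regions)))))
    regions
}

#' Read a gene annotation track
#'
#' GFF3 (\code{type == "gene"} features, falling back to all features when
#' none are typed "gene") or BED. Gene identifiers come from, in order of
#' preference: \code{gene_id}, \code{ID}, \code{Name}, \code{name}.
#'
#' @param path GFF3 or BED file.
#' @return \code{GRanges} with a \code{geneId} metadata column.
#' @export
readGeneTrack <- function(path) {
    fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "BED"
           else "GFF3"
    gr <- rtracklayer::import(path, format = fmt)
    if (fmt == "GFF3" && "type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
        gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    id <- NULL
    for (cand in c("gene_id", "ID", "Name", "name"))
        if (is.null(id) && cand %in% colnames(mc)) id <- as.character(mc[[cand]])
    if (is.null(id)) id <- paste0("gene", seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(geneId = id)
    gr
}

#' Genes overlapping sweep regions
#'
#' A gene is assigned to a region when they overlap by at least 1 bp.
#'
#' @param regions \code{GRanges} of sweep regions.
#' @param genes \code{GRanges} with \code{geneId} (see
#'   \code{\link{readGeneTrack}}).
#' @return list: \code{perRegion} (character list, gene ids per region) and
#'   \code{genes} (unique gene ids over all regions).
#' @export
annotateGenes <- function(regions, genes) {
    unmatched <- setdiff(unique(as.character(seqnames(regions))),
                         unique(as.character(seqnames(genes))))
    if (length(unmatched))
        warning("no genes on scaffold(s): ",
                paste(unmatched, collapse = ", "), call. = FALSE)
    hits <- suppressWarnings(findOverlaps(regions, genes, minoverlap = 1L))
    per <- vector("list", length(regions))
    for (i in seq_along(per)) per[[i]] <- character(0)
    if (length(hits)) {
        sp <- split(S4Vectors::mcols(genes)$geneId[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
        per[as.integer(names(sp))] <- lapply(sp, unique)
    }
    list(perRegion = per, genes = unique(unlist(per)))
}

#' Group-diagnostic fixed variants
#'
#' Returns the variants at which every called sample of group A is
#' homozygous for one allele and every called sample of group B homozygous
#' for the other, with at least \code{minCalled} called samples in each
#' group -- the fixed-homozygous-difference pattern of a phenotype-
#' diagnostic locus.
#'
#' @param cohort a \code{VariantCohort}.
#' @param groupA,groupB sample column indices of the two phenotype groups.
#' @param minCalled minimum called samples per group.
#' @return \code{GRanges} of diagnostic variants with \code{varClass} and
#'   \code{groupAState} (\code{"alt"} or \code{"ref"}) metadata.
#' @export
diagnosticVariants <- function(cohort, groupA, groupB, minCalled = 1L) {
    stopifnot(length(groupA) > 0, length(groupB) > 0)
    gt <- genotypes(cohort)
    ga <- gt[, groupA, drop = FALSE]
    gb <- gt[, groupB, drop = FALSE]
    calledA <- rowSums(!is.na(ga)); calledB <- rowSums(!is.na(gb))
    allA2 <- rowSums(ga != 2L, na.rm = TRUE) == 0
    allA0 <- rowSums(ga != 0L, na.rm = TRUE) == 0
    allB2 <- rowSums(gb != 2L, na.rm = TRUE) == 0
    allB0 <- rowSums(gb != 0L, na.rm = TRUE) == 0
    ok <- calledA >= minCalled & calledB >= minCalled
    altInA <- ok & allA2 & allB0
    refInA <- ok & allA0 & allB2
    hit <- altInA | refInA
    out <- rowRanges(cohort)[hit]
    S4Vectors::mcols(out)$groupAState <-
        ifelse(altInA[hit], "alt", "ref")
    out
}

#' End-to-end sweep scan
#'
#' Convenience wrapper: window statistics, joint outliers, merged regions
#' and (optionally) gene annotation.
#'
#' @inheritParams windowDiversityStats
#' @param q upper-tail fraction for both marginals.
#' @param genes optional gene \code{GRanges}.
#' @return list: \code{stats}, \code{outliers}, \code{regions},
#'   \code{genes} (when an annotation was given).
#' @export
sweepScan <- function(cohort, groupA, groupB, windows, q = 0.05,
                      genes = NULL) {
    stats <- windowDiversityStats(cohort, groupA, groupB, windows)
    out <- jointOutliers(stats, q = q)
    regions <- mergeRegions(stats, out$selected)
    res <- list(stats = stats, outliers = out, regions = regions)
    if (!is.null(genes)) res$genes <- annotateGenes(regions, genes)
    res
}
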