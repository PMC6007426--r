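#' @import methods
#' @importFrom S4Vectors DataFrame mcols "mcols<-" metadata "metadata<-" queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges seqnames start end width findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData assayNames "rowRanges<-" "colData<-"
#' @importFrom GenomeInfoDb seqlengths seqlevels keepSeqlevels seqlevelsInUse "seqlengths<-" Seqinfo
#' @importFrom stats optim optimize quantile rbinom rpois runif sd setNames rmultinom
#'   fisher.test wilcox.test na.omit median aggregate rgeom dhyper as.dist
#' @importFrom utils write.table read.table head tail
#' @useDynLib SweepDemes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multi-sample variant cohort
#'
#' A \code{VariantCohort} holds biallelic variants for a set of diploid
#' samples: a \code{GRanges} of sites (REF/ALT alleles, variant class, QC
#' annotations as metadata columns), a genotype matrix coded as alternate
#' allele dosage (0, 1, 2, \code{NA} = missing), optional per-sample allele
#' depths, and per-sample population/group assignments in \code{colData}.
#' It extends \code{RangedSummarizedExperiment}, so all the usual
#' subsetting and accessor machinery applies.
#'
#' Coordinates are 1-based inclusive at the interface (VCF convention);
#' window arithmetic inside the package is 0-based half-open and converted
#' centrally by \code{\link{makeWindows}}.
#'
#' @slot .. see \code{RangedSummarizedExperiment}; the \code{"GT"} assay is
#'   mandatory.
#' @export
setClass("VariantCohort", contains = "RangedSummarizedExperiment")

setValidity("VariantCohort", function(object) {
    msg <- NULL
    if (!"GT" %in% assayNames(object))
        msg <- c(msg, "assay 'GT' (alt-allele dosage) is required")
    else {
        gt <- assay(object, "GT")
        bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
        if (any(bad))
            msg <- c(msg, "GT values must be 0, 1, 2 or NA")
    }
    rr <- rowRanges(object)
    need <- c("REF", "ALT", "varClass", "indelLen")
    miss <- setdiff(need, colnames(S4Vectors::mcols(rr)))
    if (length(miss))
        msg <- c(msg, paste0("rowRanges lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantCohort
#'
#' @param gt integer matrix of alt-allele dosages (variants x samples).
#' @param ranges \code{GRanges} of variant sites (length \code{nrow(gt)})
#'   with at least \code{REF} and \code{ALT} metadata columns.
#' @param colData \code{DataFrame} of per-sample annotation; row names are
#'   sample names.
#' @param adRef,adAlt,dp optional per-sample matrices: reference/alternate
#'   allele read depths and total depth.
#' @return a \code{VariantCohort}, rows sorted by (scaffold, position).
#' @export
VariantCohort <- function(gt, ranges, colData = NULL,
                          adRef = NULL, adAlt = NULL, dp = NULL) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    mc <- S4Vectors::mcols(ranges)
    if (!"varClass" %in% colnames(mc) || !"indelLen" %in% colnames(mc)) {
        cls <- classifyAlleles(mc$REF, mc$ALT)
        S4Vectors::mcols(ranges)$varClass <- cls$varClass
        S4Vectors::mcols(ranges)$indelLen <- cls$indelLen
    }
    if (is.null(colData)) {
        sn <- colnames(gt)
        if (is.null(sn)) sn <- paste0("S", seq_len(ncol(gt)))
        colData <- S4Vectors::DataFrame(row.names = sn)
    }
    al <- list(GT = gt)
    if (!is.null(adRef)) al$adRef <- as.matrix(adRef)
    if (!is.null(adAlt)) al$adAlt <- as.matrix(adAlt)
    if (!is.null(dp)) al$dp <- as.matrix(dp)
    se <- SummarizedExperiment(assays = al, rowRanges = ranges,
                               colData = colData)
    o <- order(as.factor(seqnames(se)), start(se))
    se <- se[o, ]
    new("VariantCohort", se)
}

setMethod("show", "VariantCohort", function(object) {
    cls <- variantClass(object)
    cat("VariantCohort:", nrow(object), "variants x", ncol(object),
        "samples\n")
    cat("  SNPs:", sum(cls == "SNP"), " INDELs:", sum(cls == "INDEL"), "\n")
    cat("  scaffolds:", length(seqlevelsInUse(rowRanges(object))), "\n")
    if ("population" %in% colnames(colData(object))) {
        tab <- table(colData(object)$population)
        cat("  populations:", paste(names(tab), tab, sep = ":",
                                    collapse = " "), "\n")
    }
})

#' Folded (joint) site-frequency spectrum
#'
#' Mass is indexed by minor-allele count per population, dimension
#' \code{projections + 1} (bin 0 .. m per population). The two corner cells
#' (all-zero and all-top) are non-polymorphic and masked; masked cells carry
#' no countable mass. \code{nSkipped} counts input sites dropped because a
#' population had fewer called haplotypes than its projection.
#'
#' @slot mass numeric array of frequency-class masses.
#' @slot mask logical array, \code{TRUE} = excluded cell.
#' @slot projections integer vector of projected haplotype counts.
#' @slot popNames character vector naming the populations.
#' @slot nSkipped integer, sites skipped for insufficient call-rate.
#' @export
setClass("FoldedSFS",
    representation(mass = "array", mask = "array", projections = "integer",
                   popNames = "character", nSkipped = "integer"))

setValidity("FoldedSFS", function(object) {
    msg <- NULL
    if (!identical(dim(object@mass), dim(object@mask)))
        msg <- c(msg, "mass and mask dims differ")
    if (!identical(dim(object@mass), object@projections + 1L))
        msg <- c(msg, "dims must equal projections + 1")
    if (any(object@mass < -1e-9, na.rm = TRUE))
        msg <- c(msg, "negative mass")
    if (any(abs(object@mass[object@mask]) > 1e-9))
        msg <- c(msg, "masked cells must carry no mass")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "FoldedSFS", function(object) {
    cat("FoldedSFS: projections (",
        paste(object@projections, collapse = ", "), ") for pops ",
        paste(object@popNames, collapse = "/"), "\n", sep = "")
    cat("  segregating mass:", format(sfsMass(object)), " skipped sites:",
        object@nSkipped, "\n")
})

#' Demographic model for wild plus two domesticated lineages
#'
#' Piecewise-constant structured-coalescent model in diffusion-style scaled
#' units: population sizes relative to the ancestral reference size
#' \eqn{N_{ref}}, times in units of \eqn{2 N_{ref}} generations (backwards
#' from the present), migration as \eqn{2 N_{ref} m} (backwards per-lineage
#' jump rate per scaled time unit). Four domestication scenarios are
#' supported, see \code{\link{buildModel}}.
#'
#' @slot scenario one of \code{"model1".."model4"}.
#' @slot params named numeric vector of scaled parameters.
#' @slot popNames sampled population names (wild, meat, egg/dual-purpose).
#' @export
setClass("DemographicModel",
    representation(scenario = "character", params = "numeric",
                   popNames = "character"))

setMethod("show", "DemographicModel", function(object) {
    cat("DemographicModel <", object@scenario, ">\n", sep = "")
    print(round(object@params, 6))
})

#' Result of a composite-likelihood model fit
#'
#' @slot model fitted \code{DemographicModel} (parameters at the optimum).
#' @slot free names of the parameters that were optimized.
#' @slot loglik maximized Poisson composite log-likelihood.
#' @slot aic \eqn{2k - 2 \log L}.
#' @slot theta analytically profiled total-mass scaling \eqn{\hat\theta}.
#' @slot converged logical: best two restarts agreed within tolerance.
#' @slot nEval objective evaluations used.
#' @export
setClass("DemographicFit",
    representation(model = "DemographicModel", free = "character",
                   loglik = "numeric", aic = "numeric", theta = "numeric",
                   converged = "logical", nEval = "integer"))

setMethod("show", "DemographicFit", function(object) {
    cat("DemographicFit <", object@model@scenario, ">  logL = ",
        format(object@loglik), "  AIC = ", format(object@aic),
        if (!object@converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
    print(round(object@model@params[object@free], 6))
})
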