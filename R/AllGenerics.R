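#' Accessors for VariantCohort and FoldedSFS
#'
#' \code{genotypes} returns the alt-allele dosage matrix (0/1/2/NA);
#' \code{variantClass} and \code{indelLength} the per-variant classification;
#' \code{qcAnnotation} a named QC annotation vector (e.g. \code{"QD"});
#' \code{populations} the per-sample population factor; \code{sampleGroups}
#' the per-sample labels of a grouping scheme (\code{"production"} or
#' \code{"plumage"}); \code{scaffoldLengths} the named scaffold length
#' vector; \code{sfsMass} the total unmasked (segregating) mass of a folded
#' spectrum.
#'
#' @param x a \code{VariantCohort} (or \code{FoldedSFS} for \code{sfsMass}).
#' @param name QC annotation name.
#' @param scheme grouping scheme name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "VariantCohort", function(x) assay(x, "GT"))

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))
#' @rdname accessors
#' @export
setMethod("variantClass", "VariantCohort",
          function(x) S4Vectors::mcols(rowRanges(x))$varClass)

#' @rdname accessors
#' @export
setGeneric("indelLength", function(x) standardGeneric("indelLength"))
#' @rdname accessors
#' @export
setMethod("indelLength", "VariantCohort",
          function(x) S4Vectors::mcols(rowRanges(x))$indelLen)

#' @rdname accessors
#' @export
setGeneric("qcAnnotation", function(x, name) standardGeneric("qcAnnotation"))
#' @rdname accessors
#' @export
setMethod("qcAnnotation", "VariantCohort", function(x, name) {
    mc <- S4Vectors::mcols(rowRanges(x))
    if (!name %in% colnames(mc)) return(rep(NA_real_, nrow(x)))
    as.numeric(mc[[name]])
})

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setMethod("populations", "VariantCohort", function(x) {
    cd <- colData(x)
    if (!"population" %in% colnames(cd))
        stop("no population map attached; see attachPopulations()")
    setNames(as.character(cd$population), rownames(cd))
})

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x, scheme = "production")
    standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "VariantCohort", function(x, scheme = "production") {
    cd <- colData(x)
    col <- paste0("group_", scheme)
    if (!col %in% colnames(cd))
        stop("grouping scheme '", scheme, "' not attached")
    setNames(as.character(cd[[col]]), rownames(cd))
})

#' @rdname accessors
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))
#' @rdname accessors
#' @export
setMethod("scaffoldLengths", "VariantCohort",
          function(x) seqlengths(rowRanges(x)))

#' @rdname accessors
#' @export
setGeneric("sfsMass", function(x) standardGeneric("sfsMass"))
#' @rdname accessors
#' @export
setMethod("sfsMass", "FoldedSFS", function(x) sum(x@mass[!x@mask]))
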