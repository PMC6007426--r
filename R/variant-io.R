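# VCF and population-map I/O plus variant classification.
#
# Reading goes through vcfR (robust VCF v4.2 parser, bgzip-aware); writing
# is a plain-text emitter so the round trip is exact at field level.

QC_INFO_FIELDS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "DP")

#' Classify REF/ALT allele pairs
#'
#' Single-base REF and ALT is a SNP; otherwise an INDEL with signed length
#' \code{nchar(ALT) - nchar(REF)}. Symbolic alleles (\code{<DEL>} etc.) are
#' rejected.
#'
#' @param ref,alt character vectors of alleles.
#' @return list with \code{varClass} and \code{indelLen}.
#' @export
classifyAlleles <- function(ref, alt) {
    if (any(!nzchar(ref)) || any(!nzchar(alt)))
        stop("empty allele string")
    if (any(grepl("[^ACGTNacgtn]", paste0(ref, alt))))
        stop("symbolic or breakend alleles are not supported")
    snp <- nchar(ref) == 1L & nchar(alt) == 1L
    list(varClass = ifelse(snp, "SNP", "INDEL"),
         indelLen = ifelse(snp, 0L, nchar(alt) - nchar(ref)))
}

#' Classify variants and enforce the small-INDEL size bound
#'
#' Re-derives \code{varClass}/\code{indelLen} from the alleles and drops
#' INDELs longer than \code{maxIndel} bp (SNPs and small INDELs, 1--50 bp,
#' are the supported variant universe). Idempotent.
#'
#' @param cohort a \code{VariantCohort}.
#' @param maxIndel maximum |indel length| retained (bp).
#' @return list: \code{cohort} (classified, oversize INDELs removed) and
#'   \code{report} (one-row data.frame of tested/dropped counts).
#' @export
classifyVariants <- function(cohort, maxIndel = 50L) {
    rr <- rowRanges(cohort)
    cls <- classifyAlleles(S4Vectors::mcols(rr)$REF, S4Vectors::mcols(rr)$ALT)
    S4Vectors::mcols(rr)$varClass <- cls$varClass
    S4Vectors::mcols(rr)$indelLen <- cls$indelLen
    rowRanges(cohort) <- rr
    keep <- abs(cls$indelLen) <= maxIndel
    if (any(!keep))
        message(sum(!keep), " INDEL(s) longer than ", maxIndel,
                " bp removed")
    list(cohort = cohort[keep, ],
         report = data.frame(filter = "indel_size", tested = length(keep),
                             passed = sum(keep), failed = sum(!keep)))
}

.parse_gt_dosage <- function(gt, allele = 1L) {
    # "0/1", "0|1", "./.", "0/.", "1" -> dosage vs the given ALT allele index;
    # any missing haplotype call makes the genotype missing (half-call rule)
    out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    toks <- strsplit(as.vector(gt), "[/|]")
    dos <- vapply(toks, function(tk) {
        if (length(tk) == 0L || any(tk == ".") || any(is.na(tk)))
            return(NA_integer_)
        sum(tk == as.character(allele))
    }, integer(1))
    out[] <- dos
    out[is.na(gt)] <- NA_integer_
    out
}

#' Read a multi-sample VCF into a VariantCohort
#'
#' Multiallelic records are split into one biallelic record per ALT allele
#' (genotypes recoded as dosage of that ALT; other alternate alleles count
#' as reference) or rejected, per \code{multiallelic}. QC annotations
#' (QUAL plus \code{QD, FS, MQ, MQRankSum, ReadPosRankSum, DP}) are carried
#' as \code{rowRanges} metadata columns when present; per-sample AD/DP
#' become assays. Scaffold lengths are taken from \code{##contig} headers.
#'
#' @param path VCF file (plain or bgzip).
#' @param sampleSubset optional character vector of samples to keep.
#' @param multiallelic \code{"split"} (default) or \code{"reject"}.
#' @return a \code{VariantCohort}.
#' @export
readVcfCohort <- function(path, sampleSubset = NULL,
                          multiallelic = c("split", "reject")) {
    multiallelic <- match.arg(multiallelic)
    if (!file.exists(path)) stop("no such file: ", path)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)) && !is.null(fix))
        fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (is.null(fix))
        fix <- matrix(character(0), 0, 7,
                      dimnames = list(NULL, c("CHROM", "POS", "ID", "REF",
                                              "ALT", "QUAL", "FILTER")))
    nrec <- nrow(fix)
    samples_all <- if (ncol(v@gt) > 1) colnames(v@gt)[-1] else character(0)
    gt_raw <- if (nrec > 0 && length(samples_all))
        vcfR::extract.gt(v, element = "GT") else
        matrix(character(0), nrec * (nrec > 0), length(samples_all),
               dimnames = list(NULL, samples_all))
    ad_raw <- if (nrec > 0 && ncol(v@gt) > 1)
        suppressWarnings(vcfR::extract.gt(v, element = "AD")) else NULL
    dp_raw <- if (nrec > 0 && ncol(v@gt) > 1)
        suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE)) else NULL
    samples <- colnames(gt_raw)
    if (!is.null(sampleSubset)) {
        unknown <- setdiff(sampleSubset, samples)
        if (length(unknown))
            stop("unknown sample(s) in subset: ",
                 paste(unknown, collapse = ", "))
        keep <- samples %in% sampleSubset
        gt_raw <- gt_raw[, keep, drop = FALSE]
        if (!is.null(ad_raw)) ad_raw <- ad_raw[, keep, drop = FALSE]
        if (!is.null(dp_raw)) dp_raw <- dp_raw[, keep, drop = FALSE]
        samples <- colnames(gt_raw)
    }
    alt_chr <- fix[, "ALT"]
    alt_chr[is.na(alt_chr)] <- ""
    alt_list <- strsplit(alt_chr, ",", fixed = TRUE)
    n_alt <- lengths(alt_list)
    if (multiallelic == "reject" && any(n_alt > 1))
        stop(sum(n_alt > 1), " multiallelic record(s); set multiallelic='split'")
    rec_idx <- rep.int(seq_len(nrec), n_alt)
    allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

    info_vals <- lapply(QC_INFO_FIELDS, function(f)
        suppressWarnings(as.numeric(vcfR::extract.info(v, element = f))))
    names(info_vals) <- QC_INFO_FIELDS

    gt <- matrix(NA_integer_, length(rec_idx), length(samples),
                 dimnames = list(NULL, samples))
    adRef <- adAlt <- NULL
    if (!is.null(ad_raw) && !all(is.na(ad_raw))) {
        adRef <- adAlt <- matrix(NA_real_, length(rec_idx), length(samples),
                                 dimnames = list(NULL, samples))
        ad_split <- strsplit(as.vector(ad_raw), ",", fixed = TRUE)
    }
    for (a in unique(allele_idx)) {
        rows <- which(allele_idx == a)
        src <- rec_idx[rows]
        gt[rows, ] <- .parse_gt_dosage(gt_raw[src, , drop = FALSE], a)
        if (!is.null(adRef)) {
            pick <- function(parts, k)
                suppressWarnings(as.numeric(vapply(parts, function(p)
                    if (length(p) >= k) p[[k]] else NA_character_,
                    character(1))))
            idx <- as.vector(outer(src, (seq_along(samples) - 1L) * nrec, "+"))
            parts <- ad_split[idx]
            adRef[rows, ] <- pick(parts, 1L)
            adAlt[rows, ] <- pick(parts, a + 1L)
        }
    }
    mc <- S4Vectors::DataFrame(
        REF = fix[rec_idx, "REF"],
        ALT = vapply(seq_along(rec_idx), function(i)
            alt_list[[rec_idx[i]]][allele_idx[i]], character(1)),
        QUAL = suppressWarnings(as.numeric(fix[rec_idx, "QUAL"])))
    for (f in QC_INFO_FIELDS) mc[[f]] <- info_vals[[f]][rec_idx]
    gr <- GRanges(fix[rec_idx, "CHROM"],
                  IRanges(as.integer(fix[rec_idx, "POS"]), width = 1L))
    S4Vectors::mcols(gr) <- mc
    # contig lengths from the header
    meta <- v@meta
    contig <- grep("^##contig=", meta, value = TRUE)
    if (length(contig)) {
        ids <- sub('.*ID=([^,>"]+).*', "\\1", contig)
        lens <- suppressWarnings(as.integer(
            sub(".*length=([0-9]+).*", "\\1", contig)))
        sl <- setNames(lens, ids)
        lv <- unique(c(ids, as.character(seqnames(gr))))
        gr <- GRanges(as.character(seqnames(gr)), IRanges::ranges(gr),
                      seqinfo = GenomeInfoDb::Seqinfo(lv, sl[lv]))
        S4Vectors::mcols(gr) <- mc
    }
    dp <- if (!is.null(dp_raw)) dp_raw[rec_idx, , drop = FALSE] else NULL
    VariantCohort(gt, gr, adRef = adRef, adAlt = adAlt, dp = dp)
}

.fmt_num <- function(x) {
    ifelse(is.na(x), ".",
           vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                        trim = TRUE), character(1)))
}

#' Write a VariantCohort as VCF v4.2
#'
#' Emits a sorted, header-complete plain-text VCF (contig lines from the
#' cohort's scaffold lengths; GT plus AD/DP when present). Reading the file
#' back with \code{\link{readVcfCohort}} reproduces the cohort field for
#' field.
#'
#' @param cohort a \code{VariantCohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVcfCohort <- function(cohort, path) {
    rr <- rowRanges(cohort)
    mc <- S4Vectors::mcols(rr)
    sl <- scaffoldLengths(cohort)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s%s>", names(sl),
                     ifelse(is.na(sl), "", paste0(",length=", sl))),
             sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                     QC_INFO_FIELDS, QC_INFO_FIELDS),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
    n <- nrow(cohort)
    info <- rep(".", n)
    if (n > 0) {
        pieces <- lapply(QC_INFO_FIELDS, function(f) {
            v <- if (f %in% colnames(mc)) as.numeric(mc[[f]]) else
                rep(NA_real_, n)
            ifelse(is.na(v), NA_character_, paste0(f, "=", .fmt_num(v)))
        })
        info <- apply(do.call(cbind, pieces), 1, function(z)
            if (all(is.na(z))) "." else paste(z[!is.na(z)], collapse = ";"))
    }
    gt <- genotypes(cohort)
    ns <- ncol(cohort)
    gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = n, ncol = ns)
    gtStr[is.na(gt)] <- "./."
    fmt <- "GT"
    hasAD <- "adRef" %in% assayNames(cohort)
    hasDP <- "dp" %in% assayNames(cohort)
    if (hasAD) {
        ar <- assay(cohort, "adRef"); aa <- assay(cohort, "adAlt")
        adStr <- matrix(paste0(.fmt_num(ar), ",", .fmt_num(aa)),
                        nrow = n, ncol = ns)
        adStr[is.na(ar) & is.na(aa)] <- "."
        gtStr <- matrix(paste(gtStr, adStr, sep = ":"), nrow = n,
                        ncol = ns)
        fmt <- paste0(fmt, ":AD")
    }
    if (hasDP) {
        dpm <- assay(cohort, "dp")
        gtStr <- matrix(paste(gtStr, .fmt_num(dpm), sep = ":"),
                        nrow = n, ncol = ns)
        fmt <- paste0(fmt, ":DP")
    }
    colnames(gtStr) <- colnames(cohort)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(cohort)), collapse = "\t"),
               con)
    if (n > 0) {
        body <- cbind(as.character(seqnames(rr)), start(rr), ".",
                      mc$REF, mc$ALT, .fmt_num(mc$QUAL), "PASS", info,
                      fmt, gtStr)
        writeLines(apply(body, 1, paste, collapse = "\t"), con)
    }
    invisible(path)
}

#' Read a population map
#'
#' Three-column TSV: \code{sample<TAB>population<TAB>group1[,group2]} where
#' group1 is the production-type group and the optional group2 the plumage
#' group.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{sample}, \code{population},
#'   \code{group_production}, \code{group_plumage}.
#' @export
readPopmap <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE,
                     col.names = c("sample", "population", "groups"))
    g <- strsplit(df$groups, ",", fixed = TRUE)
    data.frame(sample = df$sample, population = df$population,
               group_production = vapply(g, `[`, character(1), 1L),
               group_plumage = vapply(g, function(x)
                   if (length(x) > 1) x[[2]] else NA_character_, character(1)),
               stringsAsFactors = FALSE)
}

#' Attach population and group assignments to a cohort
#'
#' Validates that the map covers every sample exactly once and that no
#' population is empty, then stores population and group labels in
#' \code{colData}.
#'
#' @param cohort a \code{VariantCohort}.
#' @param popmap data.frame as returned by \code{\link{readPopmap}} (columns
#'   \code{sample}, \code{population}, optionally \code{group_production},
#'   \code{group_plumage}).
#' @return the annotated \code{VariantCohort}.
#' @export
attachPopulations <- function(cohort, popmap) {
    sn <- colnames(cohort)
    missing <- setdiff(sn, popmap$sample)
    if (length(missing))
        stop("popmap does not cover sample(s): ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(popmap$sample))
        stop("popmap lists sample(s) more than once: ",
             paste(unique(popmap$sample[duplicated(popmap$sample)]),
                   collapse = ", "))
    m <- popmap[match(sn, popmap$sample), ]
    if (any(!nzchar(m$population) | is.na(m$population)))
        stop("empty population label")
    cd <- colData(cohort)
    cd$population <- m$population
    if ("group_production" %in% colnames(m))
        cd$group_production <- m$group_production
    if ("group_plumage" %in% colnames(m))
        cd$group_plumage <- m$group_plumage
    colData(cohort) <- cd
    cohort
}

#' Per-population sample index lists
#'
#' @param cohort a cohort with populations attached.
#' @return named list of column indices, one per population.
#' @export
popSampleIndices <- function(cohort) {
    pop <- populations(cohort)
    split(seq_along(pop), pop)
}

#' Sample indices belonging to populations or a group label
#'
#' @param cohort a cohort with populations attached.
#' @param pops population names, or \code{NULL} with \code{group}/\code{scheme}.
#' @param group group label to select (e.g. \code{"wild"}).
#' @param scheme grouping scheme, \code{"production"} or \code{"plumage"}.
#' @return integer vector of sample (column) indices.
#' @export
sampleIndices <- function(cohort, pops = NULL, group = NULL,
                          scheme = "production") {
    if (!is.null(pops)) {
        pop <- populations(cohort)
        unknown <- setdiff(pops, pop)
        if (length(unknown))
            stop("unknown population(s): ", paste(unknown, collapse = ", "))
        return(which(pop %in% pops))
    }
    g <- sampleGroups(cohort, scheme)
    which(g %in% group)
}
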