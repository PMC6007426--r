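# Synthetic-cohort generator: structured-coalescent windows, infinite-sites
# mutation, diploid pairing, synthesized QC annotations, missingness, sweep
# emulation (local size scaling) and diagnostic-locus injection, with truth
# records for every window and injected variant.

#' Default demography of the simulated domestication cohort
#'
#' The generator's reference demography: a large wild mallard population, an
#' ancestral size change deep in the past, a recent single domestication
#' through a severe bottleneck (ancestral domesticated Ne = 320) followed
#' ~100 years later by the meat vs egg/dual-purpose breed split, expansion
#' to the current breed sizes, and continuous gene flow from both breeds
#' back into the wild population (about 1 and 4 migrants per generation).
#' Sizes in individuals / times in years are converted to scaled units with
#' the reference size \code{Nref} (the pre-size-change ancestral size, the
#' generator's choice) and a 1-year generation.
#'
#' @param Nref ancestral reference size (individuals).
#' @param g generation time in years.
#' @return list: \code{model} (a \code{DemographicModel}, scenario
#'   \code{"model2"}), \code{Nref}, \code{realParams} (the real-unit
#'   values).
#' @export
duckDomesticationModel <- function(Nref = 1e5, g = 1) {
    real <- c(NeAncestral = 663439, NeWild = 88842, NeMeat = 5597,
              NeEggDp = 12988, NeDomBottleneck = 320,
              TSizeChangeYr = 249944, TDomesticationYr = 2228,
              TBreedSplitYr = 2126,
              migrantsWildFromMeat = 1.12, migrantsWildFromEggDp = 3.92)
    nuW <- real[["NeWild"]] / Nref
    params <- c(
        nuA = real[["NeAncestral"]] / Nref,
        nuW = nuW,
        nuM = real[["NeMeat"]] / Nref,
        nuE = real[["NeEggDp"]] / Nref,
        nuD0 = real[["NeDomBottleneck"]] / Nref,
        TA = real[["TSizeChangeYr"]] / (2 * Nref * g),
        TDOM = real[["TDomesticationYr"]] / (2 * Nref * g),
        TDIV = real[["TBreedSplitYr"]] / (2 * Nref * g),
        MWM = 2 * real[["migrantsWildFromMeat"]] / nuW,
        MWE = 2 * real[["migrantsWildFromEggDp"]] / nuW)
    list(model = buildModel("model2", params), Nref = Nref, realParams = real)
}

.default_pop_table <- function() {
    data.frame(
        population = c("MDN", "MDZ", "PK", "CV", "ML", "JD", "SM", "SX",
                       "GY"),
        deme = c("wild", "wild", "meat", "meat", "meat", "eggdp", "eggdp",
                 "eggdp", "eggdp"),
        nDiploid = c(8L, 14L, 8L, 8L, 8L, 8L, 8L, 8L, 8L),
        group_production = c("wild", "wild", "meat", "meat", "meat", "egg",
                             "egg", "egg", "dual-purpose"),
        group_plumage = c("nonwhite", "nonwhite", "white", "white", "white",
                          "nonwhite", "nonwhite", "nonwhite", "nonwhite"),
        stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Validated configuration for \code{\link{simulateCohort}}. Windows are
#' genealogically independent; sites within a window are completely linked
#' (no intra-window recombination). Sweeps are emulated by dividing the
#' domesticated demes' coalescent sizes by \code{factor} inside the sweep
#' span (accelerated coalescence: reduced diversity, elevated
#' differentiation).
#'
#' @param model a 3-population \code{DemographicModel}; default
#'   \code{\link{duckDomesticationModel}}.
#' @param Nref reference size used for theta scaling.
#' @param popTable data.frame: population, deme (wild/meat/eggdp),
#'   nDiploid, group_production, group_plumage.
#' @param nScaffolds,scaffoldLength genome shape (bp).
#' @param windowBp independent-genealogy window size (bp).
#' @param mu per-site per-generation mutation rate.
#' @param missingness per-genotype missing probability.
#' @param meanDepth mean per-sample read depth for synthesized AD/DP.
#' @param indelFraction fraction of variants emitted as INDELs (geometric
#'   lengths, 1 bp predominant).
#' @param qcFailRate fraction of records given deliberately failing QC
#'   annotations (0 = all passing).
#' @param sweeps data.frame scaffold/start/end/factor, or NULL.
#' @param diagnostic list(scaffold, positions, scheme, group) or NULL:
#'   inject variants fixed hom-alt in that group, absent elsewhere.
#' @param seed mandatory RNG seed.
#' @return a validated config (list, class \code{"SimulationConfig"}).
#' @export
simulationConfig <- function(model = NULL, Nref = 1e5,
                             popTable = .default_pop_table(),
                             nScaffolds = 5L, scaffoldLength = 100000L,
                             windowBp = 10000L, mu = 1.191e-9,
                             missingness = 0.02, meanDepth = 5,
                             indelFraction = 0.08, qcFailRate = 0,
                             sweeps = NULL, diagnostic = NULL, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (is.null(model)) model <- duckDomesticationModel(Nref)$model
    stopifnot(all(popTable$nDiploid >= 1), nScaffolds >= 1,
              scaffoldLength >= windowBp, missingness >= 0,
              missingness < 1, indelFraction >= 0, indelFraction < 1)
    if (!is.null(sweeps)) stopifnot(all(sweeps$factor >= 1))
    cfg <- list(model = model, Nref = Nref, popTable = popTable,
                nScaffolds = as.integer(nScaffolds),
                scaffoldLength = as.integer(scaffoldLength),
                windowBp = as.integer(windowBp), mu = mu,
                missingness = missingness, meanDepth = meanDepth,
                indelFraction = indelFraction, qcFailRate = qcFailRate,
                sweeps = sweeps, diagnostic = diagnostic,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

.sweep_epochs <- function(epochs, factor) {
    # domestic demes are 2 (meat) and 3 (eggdp); scale their sizes down
    ep <- epochs
    ep$nu[2:3, ] <- ep$nu[2:3, ] / factor
    ep
}

.random_alleles <- function(n, indel, lens) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(seq_len(n), function(i) {
        a <- sample(setdiff(bases, ref[i]), 1)
        a
    }, character(1))
    if (any(indel)) {
        for (i in which(indel)) {
            tail_seq <- paste(sample(bases, abs(lens[i]), replace = TRUE),
                              collapse = "")
            if (lens[i] > 0) alt[i] <- paste0(ref[i], tail_seq)
            else { alt[i] <- ref[i]; ref[i] <- paste0(ref[i], tail_seq) }
        }
    }
    list(ref = ref, alt = alt)
}

#' Genealogy summary statistics of a model
#'
#' TMRCA and total branch length (scaled units of \eqn{2 N_{ref}}
#' generations) over independent replicate genealogies.
#'
#' @param model a \code{DemographicModel}.
#' @param sampleSizes haplotypes per population.
#' @param nReps replicates.
#' @param seed RNG seed.
#' @return data.frame with \code{tmrca} and \code{totalLength}.
#' @export
simulateGenealogyStats <- function(model, sampleSizes, nReps = 1000L,
                                   seed = 1L) {
    ep <- compileEpochs(model)
    set.seed(seed)
    m <- cpp_genealogy_stats(ep$epochStart, ep$nu, ep$mig, ep$remap,
                             as.integer(sampleSizes),
                             seq_along(sampleSizes), as.integer(nReps))
    data.frame(tmrca = m[, 1], totalLength = m[, 2])
}

#' Simulate one non-recombining locus
#'
#' One structured-coalescent genealogy with Poisson infinite-sites
#' mutations; uses the current RNG stream.
#'
#' @param model a \code{DemographicModel}.
#' @param sampleSizes haplotypes per population.
#' @param thetaLocus \eqn{4 N_{ref} \mu L} for the locus.
#' @return 0/1 matrix, segregating sites x haplotypes.
#' @export
simulateLocus <- function(model, sampleSizes, thetaLocus) {
    ep <- compileEpochs(model)
    cpp_sim_locus(ep$epochStart, ep$nu, ep$mig, ep$remap,
                  as.integer(sampleSizes), seq_along(sampleSizes),
                  thetaLocus)
}

#' Simulate a full cohort with truth records
#'
#' Per-window independent genealogies under the configured demography,
#' haplotypes paired into diploids, genotype missingness, synthesized QC
#' annotations and allele depths, sweep-window size scaling and
#' diagnostic-locus injection. Fully deterministic given the seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{cohort} (a \code{VariantCohort} with populations
#'   attached), \code{truth} (list: \code{windows} GRanges with
#'   neutral/sweep labels, \code{diagnostics} GRanges, \code{params},
#'   \code{Nref}), \code{popmap} (data.frame), \code{genes} (synthetic gene
#'   GRanges).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    pt <- config$popTable
    demes <- c("wild", "meat", "eggdp")
    stopifnot(all(pt$deme %in% demes))
    # haplotype sample sizes per deme, and column layout per population
    pt$deme <- factor(pt$deme, demes)
    ord <- order(as.integer(pt$deme))
    pt <- pt[ord, ]
    sampleSizes <- as.integer(tapply(2L * pt$nDiploid, pt$deme, sum,
                                     default = 0L))
    samples <- unlist(lapply(seq_len(nrow(pt)), function(i)
        paste0(pt$population[i], "_", seq_len(pt$nDiploid[i]))))
    nDip <- sum(pt$nDiploid)
    popmap <- data.frame(
        sample = samples,
        population = rep(pt$population, pt$nDiploid),
        group_production = rep(pt$group_production, pt$nDiploid),
        group_plumage = rep(pt$group_plumage, pt$nDiploid),
        stringsAsFactors = FALSE)
    ep0 <- compileEpochs(config$model)
    theta <- 4 * config$Nref * config$mu * config$windowBp
    scafNames <- sprintf("scaffold%02d", seq_len(config$nScaffolds))
    scafLens <- setNames(rep(config$scaffoldLength, config$nScaffolds),
                         scafNames)
    nWin <- config$scaffoldLength %/% config$windowBp
    win_sc <- rep(scafNames, each = nWin)
    win_start0 <- rep((seq_len(nWin) - 1L) * config$windowBp,
                      config$nScaffolds)
    sweep_of_window <- rep(NA_real_, length(win_sc))
    if (!is.null(config$sweeps)) {
        for (i in seq_len(nrow(config$sweeps))) {
            sw <- config$sweeps[i, ]
            hitw <- win_sc == sw$scaffold &
                win_start0 < sw$end & (win_start0 + config$windowBp) > sw$start
            sweep_of_window[hitw] <- sw$factor
        }
    }
    pos_l <- ref_l <- alt_l <- list(); sc_l <- list()
    gt_l <- list()
    for (w in seq_along(win_sc)) {
        ep <- if (!is.na(sweep_of_window[w]))
            .sweep_epochs(ep0, sweep_of_window[w]) else ep0
        hap <- cpp_sim_locus(ep$epochStart, ep$nu, ep$mig, ep$remap,
                             sampleSizes, seq_along(sampleSizes), theta)
        S <- nrow(hap)
        if (S == 0) next
        S <- min(S, config$windowBp)
        hap <- hap[seq_len(S), , drop = FALSE]
        dos <- hap[, seq(1, 2 * nDip, by = 2), drop = FALSE] +
            hap[, seq(2, 2 * nDip, by = 2), drop = FALSE]
        pos <- sort(sample.int(config$windowBp, S)) + win_start0[w]
        pos_l[[length(pos_l) + 1L]] <- pos
        sc_l[[length(sc_l) + 1L]] <- rep(win_sc[w], S)
        gt_l[[length(gt_l) + 1L]] <- dos
    }
    gt <- do.call(rbind, gt_l)
    if (is.null(gt)) gt <- matrix(integer(0), 0, nDip)
    colnames(gt) <- samples
    nv <- nrow(gt)
    pos <- unlist(pos_l); sc <- unlist(sc_l)
    # variant classes and alleles
    is_indel <- runif(nv) < config$indelFraction
    ilen <- integer(nv)
    if (any(is_indel)) {
        ilen[is_indel] <- (rgeom(sum(is_indel), 0.6) + 1L) *
            sample(c(-1L, 1L), sum(is_indel), replace = TRUE)
        ilen[abs(ilen) > 50L] <- 1L
    }
    al <- .random_alleles(nv, is_indel, ilen)
    # missingness, depths, QC annotations
    gt[matrix(runif(length(gt)) < config$missingness, nrow = nv)] <- NA_integer_
    dp <- matrix(rpois(length(gt), config$meanDepth) + 1L, nrow = nv)
    adAlt <- matrix(0, nrow = nv, ncol = nDip)
    het <- !is.na(gt) & gt == 1L
    hom <- !is.na(gt) & gt == 2L
    # het alternate reads get at least half the sample depth so the
    # synthesized depths satisfy the allele-depth QC rule by construction
    adAlt[het] <- dp[het] - dp[het] %/% 2L
    adAlt[hom] <- dp[hom]
    adRef <- dp - adAlt
    dp[is.na(gt)] <- NA_integer_
    adAlt[is.na(gt)] <- NA_real_; adRef[is.na(gt)] <- NA_real_
    qc <- data.frame(
        QUAL = round(runif(nv, 60, 900), 2),
        QD = round(runif(nv, 10, 30), 2),
        FS = round(runif(nv, 0, 20), 2),
        MQ = round(runif(nv, 50, 60), 2),
        MQRankSum = round(runif(nv, -2, 2), 2),
        ReadPosRankSum = round(runif(nv, -2, 2), 2))
    if (config$qcFailRate > 0 && nv > 0) {
        fail <- which(runif(nv) < config$qcFailRate)
        pickcol <- sample(names(qc), length(fail), replace = TRUE)
        failval <- c(QUAL = 10, QD = 2, FS = 300, MQ = 20,
                     MQRankSum = -20, ReadPosRankSum = -25)
        for (i in seq_along(fail))
            qc[fail[i], pickcol[i]] <- failval[[pickcol[i]]]
    }
    gr <- GRanges(sc, IRanges(pos, width = 1L),
                  seqinfo = GenomeInfoDb::Seqinfo(scafNames,
                                                  unname(scafLens)))
    mc <- S4Vectors::DataFrame(REF = al$ref, ALT = al$alt, QUAL = qc$QUAL,
                               QD = qc$QD, FS = qc$FS, MQ = qc$MQ,
                               MQRankSum = qc$MQRankSum,
                               ReadPosRankSum = qc$ReadPosRankSum,
                               DP = as.numeric(rowSums(dp, na.rm = TRUE)))
    S4Vectors::mcols(gr) <- mc
    cohort <- VariantCohort(gt, gr, adRef = adRef, adAlt = adAlt, dp = dp)
    # diagnostic-locus injection
    diag_gr <- GRanges()
    if (!is.null(config$diagnostic)) {
        dg <- config$diagnostic
        scheme <- if (is.null(dg$scheme)) "plumage" else dg$scheme
        gcol <- paste0("group_", scheme)
        inA <- popmap[[gcol]] == dg$group
        occupied <- paste(as.character(seqnames(rowRanges(cohort))),
                          start(rowRanges(cohort)))
        posd <- integer(0)
        for (p0 in dg$positions) {
            p <- p0
            while (paste(dg$scaffold, p) %in% c(occupied,
                                                paste(dg$scaffold, posd))) {
                p <- p + 1L
                message("diagnostic position ", p0,
                        " occupied; shifted to ", p)
            }
            posd <- c(posd, p)
        }
        nd <- length(posd)
        gtd <- matrix(rep(ifelse(inA, 2L, 0L), each = nd), nrow = nd)
        colnames(gtd) <- samples
        bases <- c("A", "C", "G", "T")
        refd <- sample(bases, nd, replace = TRUE)
        altd <- vapply(refd, function(r) sample(setdiff(bases, r), 1),
                       character(1))
        grd <- GRanges(dg$scaffold, IRanges(posd, width = 1L),
                       seqinfo = GenomeInfoDb::Seqinfo(scafNames,
                                                       unname(scafLens)))
        S4Vectors::mcols(grd) <- S4Vectors::DataFrame(
            REF = refd, ALT = unname(altd),
            QUAL = round(runif(nd, 60, 900), 2),
            QD = round(runif(nd, 10, 30), 2),
            FS = round(runif(nd, 0, 20), 2),
            MQ = round(runif(nd, 50, 60), 2),
            MQRankSum = round(runif(nd, -2, 2), 2),
            ReadPosRankSum = round(runif(nd, -2, 2), 2),
            DP = as.numeric(2 * nDip * config$meanDepth))
        dpd <- matrix(rpois(nd * nDip, config$meanDepth) + 1L, nd, nDip)
        adAltd <- ifelse(gtd == 2L, dpd, 0)
        cohort2 <- VariantCohort(gtd, grd, adRef = dpd - adAltd,
                                 adAlt = adAltd, dp = dpd)
        cohort <- VariantCohort(
            rbind(genotypes(cohort), genotypes(cohort2)),
            c(rowRanges(cohort), rowRanges(cohort2)),
            adRef = rbind(assay(cohort, "adRef"), assay(cohort2, "adRef")),
            adAlt = rbind(assay(cohort, "adAlt"), assay(cohort2, "adAlt")),
            dp = rbind(assay(cohort, "dp"), assay(cohort2, "dp")))
        diag_gr <- granges(grd)
        S4Vectors::mcols(diag_gr)$group <- dg$group
    }
    cohort <- attachPopulations(cohort, popmap)
    truth_win <- GRanges(win_sc, IRanges(win_start0 + 1L,
                                         width = config$windowBp),
                         seqinfo = GenomeInfoDb::Seqinfo(scafNames,
                                                         unname(scafLens)))
    S4Vectors::mcols(truth_win)$label <-
        ifelse(is.na(sweep_of_window), "neutral", "sweep")
    S4Vectors::mcols(truth_win)$factor <- sweep_of_window
    genes <- makeGeneTrack(scafLens, nGenes = 4L * config$nScaffolds)
    list(cohort = cohort,
         truth = list(windows = truth_win, diagnostics = diag_gr,
                      params = config$model@params, Nref = config$Nref),
         popmap = popmap, genes = genes)
}

#' Synthetic gene track
#'
#' Random non-overlapping gene spans per scaffold, for exercising
#' sweep-region annotation. Marked synthetic by construction.
#'
#' @param scaffoldLengths named lengths (bp).
#' @param nGenes total genes to place.
#' @return \code{GRanges} with \code{geneId}.
#' @export
makeGeneTrack <- function(scaffoldLengths, nGenes = 20L) {
    sc <- sample(names(scaffoldLengths), nGenes, replace = TRUE)
    glen <- pmax(500L, as.integer(rgeom(nGenes, 1 / 4000)))
    start <- vapply(seq_len(nGenes), function(i)
        sample.int(max(1L, scaffoldLengths[[sc[i]]] - glen[i]), 1L),
        integer(1))
    gr <- GRanges(sc, IRanges(start, width = glen),
                  seqinfo = GenomeInfoDb::Seqinfo(names(scaffoldLengths),
                                                  unname(scaffoldLengths)))
    gr <- sort(gr)
    S4Vectors::mcols(gr)$geneId <- sprintf("SYNGENE%03d", seq_along(gr))
    gr
}

#' Write simulated outputs to files
#'
#' VCF, popmap TSV, truth JSON and a synthetic GFF3 gene track, under a
#' common prefix.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param prefix output path prefix.
#' @return named character vector of the written paths.
#' @export
writeSimulation <- function(sim, prefix) {
    paths <- c(vcf = paste0(prefix, ".vcf"),
               popmap = paste0(prefix, ".popmap.tsv"),
               truth = paste0(prefix, ".truth.json"),
               genes = paste0(prefix, ".genes.gff3"))
    writeVcfCohort(sim$cohort, paths[["vcf"]])
    pm <- sim$popmap
    write.table(data.frame(pm$sample, pm$population,
                           paste(pm$group_production, pm$group_plumage,
                                 sep = ",")),
                paths[["popmap"]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    tw <- sim$truth$windows
    truth <- list(
        windows = data.frame(scaffold = as.character(seqnames(tw)),
                             start = start(tw), end = end(tw),
                             label = S4Vectors::mcols(tw)$label),
        diagnostics = if (length(sim$truth$diagnostics))
            data.frame(scaffold = as.character(seqnames(sim$truth$diagnostics)),
                       pos = start(sim$truth$diagnostics)) else list(),
        params = as.list(sim$truth$params), Nref = sim$truth$Nref)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    rtracklayer::export(sim$genes, paths[["genes"]], format = "GFF3")
    paths
}
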