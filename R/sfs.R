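# Folded joint site-frequency spectra with hypergeometric projection.
#
# Projection to m haplotypes is the expectation over subsamples: a site
# with j alternate of n called haplotypes contributes
# w(i) = C(j,i) C(n-j, m-i) / C(n,m) to frequency class i, i.e. dhyper().
# Sites with fewer called haplotypes than the projection in any population
# are skipped (and counted).

#' Hypergeometric projection of one site
#'
#' @param j alternate-allele count at the site.
#' @param n called haplotypes at the site.
#' @param m projection size (1 <= m <= n).
#' @return numeric vector of weights over frequency classes 0..m (sums to 1).
#' @export
projectSite <- function(j, n, m) {
    if (m > n) stop("projection size exceeds called haplotypes")
    stopifnot(j >= 0, j <= n, m >= 1)
    stats::dhyper(0:m, j, n - j, m)
}

.fold_array <- function(mass) {
    d <- dim(mass)
    rev_idx <- lapply(d, function(k) k:1)
    revm <- do.call(`[`, c(list(mass), rev_idx))
    dim(revm) <- d
    tot_idx <- Reduce(`+`, lapply(seq_along(d), function(p) {
        slice_idx <- slice.index(mass, p) - 1L
        slice_idx
    }))
    tot <- sum(d - 1L)
    folded <- mass + revm
    folded[tot_idx * 2L == tot] <- folded[tot_idx * 2L == tot] / 2
    folded[tot_idx * 2L > tot] <- 0
    folded
}

.sfs_mask <- function(dims) {
    mask <- array(FALSE, dims)
    tot_idx <- Reduce(`+`, lapply(seq_along(dims), function(p)
        slice.index(mask, p) - 1L))
    tot <- sum(dims - 1L)
    mask[tot_idx * 2L > tot] <- TRUE          # structurally empty after fold
    mask[matrix(1L, 1, length(dims))] <- TRUE # non-polymorphic corner
    corner <- matrix(dims, 1)
    if (!mask[corner]) mask[corner] <- TRUE
    mask
}

#' Folded joint SFS of a cohort
#'
#' Each usable site contributes the outer product of its per-population
#' hypergeometric projection vectors to the unfolded joint spectrum, which
#' is then folded on the global minor allele (cells at exactly 50\% global
#' frequency receive half mass in each mirrored cell). Non-polymorphic
#' corners and structurally empty cells are masked.
#'
#' @param cohort a \code{VariantCohort} (SNPs are used).
#' @param popIndices named list of sample-column indices, one per
#'   population (1 to 3 populations supported).
#' @param projections integer vector of projected haplotype counts, same
#'   length and order as \code{popIndices}.
#' @return a \code{\link{FoldedSFS}}.
#' @export
jointFoldedSfs <- function(cohort, popIndices, projections) {
    npop <- length(popIndices)
    stopifnot(npop >= 1, npop <= 3, length(projections) == npop)
    projections <- as.integer(projections)
    snp <- which(variantClass(cohort) == "SNP")
    J <- N <- matrix(0L, length(snp), npop)
    for (p in seq_len(npop)) {
        ac <- siteAlleleCounts(cohort[snp, ], popIndices[[p]])
        J[, p] <- as.integer(ac$altCount)
        N[, p] <- as.integer(ac$nHap)
    }
    usable <- rowSums(N < rep(projections, each = nrow(N))) == 0
    nSkipped <- sum(!usable)
    J <- J[usable, , drop = FALSE]; N <- N[usable, , drop = FALSE]
    dims <- projections + 1L
    unfolded <- array(0, dims)
    if (nrow(J)) {
        key <- apply(cbind(J, N), 1, paste, collapse = ",")
        tab <- table(key)
        uniq <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
        uniq <- matrix(as.integer(uniq), nrow = nrow(uniq))
        for (u in seq_len(nrow(uniq))) {
            w <- projectSite(uniq[u, 1], uniq[u, npop + 1], projections[1])
            if (npop > 1) for (p in 2:npop)
                w <- outer(w, projectSite(uniq[u, p], uniq[u, npop + p],
                                          projections[p]))
            unfolded <- unfolded + as.numeric(tab[u]) * array(w, dims)
        }
    }
    mass <- .fold_array(unfolded)
    mask <- .sfs_mask(dims)
    mass[mask] <- 0
    nm <- names(popIndices)
    if (is.null(nm)) nm <- paste0("pop", seq_len(npop))
    new("FoldedSFS", mass = mass, mask = mask, projections = projections,
        popNames = nm, nSkipped = as.integer(nSkipped))
}

#' Choose projections maximizing segregating mass
#'
#' Grid search over candidate projection sizes (even haplotype counts from
#' 4 to each population's full sample size). The objective is the total
#' projected spectrum mass outside the two non-polymorphic corners, which
#' decomposes per site and is evaluated in closed form without building
#' full spectra.
#'
#' @param cohort a \code{VariantCohort}.
#' @param popIndices named list of per-population sample columns.
#' @param grid optional list of candidate m vectors per population.
#' @return list: \code{projections} (argmax), \code{mass} (objective at the
#'   argmax), \code{surface} (data.frame of all combinations).
#' @export
chooseProjection <- function(cohort, popIndices, grid = NULL) {
    npop <- length(popIndices)
    snp <- which(variantClass(cohort) == "SNP")
    J <- N <- matrix(0L, length(snp), npop)
    for (p in seq_len(npop)) {
        ac <- siteAlleleCounts(cohort[snp, ], popIndices[[p]])
        J[, p] <- as.integer(ac$altCount); N[, p] <- as.integer(ac$nHap)
    }
    if (is.null(grid))
        grid <- lapply(seq_len(npop), function(p) {
            full <- 2L * length(popIndices[[p]])
            seq.int(4L, max(4L, full), by = 2L)
        })
    # per pop & candidate: usable flag, corner weights
    per <- lapply(seq_len(npop), function(p) {
        lapply(grid[[p]], function(m) {
            ok <- N[, p] >= m
            w0 <- wt <- numeric(nrow(N))
            w0[ok] <- stats::dhyper(0, J[ok, p], N[ok, p] - J[ok, p], m)
            wt[ok] <- stats::dhyper(m, J[ok, p], N[ok, p] - J[ok, p], m)
            list(ok = ok, w0 = w0, wt = wt)
        })
    })
    combos <- expand.grid(lapply(grid, seq_along))
    surf <- data.frame(combos)
    surf$mass <- NA_real_
    best <- -Inf; bestM <- NULL
    for (i in seq_len(nrow(combos))) {
        ok <- rep(TRUE, nrow(N)); w0 <- wt <- rep(1, nrow(N))
        for (p in seq_len(npop)) {
            e <- per[[p]][[combos[i, p]]]
            ok <- ok & e$ok; w0 <- w0 * e$w0; wt <- wt * e$wt
        }
        m <- sum((1 - w0 - wt)[ok])
        surf$mass[i] <- m
        cand <- vapply(seq_len(npop), function(p)
            grid[[p]][combos[i, p]], integer(1))
        # ties broken toward the larger projection (keep more haplotypes)
        if (m > best + 1e-9 ||
            (m > best - 1e-9 && !is.null(bestM) && sum(cand) > sum(bestM))) {
            best <- max(m, best)
            bestM <- cand
        } else if (is.null(bestM)) {
            best <- m
            bestM <- cand
        }
    }
    for (p in seq_len(npop))
        surf[[p]] <- grid[[p]][combos[, p]]
    names(surf)[seq_len(npop)] <- paste0("m_", names(popIndices))
    list(projections = bestM, mass = best, surface = surf)
}

#' Thin sites to a retention fraction
#'
#' Uniform random retention without replacement (to alleviate linkage
#' between markers); seeded and reproducible; output order preserved.
#'
#' @param cohort a \code{VariantCohort}.
#' @param fraction retention fraction in (0, 1].
#' @param seed integer RNG seed (mandatory).
#' @param systematic take every \code{1/fraction}-th site instead of a
#'   random subset.
#' @return the thinned \code{VariantCohort}.
#' @export
thinSites <- function(cohort, fraction = 0.01, seed, systematic = FALSE) {
    stopifnot(fraction > 0, fraction <= 1)
    if (fraction == 1) return(cohort)
    n <- nrow(cohort)
    k <- round(fraction * n)
    if (systematic) {
        keep <- round(seq(1, n, length.out = k))
    } else {
        set.seed(seed)
        keep <- sort(sample.int(n, k))
    }
    cohort[keep, ]
}

#' Subset a cohort by a BED-style region mask
#'
#' Used e.g. to restrict the spectrum to noncoding regions before
#' demographic inference.
#'
#' @param cohort a \code{VariantCohort}.
#' @param mask \code{GRanges} of regions to keep (or drop).
#' @param invert drop instead of keep.
#' @return the subset \code{VariantCohort}.
#' @export
subsetByMask <- function(cohort, mask, invert = FALSE) {
    hit <- IRanges::overlapsAny(rowRanges(cohort), mask)
    cohort[xor(hit, invert), ]
}

#' Serialize / read a folded spectrum as plain text
#'
#' @param sfs a \code{FoldedSFS}.
#' @param path file path.
#' @return \code{readFoldedSfs} returns a \code{FoldedSFS}.
#' @export
writeFoldedSfs <- function(sfs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste("#pops", paste(sfs@popNames, collapse = " ")),
                 paste("#skipped", sfs@nSkipped),
                 paste(sfs@projections, collapse = " "),
                 paste(format(as.vector(sfs@mass), digits = 17),
                       collapse = " "),
                 paste(as.integer(as.vector(sfs@mask)), collapse = " ")),
               con)
    invisible(path)
}

#' @rdname writeFoldedSfs
#' @export
readFoldedSfs <- function(path) {
    ln <- readLines(path)
    pops <- strsplit(sub("^#pops ", "", ln[1]), " ")[[1]]
    skipped <- as.integer(sub("^#skipped ", "", ln[2]))
    proj <- as.integer(strsplit(ln[3], " ")[[1]])
    mass <- array(as.numeric(strsplit(ln[4], " ")[[1]]), proj + 1L)
    mask <- array(as.logical(as.integer(strsplit(ln[5], " ")[[1]])),
                  proj + 1L)
    new("FoldedSFS", mass = mass, mask = mask, projections = proj,
        popNames = pops, nSkipped = skipped)
}
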