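# Population-structure utilities: genetic relationship matrix, PCA,
# allele-sharing distances, neighbor-joining tree.

#' Genetic relationship matrix
#'
#' \eqn{G_{jk} = \frac{1}{M}\sum_m \frac{(x_{jm}-2p_m)(x_{km}-2p_m)}
#' {2p_m(1-p_m)}} over SNPs with sample allele frequency \eqn{p_m} in
#' (0, 1); missing genotypes are mean-imputed per site (standard GRM
#' convention); monomorphic sites are excluded.
#'
#' @param cohort a \code{VariantCohort} (apply
#'   \code{\link{filterStructureSites}} first).
#' @return symmetric samples x samples matrix.
#' @export
grMatrix <- function(cohort) {
    gt <- genotypes(cohort)
    storage.mode(gt) <- "double"
    n <- colSums(!is.na(gt))
    p <- rowSums(gt, na.rm = TRUE) / (2 * rowSums(!is.na(gt)))
    keep <- !is.na(p) & p > 0 & p < 1
    gt <- gt[keep, , drop = FALSE]
    p <- p[keep]
    x <- sweep(gt, 1, 2 * p)      # center by row (per-site 2p)
    x[is.na(x)] <- 0              # mean imputation = centered zero
    w <- 1 / sqrt(2 * p * (1 - p))
    xs <- x * w
    crossprod(xs) / nrow(xs)
}

#' Principal components of a relationship matrix
#'
#' Top-k eigenpairs, descending; variance fractions over the non-negative
#' part of the spectrum.
#'
#' @param grm symmetric matrix from \code{\link{grMatrix}}.
#' @param k number of eigenvectors (default 20, capped at the dimension).
#' @return list: \code{vectors} (samples x k), \code{values},
#'   \code{varianceExplained} (fractions).
#' @export
grmPca <- function(grm, k = 20L) {
    stopifnot(isSymmetric(unname(grm), tol = 1e-8))
    e <- eigen(grm, symmetric = TRUE)
    k <- min(k, ncol(grm))
    pos <- pmax(e$values, 0)
    list(vectors = e$vectors[, seq_len(k), drop = FALSE],
         values = e$values[seq_len(k)],
         varianceExplained = e$values[seq_len(k)] / sum(pos))
}

#' Pairwise allele-sharing distance matrix
#'
#' \eqn{d_{jk} = \frac{1}{M_{jk}} \sum_m |x_{jm} - x_{km}| / 2} over sites
#' called in both samples (pairwise-complete deletion); identical samples
#' have distance 0, opposite homozygotes at every site distance 1.
#'
#' @param cohort a \code{VariantCohort}.
#' @return symmetric distance matrix with sample dimnames.
#' @export
alleleSharingDistance <- function(cohort) {
    gt <- genotypes(cohort)
    storage.mode(gt) <- "double"
    ns <- ncol(gt)
    ok <- !is.na(gt)
    g0 <- gt; g0[!ok] <- 0
    # |xj - xk|/2 decomposes over dosage products:
    # sum |xj-xk| = sum xj + sum xk - 2*sum min(xj,xk); easier pairwise loop
    d <- matrix(0, ns, ns, dimnames = list(colnames(gt), colnames(gt)))
    for (j in seq_len(ns - 1)) {
        for (kk in (j + 1):ns) {
            both <- ok[, j] & ok[, kk]
            M <- sum(both)
            d[j, kk] <- d[kk, j] <- if (M > 0)
                sum(abs(gt[both, j] - gt[both, kk])) / (2 * M) else NA_real_
        }
    }
    d
}

#' Aggregate a sample distance matrix to population means
#'
#' @param d sample distance matrix.
#' @param populations named population vector (sample -> population).
#' @return population-level distance matrix (mean over cross pairs).
#' @export
populationDistance <- function(d, populations) {
    pops <- unique(populations[rownames(d)])
    out <- matrix(0, length(pops), length(pops),
                  dimnames = list(pops, pops))
    for (i in seq_along(pops)) for (j in seq_along(pops)) {
        if (i == j) next
        si <- names(populations)[populations == pops[i]]
        sj <- names(populations)[populations == pops[j]]
        out[i, j] <- mean(d[si, sj, drop = FALSE])
    }
    out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining (Q-matrix agglomeration, standard branch
#' lengths) via ape; taxa are ordered by label before agglomeration so tie
#' handling is deterministic. The 2-taxon degenerate case returns a single
#' edge of the given length.
#'
#' @param d symmetric distance matrix with dimnames.
#' @return an \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
    if (any(!is.finite(d))) stop("non-finite distances")
    if (nrow(d) < 2) stop("need at least 2 taxa")
    labs <- sort(rownames(d))
    d <- d[labs, labs]
    if (nrow(d) == 2) {
        tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                   edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                   tip.label = labs, Nnode = 1L)
        class(tr) <- "phylo"
        return(tr)
    }
    ape::nj(stats::as.dist(d))
}

#' Write a square PHYLIP distance matrix
#'
#' @param d distance matrix.
#' @param path output path.
#' @export
writePhylip <- function(d, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(format(nrow(d)), con)
    for (i in seq_len(nrow(d)))
        writeLines(paste(formatC(rownames(d)[i], width = -10),
                         paste(format(d[i, ], digits = 8),
                               collapse = " ")), con)
    invisible(path)
}
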