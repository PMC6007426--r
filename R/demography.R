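# Demographic scenarios, Monte-Carlo expected SFS, composite-likelihood
# fitting, AIC comparison, real-unit scaling and bootstrap intervals.
#
# The expected folded joint SFS is computed from independent structured-
# coalescent genealogies by the branch-length method (each lineage's
# waiting time accrues to the frequency class of its descendant counts),
# which gives the expected spectrum under infinite sites without a
# diffusion solver.  A fixed simulation seed per optimization (common
# random numbers) makes the objective deterministic and smooth in the
# parameters.

.scenario_params <- list(
    model1 = c("nuA", "nuW", "nuM", "nuE", "TA", "TDOM", "MWM", "MWE"),
    model2 = c("nuA", "nuW", "nuM", "nuE", "nuD0", "TA", "TDOM", "TDIV",
               "MWM", "MWE"),
    model3 = c("nuA", "nuW", "nuM", "nuE", "TA", "TM", "TE", "MWM", "MWE"),
    model4 = c("nuA", "nuW", "nuM", "nuE", "TA", "TM", "TE", "MWM", "MWE"))

#' Build a domestication demographic model
#'
#' Four scenarios for a wild population and two domesticated lineages
#' (meat; egg/dual-purpose), all in scaled units (sizes relative to the
#' ancestral reference \eqn{N_{ref}}, times in \eqn{2 N_{ref}} generations
#' backwards, migration \eqn{2 N_{ref} m}):
#' \describe{
#'   \item{model1}{simultaneous domestication of both breeds at
#'     \code{TDOM} (trifurcation).}
#'   \item{model2}{a single domestication at \code{TDOM} founding an
#'     ancestral domesticated population of size \code{nuD0}, which splits
#'     into the two breeds at \code{TDIV < TDOM}.}
#'   \item{model3}{two independent domestications, meat first
#'     (\code{TM > TE}).}
#'   \item{model4}{two independent domestications, egg/dual-purpose first
#'     (\code{TE > TM}).}
#' }
#' All scenarios share an ancestral size change to \code{nuA} at \code{TA}
#' and continuous migration into the wild population from each breed
#' (\code{MWM}, \code{MWE}) while the breed exists.
#'
#' @param scenario \code{"model1"}..\code{"model4"}, or \code{"custom"}
#'   with \code{epochs}.
#' @param params named numeric vector, complete for the scenario.
#' @param epochs precompiled epoch list for \code{scenario = "custom"}
#'   (see \code{\link{epochModel}}).
#' @return a \code{\link{DemographicModel}}.
#' @export
buildModel <- function(scenario, params = numeric(0), epochs = list()) {
    if (scenario == "custom") {
        m <- new("DemographicModel", scenario = "custom", params = params,
                 popNames = attr(epochs, "popNames"))
        attr(m@params, "epochs") <- epochs
        return(m)
    }
    need <- .scenario_params[[scenario]]
    if (is.null(need)) stop("unknown scenario: ", scenario)
    miss <- setdiff(need, names(params))
    if (length(miss))
        stop("missing parameter(s) for ", scenario, ": ",
             paste(miss, collapse = ", "))
    p <- params[need]
    if (any(p[grep("^nu", need)] <= 0)) stop("population sizes must be > 0")
    if (any(p[grep("^M", need)] < 0)) stop("migration must be >= 0")
    if (scenario == "model2" && !(p[["TDIV"]] < p[["TDOM"]]))
        stop("model2 requires breed divergence more recent than ",
             "domestication (TDIV < TDOM)")
    if (scenario == "model3" && !(p[["TM"]] > p[["TE"]]))
        stop("model3 requires the meat breed to be domesticated first ",
             "(TM > TE)")
    if (scenario == "model4" && !(p[["TE"]] > p[["TM"]]))
        stop("model4 requires the egg/dual-purpose breed to be ",
             "domesticated first (TE > TM)")
    tm <- p[grep("^T", need)]
    if (p[["TA"]] <= max(tm[names(tm) != "TA"]))
        stop("ancestral size change must predate all domestication events")
    if (any(tm <= 0)) stop("event times must be > 0")
    new("DemographicModel", scenario = scenario, params = p,
        popNames = c("wild", "meat", "eggdp"))
}

#' Assemble a custom epoch model
#'
#' Low-level epoch representation used by the coalescent engine: epoch
#' start times (ascending, backwards from 0), per-epoch deme sizes
#' \code{nu} (demes x epochs), backwards migration rates \code{mig}
#' (demes x demes x epochs; \code{mig[i,j,e]} is the per-lineage rate of
#' jumping from deme i to deme j) and a deme \code{remap} applied on entry
#' to each epoch.
#'
#' @param epochStart numeric vector of epoch start times.
#' @param nu matrix demes x epochs of relative sizes.
#' @param mig array demes x demes x epochs.
#' @param remap integer matrix demes x epochs (1-based deme targets).
#' @param popNames names of the sampled populations (demes 1..npop).
#' @return a \code{DemographicModel} with scenario \code{"custom"}.
#' @export
epochModel <- function(epochStart, nu, mig = NULL, remap = NULL,
                       popNames = NULL) {
    nd <- nrow(nu); ne <- ncol(nu)
    if (is.null(mig)) mig <- array(0, c(nd, nd, ne))
    if (is.null(remap)) remap <- matrix(rep(seq_len(nd), ne), nd, ne)
    ep <- list(epochStart = as.numeric(epochStart), nu = nu,
               mig = as.numeric(mig), remap = remap)
    if (is.null(popNames)) popNames <- paste0("pop", seq_len(nd))
    attr(ep, "popNames") <- popNames
    buildModel("custom", epochs = ep)
}

#' Compile a model into epochs for the coalescent engine
#'
#' @param model a \code{DemographicModel}.
#' @return list with \code{epochStart}, \code{nu}, \code{mig}, \code{remap}.
#' @export
compileEpochs <- function(model) {
    if (model@scenario == "custom")
        return(attr(model@params, "epochs"))
    p <- as.list(model@params)
    mk_mig <- function(mwm, mwe) {
        m <- array(0, c(3, 3, 1)); m[1, 2, 1] <- mwm; m[1, 3, 1] <- mwe
        as.numeric(m)
    }
    id <- 1:3
    if (model@scenario == "model1") {
        ep <- list(
            epochStart = c(0, p$TDOM, p$TA),
            nu = cbind(c(p$nuW, p$nuM, p$nuE), c(p$nuA, 1, 1), c(1, 1, 1)),
            mig = c(mk_mig(p$MWM, p$MWE), rep(0, 9), rep(0, 9)),
            remap = cbind(id, c(1L, 1L, 1L), id))
    } else if (model@scenario == "model2") {
        ep <- list(
            epochStart = c(0, p$TDIV, p$TDOM, p$TA),
            nu = cbind(c(p$nuW, p$nuM, p$nuE), c(p$nuW, p$nuD0, 1),
                       c(p$nuA, 1, 1), c(1, 1, 1)),
            mig = c(mk_mig(p$MWM, p$MWE), rep(0, 27)),
            remap = cbind(id, c(1L, 2L, 2L), c(1L, 1L, 1L), id))
    } else if (model@scenario == "model3") {
        ep <- list(
            epochStart = c(0, p$TE, p$TM, p$TA),
            nu = cbind(c(p$nuW, p$nuM, p$nuE), c(p$nuW, p$nuM, 1),
                       c(p$nuA, 1, 1), c(1, 1, 1)),
            mig = c(mk_mig(p$MWM, p$MWE), mk_mig(p$MWM, 0), rep(0, 18)),
            remap = cbind(id, c(1L, 2L, 1L), c(1L, 1L, 1L), id))
    } else if (model@scenario == "model4") {
        ep <- list(
            epochStart = c(0, p$TM, p$TE, p$TA),
            nu = cbind(c(p$nuW, p$nuM, p$nuE), c(p$nuW, 1, p$nuE),
                       c(p$nuA, 1, 1), c(1, 1, 1)),
            mig = c(mk_mig(p$MWM, p$MWE), mk_mig(0, p$MWE), rep(0, 18)),
            remap = cbind(id, c(1L, 1L, 3L), c(1L, 1L, 1L), id))
    } else stop("unknown scenario")
    attr(ep, "popNames") <- model@popNames
    ep
}

#' Expected folded joint SFS of a model
#'
#' Monte-Carlo expectation over \code{nReps} independent structured-
#' coalescent genealogies using accumulated branch lengths per joint
#' frequency class; folded on the global minor allele and normalized to
#' proportions over unmasked cells.
#'
#' @param model a \code{DemographicModel}.
#' @param sampleSizes integer vector of sampled haplotypes per population.
#' @param nReps number of genealogies (>= 1000 recommended).
#' @param seed RNG seed; fixing it across likelihood evaluations gives a
#'   deterministic objective (common random numbers).
#' @param fold return the folded spectrum (default) or raw unfolded
#'   branch-length proportions.
#' @return a \code{\link{FoldedSFS}} of expected proportions.
#' @export
expectedSfs <- function(model, sampleSizes, nReps = 10000L, seed = 1L,
                        fold = TRUE) {
    ep <- compileEpochs(model)
    set.seed(seed)
    flat <- cpp_branch_sfs(ep$epochStart, ep$nu, ep$mig, ep$remap,
                           as.integer(sampleSizes),
                           seq_along(sampleSizes), as.integer(nReps))
    dims <- as.integer(sampleSizes) + 1L
    arr <- array(flat, dims)
    if (fold) arr <- .fold_array(arr)
    mask <- .sfs_mask(dims)
    arr[mask] <- 0
    tot <- sum(arr)
    if (tot > 0) arr <- arr / tot
    new("FoldedSFS", mass = arr, mask = mask,
        projections = as.integer(sampleSizes),
        popNames = attr(ep, "popNames")[seq_along(sampleSizes)],
        nSkipped = 0L)
}

#' Poisson composite log-likelihood of an observed spectrum
#'
#' \eqn{\sum_{cells} [\,o \ln\mu - \mu - \ln o!\,]} over unmasked cells,
#' with \eqn{\mu} = expected proportions scaled by the analytically optimal
#' \eqn{\hat\theta = \sum o / \sum e}; empty model cells receive a
#' pseudocount before the log.
#'
#' @param observed,expected \code{FoldedSFS} with identical dims and mask
#'   (\code{expected} holds proportions, e.g. from
#'   \code{\link{expectedSfs}}).
#' @param eps pseudocount for empty expected cells.
#' @return list: \code{loglik}, \code{theta}.
#' @export
compositeLogLik <- function(observed, expected, eps = 1e-12) {
    if (!identical(dim(observed@mass), dim(expected@mass)))
        stop("dimension mismatch between observed and expected spectra")
    use <- !(observed@mask | expected@mask)
    o <- observed@mass[use]
    e <- expected@mass[use]
    theta <- sum(o) / sum(e)
    mu <- pmax(e * theta, eps)
    list(loglik = sum(o * log(mu) - mu - lgamma(o + 1)), theta = theta)
}

.set_params <- function(model, values) {
    p <- model@params
    p[names(values)] <- values
    buildModel(model@scenario, p)
}

#' Fit a demographic model by composite likelihood
#'
#' Derivative-free (Nelder-Mead) maximization over log-transformed free
#' parameters, best of \code{restarts} independent log-uniform starting
#' points within bounds; the expected SFS uses a fixed simulation seed so
#' the objective is deterministic. Non-convergence (best two restarts
#' disagreeing by more than \code{tol} log-units) is flagged, not raised.
#'
#' @param model a \code{DemographicModel} holding starting/fixed values.
#' @param observed observed \code{FoldedSFS} (counts).
#' @param free names of parameters to optimize.
#' @param lower,upper named bounds for the free parameters.
#' @param nReps genealogies per likelihood evaluation.
#' @param seed base seed; evaluation seed is fixed, restart draws derive
#'   from it.
#' @param restarts independent starts.
#' @param tol log-likelihood agreement defining convergence.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a \code{\link{DemographicFit}}.
#' @export
fitModel <- function(model, observed, free, lower, upper,
                     nReps = 2000L, seed = 1L, restarts = 10L,
                     tol = 1, maxit = 200L) {
    stopifnot(all(free %in% names(model@params)),
              all(free %in% names(lower)), all(free %in% names(upper)))
    sampleSizes <- observed@projections
    nev <- 0L
    objective <- function(logp) {
        nev <<- nev + 1L
        vals <- exp(logp)
        names(vals) <- free
        vals <- pmin(pmax(vals, lower[free]), upper[free])
        m <- tryCatch(.set_params(model, vals), error = function(e) NULL)
        if (is.null(m)) return(1e12)   # ordering constraint violated
        ex <- expectedSfs(m, sampleSizes, nReps = nReps, seed = seed)
        -compositeLogLik(observed, ex)$loglik
    }
    set.seed(seed + 7L)
    starts <- lapply(seq_len(restarts), function(i) {
        if (i == 1) log(pmin(pmax(model@params[free], lower[free]),
                             upper[free]))
        else runif(length(free), log(lower[free]), log(upper[free]))
    })
    results <- if (length(free) == 1L)
        lapply(starts, function(s0)
            optim(s0, objective, method = "Brent",
                  lower = log(lower[free]), upper = log(upper[free]),
                  control = list(maxit = maxit)))
    else
        lapply(starts, function(s0)
            optim(s0, objective, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-8)))
    vals <- vapply(results, `[[`, numeric(1), "value")
    ord <- order(vals)
    best <- results[[ord[1]]]
    converged <- if (restarts >= 2)
        (vals[ord[2]] - vals[ord[1]]) < tol else best$convergence == 0
    est <- exp(best$par)
    names(est) <- free
    est <- pmin(pmax(est, lower[free]), upper[free])
    fitted <- .set_params(model, est)
    ex <- expectedSfs(fitted, sampleSizes, nReps = nReps, seed = seed)
    cl <- compositeLogLik(observed, ex)
    k <- length(free)
    new("DemographicFit", model = fitted, free = free,
        loglik = cl$loglik, aic = 2 * k - 2 * cl$loglik, theta = cl$theta,
        converged = isTRUE(converged), nEval = nev)
}

#' One-parameter composite-likelihood profile fit
#'
#' Golden-section maximization over a single free parameter (log scale),
#' all other parameters fixed; common random numbers across evaluations.
#'
#' @inheritParams fitModel
#' @param param name of the free parameter.
#' @param interval length-2 search interval for the parameter.
#' @param tol convergence tolerance of the golden-section search, on the
#'   log-parameter scale.
#' @return list: \code{estimate}, \code{loglik}, \code{theta}.
#' @export
profileFit <- function(model, observed, param, interval,
                       nReps = 20000L, seed = 1L, tol = 1e-3) {
    sampleSizes <- observed@projections
    f <- function(logp) {
        vals <- setNames(exp(logp), param)
        m <- tryCatch(.set_params(model, vals), error = function(e) NULL)
        if (is.null(m)) return(1e12)
        ex <- expectedSfs(m, sampleSizes, nReps = nReps, seed = seed)
        -compositeLogLik(observed, ex)$loglik
    }
    opt <- optimize(f, log(interval), tol = tol)
    est <- exp(opt$minimum)
    vals <- setNames(est, param)
    m <- .set_params(model, vals)
    ex <- expectedSfs(m, sampleSizes, nReps = nReps, seed = seed)
    cl <- compositeLogLik(observed, ex)
    list(estimate = est, loglik = cl$loglik, theta = cl$theta)
}

#' Rank model fits by AIC
#'
#' @param fits list of \code{\link{DemographicFit}}.
#' @return data.frame sorted by ascending AIC with \code{deltaAIC}.
#' @export
compareAic <- function(fits) {
    stopifnot(length(fits) >= 2)
    df <- data.frame(
        scenario = vapply(fits, function(f) f@model@scenario, character(1)),
        k = vapply(fits, function(f) length(f@free), numeric(1)),
        loglik = vapply(fits, function(f) f@loglik, numeric(1)),
        aic = vapply(fits, function(f) f@aic, numeric(1)),
        converged = vapply(fits, function(f) f@converged, logical(1)))
    df <- df[order(df$aic), ]
    df$deltaAIC <- df$aic - df$aic[1]
    rownames(df) <- NULL
    df
}

#' Convert scaled parameters to real units
#'
#' \eqn{N_{ref} = \hat\theta / (4 \mu L)}; sizes become individuals
#' (\eqn{\nu N_{ref}}), times years (\eqn{T \cdot 2 N_{ref} g}), migration
#' migrants per generation (\eqn{M \nu_{recipient} / 2}; the recipient of
#' both migration parameters is the wild population).
#'
#' @param params named scaled parameter vector (or a
#'   \code{DemographicModel}).
#' @param theta composite-likelihood scaling \eqn{\hat\theta}; give either
#'   \code{theta} with \code{L}, or \code{Nref} directly.
#' @param mu per-site per-generation mutation rate.
#' @param g generation time in years.
#' @param L total sequence length (bp) behind \code{theta}.
#' @param Nref reference size, if known directly.
#' @return data.frame: parameter, scaled value, real value, unit.
#' @export
toRealUnits <- function(params, theta = NULL, mu = 1.191e-9, g = 1,
                        L = NULL, Nref = NULL) {
    if (is(params, "DemographicModel")) params <- params@params
    if (is.null(Nref)) {
        if (is.null(theta) || is.null(L))
            stop("give either Nref or both theta and L")
        Nref <- theta / (4 * mu * L)
    }
    nm <- names(params)
    real <- numeric(length(params))
    unit <- character(length(params))
    nuW <- if ("nuW" %in% nm) params[["nuW"]] else NA_real_
    for (i in seq_along(params)) {
        if (startsWith(nm[i], "nu")) {
            real[i] <- params[i] * Nref; unit[i] <- "individuals"
        } else if (startsWith(nm[i], "T")) {
            real[i] <- params[i] * 2 * Nref * g; unit[i] <- "years"
        } else if (startsWith(nm[i], "M")) {
            real[i] <- params[i] * nuW / 2; unit[i] <- "migrants/generation"
        } else {
            real[i] <- params[i]; unit[i] <- ""
        }
    }
    data.frame(parameter = nm, scaled = as.numeric(params), real = real,
               unit = unit, Nref = Nref, stringsAsFactors = FALSE)
}

#' Inverse of \code{toRealUnits} for a single quantity
#'
#' @param value real-unit value.
#' @param kind \code{"size"}, \code{"time"} or \code{"migration"}.
#' @param Nref reference size.
#' @param g generation time (years).
#' @param nuRecipient recipient scaled size for migration.
#' @return scaled value.
#' @export
toScaledUnits <- function(value, kind, Nref, g = 1, nuRecipient = NA) {
    switch(kind,
           size = value / Nref,
           time = value / (2 * Nref * g),
           migration = 2 * value / nuRecipient,
           stop("unknown kind"))
}

#' Block bootstrap confidence intervals by scaffold resampling
#'
#' Resamples scaffolds with replacement, rebuilds the folded spectrum and
#' refits the free parameters; percentile intervals over replicates.
#'
#' @param cohort a \code{VariantCohort}.
#' @param popIndices,projections as in \code{\link{jointFoldedSfs}}.
#' @param model starting \code{DemographicModel}.
#' @param free,lower,upper as in \code{\link{fitModel}}.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed (same seed, same intervals).
#' @param ... passed to \code{\link{fitModel}} (e.g. \code{nReps},
#'   \code{restarts}).
#' @return list: \code{ci} (data.frame parameter/lower/upper),
#'   \code{replicates} (matrix of per-replicate estimates).
#' @export
bootstrapCi <- function(cohort, popIndices, projections, model, free,
                        lower, upper, nBoot = 100L, seed = 1L, ...) {
    stopifnot(nBoot >= 2)
    scaffolds <- as.character(unique(seqnames(rowRanges(cohort))))
    if (length(scaffolds) < 2)
        warning("single scaffold: bootstrap intervals are degenerate",
                call. = FALSE)
    set.seed(seed)
    boot_seeds <- sample.int(2^30, nBoot)
    reps <- matrix(NA_real_, nBoot, length(free),
                   dimnames = list(NULL, free))
    sc_all <- as.character(seqnames(rowRanges(cohort)))
    for (b in seq_len(nBoot)) {
        set.seed(boot_seeds[b])
        pick <- sample(scaffolds, length(scaffolds), replace = TRUE)
        rows <- unlist(lapply(pick, function(s) which(sc_all == s)))
        bs <- cohort[rows, ]
        sfs <- jointFoldedSfs(bs, popIndices, projections)
        fit <- fitModel(model, sfs, free, lower, upper,
                        seed = boot_seeds[b], ...)
        reps[b, ] <- fit@model@params[free]
    }
    ci <- data.frame(parameter = free,
                     lower = apply(reps, 2, quantile, 0.025),
                     upper = apply(reps, 2, quantile, 0.975))
    rownames(ci) <- NULL
    list(ci = ci, replicates = reps)
}
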