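#' Construct ground truth for a simulated co-IP gel
#'
#' @param targetLabel character vector, one per lane (e.g. "trigger",
#'   "seed_only").
#' @param baitLabel one of \code{"ZSWIM8"}, \code{"T6B"}, \code{"none"}
#'   per lane; each target needs exactly one T6B lane and one no-bait
#'   (0 nM) lane.
#' @param baitConc bait concentration (nM) per lane; \code{NA} for T6B,
#'   0 for the no-bait lane.
#' @param trueFractionBound true fraction of target recovered, per lane,
#'   in [0, 1]. The T6B lane is conventionally set to 1 so normalized
#'   values equal pull-down fractions.
#' @param backgroundLevel additive image background (intensity units).
#' @param gain intensity units per unit fraction bound.
#' @param noiseCv coefficient of variation of the multiplicative
#'   log-normal band noise.
#' @param seed integer seed used by \code{\link{simulateCoipGel}}.
#' @return a \linkS4class{GelTruth}.
#' @export
gelTruth <- function(targetLabel, baitLabel, baitConc, trueFractionBound,
                     backgroundLevel = 100, gain = 1000, noiseCv = 0,
                     seed = 1L) {
    lanes <- DataFrame(target_label = as.character(targetLabel),
                       bait_label = as.character(baitLabel),
                       bait_conc = as.numeric(baitConc))
    new("GelTruth", lanes = lanes,
        trueFractionBound = as.numeric(trueFractionBound),
        backgroundLevel = backgroundLevel, gain = gain,
        noiseCv = noiseCv, seed = as.integer(seed))
}

#' Simulate phosphorimager band intensities for a co-IP gel
#'
#' Each lane's band intensity is
#' \code{background + gain * fraction * (1 + noise)} where the
#' multiplicative factor \code{(1 + noise)} is log-normal with mean 1 and
#' coefficient of variation \code{noiseCv}. Three blank rectangles at the
#' additive background level are emitted for background estimation.
#'
#' @param truth a \linkS4class{GelTruth}.
#' @param nBlanks number of blank rectangles.
#' @return a \linkS4class{GelQuant} with the truth embedded.
#' @export
simulateCoipGel <- function(truth, nBlanks = 3L) {
    stopifnot(is(truth, "GelTruth"))
    validObject(truth)
    .withSeed(truth@seed, {
        cv <- truth@noiseCv
        n <- nrow(truth@lanes)
        fac <- if (cv > 0) {
            s2 <- log(1 + cv^2)
            rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
        } else rep(1, n)
        lanes <- truth@lanes
        lanes$intensity <- truth@backgroundLevel +
            truth@gain * truth@trueFractionBound * fac
        new("GelQuant", lanes = lanes,
            blanks = rep(truth@backgroundLevel, nBlanks),
            truth = list(truth = truth))
    })
}

setMethod("show", "GelQuant", function(object) {
    cat(sprintf("GelQuant: %d lanes, %d targets, %d blank rectangles\n",
                nrow(object@lanes),
                length(unique(object@lanes$target_label)),
                length(object@blanks)))
    show(head(object@lanes, 6L))
})

#' @describeIn simulateCoipGel lane table accessor.
#' @param gel a \code{GelQuant}.
#' @export
gelLanes <- function(gel) gel@lanes

#' Simulate a quadratic-isotherm titration series
#'
#' Generates fraction-bound values from the quadratic (ligand-depletion)
#' binding isotherm (\code{\link{evalQuadratic}}) across a dilution
#' series, adds Gaussian noise, and truncates to [0, 1].
#'
#' @param stockTruth true RISC stock concentration (nM).
#' @param dilutionFactors strictly monotone positive dilution factors.
#' @param targetTotal total target concentration (nM).
#' @param kdTruth true dissociation constant (nM).
#' @param fmaxTruth true plateau fraction bound, in (0, 1].
#' @param noiseSd additive Gaussian noise standard deviation (fraction
#'   units).
#' @param seed integer seed.
#' @return a \linkS4class{TitrationCurve} with the truth embedded.
#' @export
simulateTitration <- function(stockTruth, dilutionFactors, targetTotal,
                              kdTruth, fmaxTruth, noiseSd = 0, seed = 1L) {
    .assertScalar(stockTruth, "stockTruth", lower = 0, strictLower = TRUE)
    .assertScalar(targetTotal, "targetTotal", lower = 0, strictLower = TRUE)
    .assertScalar(kdTruth, "kdTruth", lower = 0, strictLower = TRUE)
    .assertScalar(fmaxTruth, "fmaxTruth", lower = 0, upper = 1,
                  strictLower = TRUE)
    .assertScalar(noiseSd, "noiseSd", lower = 0)
    if (any(dilutionFactors <= 0))
        stop("dilution factors must be > 0", call. = FALSE)
    f <- evalQuadratic(stockTruth, dilutionFactors, targetTotal, kdTruth,
                       fmaxTruth)
    .withSeed(seed, {
        if (noiseSd > 0)
            f <- pmin(pmax(f + rnorm(length(f), 0, noiseSd), 0), 1)
        new("TitrationCurve", dilutionFactors = as.numeric(dilutionFactors),
            fractionBound = f, targetTotal = targetTotal,
            fitted = list(), diagnostics = list(),
            truth = list(stock = stockTruth, kd = kdTruth,
                         fmax = fmaxTruth, noiseSd = noiseSd))
    })
}

setMethod("show", "TitrationCurve", function(object) {
    cat(sprintf("TitrationCurve: %d points, target_T = %g nM, DF %g..%g\n",
                length(object@dilutionFactors), object@targetTotal,
                min(object@dilutionFactors), max(object@dilutionFactors)))
    if (length(object@fitted))
        cat(sprintf("  fit: [stock] = %.4g nM, K_D = %.4g nM, F_max = %.4g (converged: %s)\n",
                    object@fitted$stock, object@fitted$kd,
                    object@fitted$fmax,
                    isTRUE(object@diagnostics$converged)))
})

#' @describeIn simulateTitration fitted parameter accessor (list with
#'   \code{stock}, \code{kd}, \code{fmax}; empty before fitting).
#' @param curve a \code{TitrationCurve}.
#' @export
titrationFit <- function(curve) curve@fitted
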