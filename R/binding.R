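#' Quadratic (ligand-depletion) binding isotherm
#'
#' Fraction of total target bound when RISC at concentration
#' \code{DF * stock} equilibrates with target at total concentration
#' \code{targetTotal} under mass-action binding with dissociation constant
#' \code{kd}, scaled by the plateau \code{fmax}:
#' \deqn{F = \frac{(D S + T + K) - \sqrt{(D S + T + K)^2 - 4 D S T}}{2T}
#'       F_{max}}
#' Computed via the algebraically equivalent form
#' \eqn{2 D S F_{max} / (b + \sqrt{b^2 - 4 D S T})}, which is numerically
#' stable when the discriminant approaches zero.
#'
#' @param stock RISC stock concentration (nM), > 0.
#' @param df dilution factor(s), > 0 (vectorized).
#' @param targetTotal total target concentration (nM), > 0.
#' @param kd dissociation constant (nM), > 0.
#' @param fmax plateau fraction bound, in (0, 1].
#' @return fraction bound, in [0, \code{fmax}].
#' @export
evalQuadratic <- function(stock, df, targetTotal, kd, fmax) {
    .assertScalar(stock, "stock", lower = 0, strictLower = TRUE)
    .assertScalar(targetTotal, "targetTotal", lower = 0, strictLower = TRUE)
    .assertScalar(kd, "kd", lower = 0, strictLower = TRUE)
    .assertScalar(fmax, "fmax", lower = 0, upper = 1, strictLower = TRUE)
    if (any(df <= 0)) stop("'df' must be > 0", call. = FALSE)
    A <- df * stock
    b <- A + targetTotal + kd
    disc <- pmax(b^2 - 4 * A * targetTotal, 0)
    2 * A * fmax / (b + sqrt(disc))
}

.quadRss <- function(par, df, f, targetTotal) {
    sum((f - evalQuadratic(par[1L], df, targetTotal, exp(par[2L]),
                           par[3L]))^2)
}

#' Fit the quadratic isotherm to a titration series
#'
#' Constrained Levenberg-Marquardt least squares (via
#' \code{\link[minpack.lm]{nlsLM}}) of the quadratic binding isotherm over
#' (stock, log K_D, F_max), started from a grid of initial values: stock
#' at 0.1/1/10 times a data-derived nominal, K_D at 0.01/1/100 nM, and
#' F_max at 0.3/0.6/0.9. F_max is constrained to (0, 1); K_D is fit in
#' log-transformed space. The best-residual fit across all converging
#' starts is returned.
#'
#' @param curve a \linkS4class{TitrationCurve} with at least 4 points
#'   spanning at least one decade of dilution factor.
#' @param stockNominal optional nominal stock concentration used to
#'   center the start grid; when NULL it is estimated from the dilution
#'   factor at half-maximal binding.
#' @param kdStarts,fmaxStarts start grids for K_D (nM) and F_max.
#' @return the curve with \code{fitted} (\code{stock}, \code{kd},
#'   \code{fmax}) and \code{diagnostics} (residual norm, convergence,
#'   start grid, number of converging starts) filled.
#' @export
fitQuadraticTitration <- function(curve, stockNominal = NULL,
                                  kdStarts = c(1e-2, 1, 1e2),
                                  fmaxStarts = c(0.3, 0.6, 0.9)) {
    stopifnot(is(curve, "TitrationCurve"))
    df <- curve@dilutionFactors
    f <- curve@fractionBound
    tT <- curve@targetTotal
    if (length(df) < 4L)
        stop("at least 4 titration points are required", call. = FALSE)
    if (max(df) / min(df) < 10)
        stop("dilution factors must span at least one decade", call. = FALSE)
    if (all(f <= 0) || max(f) - min(f) < 1e-12)
        stop("fraction bound carries no signal; fit is unidentifiable",
             call. = FALSE)
    if (is.null(stockNominal)) {
        half <- df[which.min(abs(f - max(f) / 2))]
        stockNominal <- tT / half
    }
    starts <- expand.grid(stock = stockNominal * c(0.1, 1, 10),
                          logKd = log(kdStarts), fmax = fmaxStarts)
    best <- NULL
    nConv <- 0L
    dat <- data.frame(df = df, f = f)
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                f ~ evalQuadratic(stock, df, tT, exp(logKd), fmax),
                data = dat,
                start = as.list(starts[i, ]),
                lower = c(stock = 1e-12, logKd = log(1e-9), fmax = 1e-6),
                upper = c(stock = Inf, logKd = log(1e9), fmax = 1),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) next
        nConv <- nConv + 1L
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(par = stats::coef(fit), rss = rss)
    }
    if (is.null(best))
        stop("quadratic titration fit failed to converge from every start",
             call. = FALSE)
    curve@fitted <- list(stock = unname(best$par["stock"]),
                         kd = unname(exp(best$par["logKd"])),
                         fmax = unname(best$par["fmax"]))
    curve@diagnostics <- list(rss = best$rss, converged = TRUE,
                              nStartsConverged = nConv,
                              startGrid = starts)
    curve
}

#' Fit a single-site (hyperbolic) binding model
#'
#' Least-squares fit of \eqn{R = R_{max} c / (K_D + c)} with K_D in log
#' space, as used for bio-layer interferometry and protein-excess
#' filter-binding series.
#'
#' @param conc concentrations (> 0), at least 4.
#' @param response measured responses (same length).
#' @return list with \code{kd}, \code{rmax}, \code{rss},
#'   \code{converged}.
#' @export
fitSingleSite <- function(conc, response) {
    if (length(conc) < 4L || length(conc) != length(response))
        stop("need >= 4 (conc, response) pairs", call. = FALSE)
    if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
    if (max(abs(response)) < 1e-12 || max(response) - min(response) < 1e-12)
        stop("response carries no signal; fit is unidentifiable",
             call. = FALSE)
    half <- conc[which.min(abs(response - max(response) / 2))]
    dat <- data.frame(conc = conc, response = response)
    best <- NULL
    for (kd0 in half * c(0.1, 1, 10)) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                response ~ rmax * conc / (exp(logKd) + conc), data = dat,
                start = list(rmax = max(response), logKd = log(kd0)),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(par = stats::coef(fit), rss = rss)
    }
    if (is.null(best))
        stop("single-site fit failed to converge", call. = FALSE)
    list(kd = unname(exp(best$par["logKd"])),
         rmax = unname(best$par["rmax"]),
         rss = best$rss, converged = TRUE)
}

#' Fraction bound from a two-membrane filter-binding spot pair
#'
#' Bound complex is retained on nitrocellulose, free RNA on the nylon
#' membrane beneath; the fraction bound is the background-subtracted
#' nitrocellulose signal over the summed signal.
#'
#' @param nitrocellulose,nylon spot intensities (scalars or parallel
#'   vectors).
#' @param nitroBackground,nylonBackground per-membrane background levels
#'   subtracted before forming the ratio.
#' @return fraction bound in [0, 1] (negative background-subtracted
#'   signals are clipped at 0).
#' @export
filterFractionBound <- function(nitrocellulose, nylon,
                                nitroBackground = 0, nylonBackground = 0) {
    if (any(nitrocellulose < 0) || any(nylon < 0))
        stop("signals must be >= 0", call. = FALSE)
    nc <- pmax(nitrocellulose - nitroBackground, 0)
    ny <- pmax(nylon - nylonBackground, 0)
    if (any(nc + ny == 0))
        stop("fraction bound is undefined when both membranes carry no signal",
             call. = FALSE)
    nc / (nc + ny)
}
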