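#' Decreasing four-parameter Hill response
#'
#' E(d) = bottom + (top - bottom) / (1 + (d / ec50)^h). At dose 0 the
#' response is `top` (the untreated viable count); it decreases towards
#' `bottom` at saturating dose.
#'
#' @param fit A \linkS4class{HillFit}, or a named vector/list with bottom,
#'   top, ec50, hill.
#' @param dose Numeric vector of doses (>= 0).
#' @return Expected response at each dose.
#' @examples
#' f <- HillFit(bottom = 0, top = 1000, ec50 = 1, hill = 2)
#' hillResponse(f, c(0, 1, 10))
#' @export
hillResponse <- function(fit, dose) {
    p <- .asHillParams(fit)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
        (1 + (dose / p[["ec50"]])^p[["hill"]])
}

.asHillParams <- function(fit) {
    if (is(fit, "HillFit")) return(hillParams(fit))
    p <- unlist(fit)
    need <- c("bottom", "top", "ec50", "hill")
    if (!all(need %in% names(p)))
        stop("Hill parameters must provide bottom, top, ec50, hill")
    p[need]
}

.asHillFit <- function(fit) {
    if (is(fit, "HillFit")) return(fit)
    p <- .asHillParams(fit)
    HillFit(p[["bottom"]], p[["top"]], p[["ec50"]], p[["hill"]])
}

#' Fit a monotherapy dose-response curve on viable counts
#'
#' Least-squares fit of the decreasing four-parameter Hill model
#' E(d) = bottom + (top - bottom)/(1 + (d/ec50)^h). For fixed (ec50, h)
#' the model is linear in (bottom, top), so those are profiled out by
#' weighted linear least squares and only (log ec50, log h) is optimized
#' numerically, from a fixed multi-start grid on EC50 (log-spaced over the
#' positive dose range, crossed with several slope starts) to avoid local
#' minima; the procedure is fully deterministic. Doses are internally
#' rescaled by the geometric mean of the positive doses (EC50 is scaled
#' back afterwards), so the fit is invariant to the dose unit and well
#' conditioned.
#'
#' @param doses Numeric doses (>= 0); at least 4 distinct values including 0.
#' @param counts Viable counts (>= 0), same length as `doses`.
#' @param weights Optional non-negative fitting weights.
#' @param doseUnit Unit string stored with the fit.
#' @return A \linkS4class{HillFit} with estimates and their covariance.
#' @examples
#' d <- rep(c(0, 0.25, 0.5, 1, 2, 4, 8, 16), each = 2)
#' y <- hillResponse(c(bottom = 100, top = 1000, ec50 = 1, hill = 2), d)
#' fitDoseResponse(d, y)
#' @export
fitDoseResponse <- function(doses, counts, weights = NULL, doseUnit = "") {
    doses <- as.numeric(doses); counts <- as.numeric(counts)
    if (length(doses) != length(counts))
        stop("doses and counts must have the same length")
    if (any(doses < 0) || any(counts < 0))
        stop("doses and counts must be non-negative")
    ud <- sort(unique(doses))
    if (length(ud) < 4)
        stop("need at least 4 distinct doses to fit a 4-parameter curve")
    if (ud[1] != 0)
        stop("the dose series must include dose 0 (untreated control)")
    if (is.null(weights)) weights <- rep(1, length(doses))

    # flat-within-noise guard: the curve is unidentifiable without response
    mu <- tapply(counts, doses, mean)
    span <- max(mu) - min(mu)
    withinSd <- sqrt(mean(tapply(counts, doses, function(x)
        if (length(x) > 1) var(x) else NA_real_), na.rm = TRUE))
    if (is.na(withinSd)) withinSd <- 0
    if (span <= max(2 * withinSd, 0.02 * max(abs(counts), 1)))
        stop("curve unidentifiable: response is flat within noise")

    # normalize by the top dose; snapping the ratios to 12 significant
    # digits makes the fit exactly invariant to dose-unit conversions
    scaleD <- max(ud)
    d <- signif(doses / scaleD, 12)
    # occupancy weight w(d) = 1/(1 + (d/ec50)^h); E = bottom*(1-w) + top*w
    occup <- function(d, lec50, lh) {
        z <- exp(pmin(exp(lh) * (log(pmax(d, .Machine$double.xmin)) - lec50),
                      700))
        ifelse(d == 0, 1, 1 / (1 + z))
    }
    profileFit <- function(par) {
        w <- occup(d, par[1], par[2])
        X <- cbind(1 - w, w)
        fit <- lm.wfit(X, counts, weights)
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        # enforce bottom >= 0 by a one-sided refit on top alone
        if (beta[1] < 0) {
            beta[1] <- 0
            beta[2] <- sum(weights * w * counts) / sum(weights * w^2)
            fit$residuals <- counts - beta[2] * w
        }
        list(rss = sum(weights * fit$residuals^2), beta = beta)
    }
    obj <- function(par) profileFit(par)$rss
    ec50Starts <- log(exp(seq(log(min(d[d > 0])), log(max(d)),
                              length.out = 7)))
    hStarts <- log(c(0.5, 1, 2, 4))
    best <- NULL
    for (e0 in ec50Starts) for (h0 in hStarts) {
        opt <- stats::optim(c(e0, h0), obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-15, maxit = 5000))
        # polish from the optimum (restarts the simplex at full size)
        opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-15, maxit = 5000))
        if (is.null(best) || opt$value < best$value) best <- opt
    }
    pf <- profileFit(best$par)
    est <- c(bottom = unname(pf$beta[1]), top = unname(pf$beta[2]),
             ec50 = exp(best$par[1]) * scaleD, hill = exp(best$par[2]))
    if (!is.finite(est[["ec50"]]) || est[["top"]] <= est[["bottom"]] ||
        est[["hill"]] <= 0)
        stop("curve unidentifiable: no decreasing Hill curve fits the data")
    # Gauss-Newton covariance from the analytic Jacobian at the optimum
    covm <- matrix(NA_real_, 4, 4)
    nObs <- length(counts)
    if (nObs > 4) {
        ec50s <- exp(best$par[1]); h <- exp(best$par[2])
        z <- ifelse(d == 0, 0, (d / ec50s)^h)
        w <- ifelse(d == 0, 1, 1 / (1 + z))
        span <- est[["top"]] - est[["bottom"]]
        # ec50 column on the input dose scale (ec50_input = ec50s * scaleD)
        dEdEc50 <- span * h * z / ((1 + z)^2 * ec50s * scaleD)
        dEdH <- ifelse(d == 0, 0,
                       -span * z * log(pmax(d / ec50s,
                                            .Machine$double.xmin)) /
                           (1 + z)^2)
        J <- cbind(1 - w, w, dEdEc50, dEdH)
        sigma2 <- pf$rss / (nObs - 4)
        JtJ <- crossprod(J * sqrt(weights))
        vc <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
        if (!is.null(vc) && all(is.finite(vc))) covm <- vc
    }
    HillFit(est[["bottom"]], est[["top"]], est[["ec50"]], est[["hill"]],
            cov = covm, doseUnit = doseUnit)
}

#' Invert a Hill curve: the dose producing a given effect
#'
#' Closed-form inversion D(E) = ec50 * ((top - E)/(E - bottom))^(1/h),
#' defined only on the open response interval (bottom, top). Effects at or
#' outside the asymptotes return NA with a warning rather than being
#' clipped, since the equivalent dose is undefined there.
#'
#' @param fit A \linkS4class{HillFit} (or named parameter vector).
#' @param effect Effect value(s) on the response scale (viable count).
#' @return Dose(s); NA where the effect is outside (bottom, top).
#' @examples
#' f <- HillFit(bottom = 0, top = 1000, ec50 = 1, hill = 2)
#' inverseDose(f, 500)   # = ec50
#' @export
inverseDose <- function(fit, effect) {
    p <- .asHillParams(fit)
    ok <- effect > p[["bottom"]] & effect < p[["top"]]
    if (any(!ok))
        warning("effect outside the open response interval (bottom, top): ",
                "equivalent dose undefined (NA returned)")
    out <- rep(NA_real_, length(effect))
    out[ok] <- p[["ec50"]] *
        ((p[["top"]] - effect[ok]) / (effect[ok] - p[["bottom"]]))^
            (1 / p[["hill"]])
    out
}

#' Expected response of a two-drug combination under scaled Loewe additivity
#'
#' Solves the Loewe equivalent-dose equation
#' psi * (dA / DA(E) + dB / DB(E)) = 1 for the response E, where DX(E) is
#' the Hill inverse of monotherapy X. psi = 1 is exact Loewe additivity;
#' psi > 1 makes the combination act as if both doses were psi-fold larger
#' (synergy, pointwise CI = 1/psi), psi < 1 antagonism. The interaction
#' applies only when both doses are positive; monotherapy wells follow
#' their own Hill curve.
#'
#' @param hillA,hillB Monotherapy \linkS4class{HillFit}s (or parameter
#'   vectors); their response ranges should overlap.
#' @param doseA,doseB Dose vectors (recycled to a common length).
#' @param psi Interaction potency factor (> 0).
#' @return Expected viable count for each dose pair.
#' @examples
#' f <- c(bottom = 0, top = 1000, ec50 = 1, hill = 2)
#' loeweResponse(f, f, doseA = 0.5, doseB = 0.5, psi = 1)  # = E(1) = 500
#' @export
loeweResponse <- function(hillA, hillB, doseA, doseB, psi = 1) {
    if (psi <= 0) stop("psi must be positive")
    pA <- .asHillParams(hillA); pB <- .asHillParams(hillB)
    n <- max(length(doseA), length(doseB))
    doseA <- rep_len(doseA, n); doseB <- rep_len(doseB, n)
    lo <- max(pA[["bottom"]], pB[["bottom"]])
    hi <- min(pA[["top"]], pB[["top"]])
    if (lo >= hi)
        stop("monotherapy response ranges do not overlap")
    vapply(seq_len(n), function(i) {
        dA <- doseA[i]; dB <- doseB[i]
        if (dA == 0 && dB == 0)
            return((hillResponse(pA, 0) + hillResponse(pB, 0)) / 2)
        if (dB == 0) return(hillResponse(pA, dA))
        if (dA == 0) return(hillResponse(pB, dB))
        f <- function(E)
            psi * (dA / inverseDose(pA, E) + dB / inverseDose(pB, E)) - 1
        eps <- (hi - lo) * 1e-12
        if (f(hi - eps) <= 0) return(hi)       # doses too small to respond
        if (f(lo + eps) >= 0) return(lo)       # fully saturated
        uniroot(f, c(lo + eps, hi - eps), tol = eps)$root
    }, numeric(1))
}

#' Simulate a two-drug checkerboard plate of viable counts
#'
#' Builds a full dose grid (both monotherapy axes and all combinations) with
#' per-well mean viable counts from the monotherapy Hill curves and the
#' scaled-Loewe interaction model of [loeweResponse()], then multiplies each
#' well by log-normal noise with the requested coefficient of variation
#' (mean-preserving; CV = 0 gives exact means).
#'
#' @param hillA,hillB True monotherapy curves (HillFit or named vectors);
#'   tops should match (the same untreated cells).
#' @param doseGridA,doseGridB Strictly increasing dose grids starting at 0.
#' @param psi Interaction potency factor; expected pointwise CI is 1/psi.
#' @param replicates Replicate wells per dose pair (>= 1).
#' @param noiseCv Log-normal noise CV (>= 0).
#' @param seed Integer seed.
#' @param drugNames Names of the two drugs.
#' @return A \linkS4class{CombinationDataset}; the generating parameters are
#'   kept in its `truth` slot.
#' @examples
#' f <- c(bottom = 0, top = 1000, ec50 = 1, hill = 2)
#' plate <- generateCombinationPlate(f, f, c(0, 0.5, 1, 2, 4),
#'                                   c(0, 0.5, 1, 2, 4), psi = 2,
#'                                   noiseCv = 0, seed = 1)
#' plate
#' @export
generateCombinationPlate <- function(hillA, hillB, doseGridA, doseGridB,
                                     psi = 1, replicates = 3, noiseCv = 0.1,
                                     seed = NULL,
                                     drugNames = c("drugA", "drugB")) {
    for (g in list(doseGridA, doseGridB)) {
        if (is.unsorted(g, strictly = TRUE))
            stop("dose grids must be strictly increasing (non-monotone grid)")
        if (g[1] != 0) stop("dose grids must start at dose 0")
    }
    if (psi <= 0) stop("psi must be positive")
    if (replicates < 1) stop("need at least one replicate")
    if (noiseCv < 0) stop("noiseCv must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    grid <- expand.grid(dose_a = doseGridA, dose_b = doseGridB,
                        KEEP.OUT.ATTRS = FALSE)
    mu <- loeweResponse(hillA, hillB, grid$dose_a, grid$dose_b, psi = psi)
    wells <- do.call(rbind, lapply(seq_len(replicates), function(r) {
        data.frame(well = sprintf("R%02dC%02d_%d",
                                  match(grid$dose_a, doseGridA),
                                  match(grid$dose_b, doseGridB), r),
                   dose_a = grid$dose_a, dose_b = grid$dose_b,
                   replicate = r, viable_count = mu)
    }))
    if (noiseCv > 0) {
        s <- sqrt(log(1 + noiseCv^2))
        wells$viable_count <- wells$viable_count *
            rlnorm(nrow(wells), -s^2 / 2, s)
    }
    new("CombinationDataset", wells = wells, doseGridA = doseGridA,
        doseGridB = doseGridB, drugNames = drugNames,
        truth = list(hillA = .asHillParams(hillA),
                     hillB = .asHillParams(hillB), psi = psi,
                     seed = if (is.null(seed)) NA_real_ else seed))
}

#' Pointwise Loewe combination indexes over a dose grid
#'
#' For every well with at least one non-zero dose, the observed mean viable
#' count E across replicates is converted to equivalent monotherapy doses
#' and the combination index CI = dA / DA(E) + dB / DB(E) is computed from
#' the fitted monotherapy curves (terms with zero dose contribute 0). Wells
#' whose observed effect lies outside the open response range of a fit with
#' non-zero dose are reported as undefined rather than extrapolated.
#' CI below the lower threshold is called synergistic, above the upper
#' threshold antagonistic, in between additive.
#'
#' @param plate A \linkS4class{CombinationDataset}.
#' @param fitA,fitB Monotherapy \linkS4class{HillFit}s.
#' @param thresholds Lower/upper CI call thresholds (default 0.8 and 1.2).
#' @return A \linkS4class{CIMatrix} over the plate's dose grid; the (0, 0)
#'   well is undefined by construction.
#' @examples
#' f <- c(bottom = 0, top = 1000, ec50 = 1, hill = 2)
#' g <- c(0, 0.25, 0.5, 1, 2, 4)
#' plate <- generateCombinationPlate(f, f, g, g, psi = 2, noiseCv = 0,
#'                                   seed = 1)
#' fit <- fitDoseResponse(g, hillResponse(f, g), doseUnit = "uM")
#' ciValues(combinationIndex(plate, fit, fit))[2:6, 2:6]
#' @export
combinationIndex <- function(plate, fitA, fitB, thresholds = c(0.8, 1.2)) {
    stopifnot(is(plate, "CombinationDataset"))
    fitA <- .asHillFit(fitA); fitB <- .asHillFit(fitB)
    w <- plate@wells
    agg <- aggregate(viable_count ~ dose_a + dose_b, data = w, FUN = mean)
    nA <- length(plate@doseGridA); nB <- length(plate@doseGridB)
    ci <- matrix(NA_real_, nA, nB,
                 dimnames = list(format(plate@doseGridA, trim = TRUE),
                                 format(plate@doseGridB, trim = TRUE)))
    pA <- hillParams(fitA); pB <- hillParams(fitB)
    for (k in seq_len(nrow(agg))) {
        dA <- agg$dose_a[k]; dB <- agg$dose_b[k]
        if (dA == 0 && dB == 0) next
        E <- agg$viable_count[k]
        i <- match(dA, plate@doseGridA); j <- match(dB, plate@doseGridB)
        termA <- termB <- 0
        if (dA > 0) {
            if (E <= pA[["bottom"]] || E >= pA[["top"]]) next
            termA <- dA / suppressWarnings(inverseDose(fitA, E))
        }
        if (dB > 0) {
            if (E <= pB[["bottom"]] || E >= pB[["top"]]) next
            termB <- dB / suppressWarnings(inverseDose(fitB, E))
        }
        ci[i, j] <- termA + termB
    }
    if (all(is.na(ci)))
        stop("all combination indexes undefined: observed effects fall ",
             "outside the fitted response ranges; redesign the dose grids")
    call <- matrix("undefined", nA, nB, dimnames = dimnames(ci))
    call[!is.na(ci) & ci < thresholds[1]] <- "synergistic"
    call[!is.na(ci) & ci > thresholds[2]] <- "antagonistic"
    call[!is.na(ci) & ci >= thresholds[1] & ci <= thresholds[2]] <- "additive"
    new("CIMatrix", ci = ci, call = call, thresholds = thresholds,
        estimator = "pointwise Loewe interaction index from fitted Hill monotherapies")
}
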