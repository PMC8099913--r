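## Local (per-curve) and global (shared-parameter) least-squares fitting of
## melting curves to the two-state model. Bounded trust-region NLS via
## stats::nls(algorithm = "port"); standard errors from the covariance
## matrix (sqrt of its diagonal).

.NLS_CONTROL <- stats::nls.control(maxiter = 5000, tol = 1e-10,
                                   minFactor = 1e-12, warnOnly = TRUE)

## Central-difference Jacobian of the RHS of an nls formula at a parameter
## vector, respecting the (possibly vector-valued) structure of 'start'.
.numJacobian <- function(formula, data, start, par) {
    rhs <- formula[[3L]]
    shapes <- lengths(start)
    toList <- function(p) {
        out <- vector("list", length(shapes))
        names(out) <- names(shapes)
        i <- 0L
        for (k in seq_along(shapes)) {
            out[[k]] <- unname(p[i + seq_len(shapes[k])])
            i <- i + shapes[k]
        }
        out
    }
    evalAt <- function(p) eval(rhs, c(as.list(data), toList(p)))
    f0 <- evalAt(par)
    J <- matrix(NA_real_, length(f0), length(par),
                dimnames = list(NULL, names(par)))
    for (j in seq_along(par)) {
        h <- max(1e-7 * abs(par[j]), 1e-8)
        up <- par; up[j] <- up[j] + h
        dn <- par; dn[j] <- dn[j] - h
        J[, j] <- (evalAt(up) - evalAt(dn)) / (2 * h)
    }
    J
}

## Safe wrapper around bounded port NLS: returns
## list(par, se, rss, converged, message, fit).
## A fit that stops with "singular convergence" on numerically perfect data
## (residual variance < 1e-12 of the signal variance) is treated as
## converged; port cannot distinguish a flat optimum from an exact one.
.tryNls <- function(formula, data, start, lower, upper, weights = NULL) {
    cl <- list(formula, data = data, start = start, lower = lower,
               upper = upper, algorithm = "port", control = .NLS_CONTROL)
    if (!is.null(weights)) cl$weights <- weights
    fit <- tryCatch(withCallingHandlers(
        do.call(stats::nls, cl),
        warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
    if (inherits(fit, "condition"))
        return(list(par = NULL, se = NULL, rss = NA_real_, converged = FALSE,
                    message = conditionMessage(fit), fit = NULL))
    par <- stats::coef(fit)
    se <- rep(NA_real_, length(par))
    names(se) <- names(par)
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))))
        se <- sqrt(pmax(diag(vc), 0))
    r <- stats::resid(fit)
    rss <- sum(r^2)
    if (any(!is.finite(se))) {
        ## vcov() can fail when the optimizer stops on a degenerate internal
        ## factor (e.g. a numerically perfect fit); recompute from a
        ## central-difference Jacobian of the model: cov = sigma^2 (J'J)^-1
        g <- tryCatch(.numJacobian(formula, data, start, par),
                      error = function(e) NULL)
        if (!is.null(g) && all(is.finite(g))) {
            if (!is.null(weights)) g <- g * sqrt(weights)
            ctp <- tryCatch(solve(crossprod(g)), error = function(e) NULL)
            dfree <- max(1L, length(r) - length(par))
            if (!is.null(ctp) && all(is.finite(diag(ctp))))
                se <- sqrt(pmax(diag(ctp), 0) * rss / dfree)
        }
    }
    y <- r + stats::fitted(fit)
    rss0 <- sum((y - mean(y))^2)
    conv <- isTRUE(fit$convInfo$isConv) ||
        (is.finite(rss0) && rss <= 1e-12 * max(rss0, .Machine$double.eps))
    list(par = par, se = se, rss = rss, converged = conv,
         message = fit$convInfo$stopMessage, fit = fit)
}

## Initial values for one curve. Primary route: variable projection -- the
## signal model is linear in the four baseline parameters once (Tm, dH, dCp)
## are fixed, so a coarse grid over (Tm, dH) with baselines solved by linear
## least squares locates the right basin even for difficult shapes (e.g.
## cold denaturation at large dCp). The smoothed-derivative extremum
## supplies one extra Tm candidate.
.initLocal <- function(Tc, Y, window, dCp = 0) {
    ys <- .smoothQuad7(Y)
    dy <- diff(ys) / diff(Tc)
    mid <- Tc[-1] - diff(Tc) / 2
    TmDeriv <- mid[which.max(abs(dy))]
    pad <- 0.02 * diff(window)
    TmGrid <- unique(c(seq(window[1] + pad, window[2] - pad,
                           length.out = 25), TmDeriv))
    TmGrid <- TmGrid[TmGrid > window[1] & TmGrid < window[2]]
    dHGrid <- c(40, 80, 120, 200, 350, 700)
    TK <- .CtoK(Tc)
    best <- NULL
    for (Tm0 in TmGrid) {
        TmK <- .CtoK(Tm0)
        for (dH0 in dHGrid) {
            dG <- dH0 + dCp * (TK - TmK) -
                TK * (dH0 / TmK + dCp * log(TK / TmK))
            fu <- 1 / (1 + exp(dG / (.RGAS * TK)))
            X <- cbind(1 - fu, (1 - fu) * Tc, fu, fu * Tc)
            sol <- tryCatch(.lm.fit(X, Y), error = function(e) NULL)
            if (is.null(sol)) next
            rss <- sum(sol$residuals^2)
            if (is.null(best) || rss < best$rss) {
                cf <- sol$coefficients
                best <- list(TmC = Tm0, dH = dH0, bf = cf[1], mf = cf[2],
                             bu = cf[3], mu = cf[4], rss = rss)
            }
        }
    }
    best[c("TmC", "dH", "mf", "bf", "mu", "bu")]
}

.windowIdx <- function(Tc, window) {
    which(Tc >= window[1] & Tc <= window[2])
}

#' Fit each melting curve of a study individually
#'
#' Per-curve ("local") least-squares fit of the two-state signal model: six
#' parameters per curve (melting temperature Tm, unfolding enthalpy dH, and
#' the slopes and intercepts of the folded and unfolded baselines), with the
#' heat-capacity change fixed. Tm is constrained to the analysis window and
#' dH to be positive. The local estimates serve as starting values for
#' [fitGlobal()]. Curves that fail to converge are flagged, not dropped, and
#' carry the optimizer diagnostic in the result.
#'
#' @param study a \linkS4class{BindingStudy}.
#' @param window analysis window `c(Tmin, Tmax)` in degC; default the
#'   study's window. Must cover at least 8 grid points.
#' @param dCp fixed heat-capacity change (kcal/(mol K)); default 0.
#' @return A \linkS4class{MeltFit} of type `"local"`.
#' @examples
#' study <- simulateStudy(simulationSpec(noisePct = 0))
#' lf <- fitLocal(study)
#' head(curveParams(lf))
#' @export
fitLocal <- function(study, window = analysisWindow(study), dCp = 0) {
    stopifnot(is(study, "BindingStudy"))
    Tc <- temperatures(study)
    idx <- .windowIdx(Tc, window)
    if (length(idx) < 8L)
        stop("fewer than 8 temperature points inside the analysis window")
    Tw <- Tc[idx]
    L0 <- ligandConcentrations(study)
    labels <- colData(study)$label
    rows <- vector("list", ncol(study))
    for (i in seq_len(ncol(study))) {
        Yw <- assay(study)[idx, i]
        rng <- diff(range(Yw))
        if (!is.finite(rng) || rng <= 1e-12 * max(1, max(abs(Yw)))) {
            rows[[i]] <- data.frame(label = labels[i], L0 = L0[i],
                Tm = NA_real_, TmSe = NA_real_, dH = NA_real_, dHSe = NA_real_,
                mf = NA_real_, mfSe = NA_real_, bf = NA_real_, bfSe = NA_real_,
                mu = NA_real_, muSe = NA_real_, bu = NA_real_, buSe = NA_real_,
                rss = NA_real_, converged = FALSE,
                message = "no transition detected (flat signal)")
            next
        }
        st <- .initLocal(Tw, Yw, window, dCp)
        lower <- c(window[1], 1e-3, -Inf, -Inf, -Inf, -Inf)
        upper <- c(window[2], 1000, Inf, Inf, Inf, Inf)
        res <- .tryNls(
            Y ~ .meltSignal(T, TmC, dH, dCp, mf, bf, mu, bu),
            data = list(T = Tw, Y = Yw, dCp = dCp),
            start = st[c("TmC", "dH", "mf", "bf", "mu", "bu")],
            lower = lower, upper = upper)
        if (!res$converged) {
            ## multi-start fallback: sweep Tm0 over window quantiles and
            ## keep the best residual norm
            for (q in c(0.25, 0.5, 0.75)) {
                st2 <- st
                st2$TmC <- window[1] + q * diff(window)
                alt <- .tryNls(
                    Y ~ .meltSignal(T, TmC, dH, dCp, mf, bf, mu, bu),
                    data = list(T = Tw, Y = Yw, dCp = dCp),
                    start = st2[c("TmC", "dH", "mf", "bf", "mu", "bu")],
                    lower = lower, upper = upper)
                better <- !is.null(alt$par) &&
                    (is.null(res$par) || is.na(res$rss) ||
                     (is.finite(alt$rss) && alt$rss < res$rss))
                if (better) res <- alt
                if (res$converged) break
            }
        }
        p <- res$par; s <- res$se
        if (is.null(p)) p <- s <- rep(NA_real_, 6)
        rows[[i]] <- data.frame(label = labels[i], L0 = L0[i],
            Tm = p[1], TmSe = s[1], dH = p[2], dHSe = s[2],
            mf = p[3], mfSe = s[3], bf = p[4], bfSe = s[4],
            mu = p[5], muSe = s[5], bu = p[6], buSe = s[6],
            rss = res$rss, converged = res$converged,
            message = res$message)
    }
    cp <- do.call(rbind, rows)
    rownames(cp) <- NULL
    new("MeltFit", curveParams = cp,
        shared = list(mf = NA_real_, mu = NA_real_, dCp = dCp,
                      mf.se = NA_real_, mu.se = NA_real_, dCp.se = NA_real_,
                      dCpFitted = FALSE),
        type = "local", dCp = dCp, window = as.numeric(window),
        P0 = proteinConcentration(study),
        converged = all(cp$converged), rss = sum(cp$rss, na.rm = TRUE))
}

## Vectorized global model: per-curve Tm/dH/bf/bu indexed by 'idx',
## shared scalars mf/mu/dCp.
.globalMeltSignal <- function(Tc, idx, Tm, dH, bf, bu, mf, mu, dCp) {
    .meltSignal(Tc, Tm[idx], dH[idx], dCp, mf, bf[idx], mu, bu[idx])
}

#' Global fit of all melting curves with shared parameters
#'
#' Single least-squares problem over all curves of the study: the baseline
#' slopes (mf, mu) are shared across curves while Tm, dH and the baseline
#' intercepts remain per-curve, all initialized from the local fits (shared
#' slopes from the median of the local slopes). Optionally the heat-capacity
#' change upon unfolding is released as an additional global parameter,
#' always initialized at 0. Curves whose local fit failed are excluded with
#' a warning. Standard errors are the square roots of the diagonal of the
#' covariance matrix; if that matrix is singular the errors are reported as
#' `NA` while the fitted values are retained.
#'
#' @param study a \linkS4class{BindingStudy}.
#' @param init a `"local"` \linkS4class{MeltFit} from [fitLocal()]; computed
#'   on the fly if missing.
#' @param fitDCp logical: fit dCp as a global variable (start value 0)?
#' @param dCpFixed heat-capacity change (kcal/(mol K)) used when
#'   `fitDCp = FALSE`.
#' @param dCpBounds bounds for a fitted dCp; default `c(0, 20)`.
#' @param window analysis window; default from `init`.
#' @return A \linkS4class{MeltFit} of type `"global"`.
#' @examples
#' study <- simulateStudy(simulationSpec(noisePct = 0))
#' gf <- fitGlobal(study, fitLocal(study))
#' sharedParams(gf)
#' @export
fitGlobal <- function(study, init = fitLocal(study, window, dCpFixed),
                      fitDCp = FALSE, dCpFixed = 0, dCpBounds = c(0, 20),
                      window = analysisWindow(study)) {
    stopifnot(is(study, "BindingStudy"), is(init, "MeltFit"))
    window <- init@window
    cp0 <- init@curveParams
    ## exclude only curves without usable local estimates (hard failures,
    ## flat signal); flagged-but-finite local fits still provide inits
    use <- which(is.finite(cp0$Tm) & is.finite(cp0$dH) &
                 is.finite(cp0$bf) & is.finite(cp0$bu))
    if (length(use) < ncol(study))
        warning(ncol(study) - length(use),
                " curve(s) excluded from the global fit (local fit failed)")
    if (length(use) < 2L)
        stop("fewer than 2 usable curves for the global fit")
    Tc <- temperatures(study)
    ridx <- .windowIdx(Tc, window)
    n <- length(use)
    Tw <- rep(Tc[ridx], times = n)
    Yw <- as.vector(assay(study)[ridx, use])
    ci <- rep(seq_len(n), each = length(ridx))
    if (init@type == "global") {
        mf0 <- init@shared$mf
        mu0 <- init@shared$mu
    } else {
        mf0 <- stats::median(cp0$mf[use])
        mu0 <- stats::median(cp0$mu[use])
    }
    start <- list(Tm = cp0$Tm[use], dH = cp0$dH[use],
                  bf = cp0$bf[use], bu = cp0$bu[use],
                  mf = mf0, mu = mu0)
    lower <- c(rep(window[1], n), rep(1e-3, n), rep(-Inf, 2 * n), -Inf, -Inf)
    upper <- c(rep(window[2], n), rep(1000, n), rep(Inf, 2 * n), Inf, Inf)
    form <- Y ~ .globalMeltSignal(T, idx, Tm, dH, bf, bu, mf, mu, dCp)
    if (fitDCp) {
        ## The joint residual surface is a long shallow valley in dCp with
        ## spurious stops when the per-curve parameters start in the wrong
        ## basin (pronounced at large true dCp, where cold denaturation
        ## reshapes the curves). Profile the residual norm over a coarse dCp
        ## grid, walked upward from the optimization start value 0 --
        ## per-curve variable-projection inits, full fixed-dCp global fit at
        ## each grid point -- then release dCp from the profile minimizer.
        dCpGrid <- seq(max(dCpBounds[1], 0), dCpBounds[2], length.out = 6L)
        bestFix <- NULL
        prevPar <- NULL
        for (d in dCpGrid) {
            stD <- lapply(seq_len(n), function(j) {
                ii <- which(ci == j)
                .initLocal(Tw[ii], Yw[ii], window, d)
            })
            startD <- list(Tm = vapply(stD, `[[`, 0, "TmC"),
                           dH = vapply(stD, `[[`, 0, "dH"),
                           bf = vapply(stD, `[[`, 0, "bf"),
                           bu = vapply(stD, `[[`, 0, "bu"),
                           mf = stats::median(vapply(stD, `[[`, 0, "mf")),
                           mu = stats::median(vapply(stD, `[[`, 0, "mu")))
            resD <- .tryNls(form, list(T = Tw, Y = Yw, idx = ci, dCp = d),
                            startD, lower, upper)
            if (!is.null(prevPar)) {
                ## warm start from the previous grid point as an alternative
                alt <- .tryNls(form, list(T = Tw, Y = Yw, idx = ci, dCp = d),
                               prevPar, lower, upper)
                if (!is.null(alt$par) &&
                    (is.null(resD$par) || is.na(resD$rss) ||
                     (is.finite(alt$rss) && alt$rss < resD$rss)))
                    resD <- alt
            }
            if (!is.null(resD$par)) {
                p <- resD$par
                prevPar <- list(Tm = unname(p[grep("^Tm", names(p))]),
                                dH = unname(p[grep("^dH", names(p))]),
                                bf = unname(p[grep("^bf", names(p))]),
                                bu = unname(p[grep("^bu", names(p))]),
                                mf = unname(p[["mf"]]),
                                mu = unname(p[["mu"]]))
                if (is.null(bestFix) || (is.finite(resD$rss) &&
                                         resD$rss < bestFix$rss))
                    bestFix <- c(resD, list(dCp = d, start = prevPar))
            }
        }
        if (!is.null(bestFix)) {
            start <- bestFix$start
            start$dCp <- bestFix$dCp
        } else start$dCp <- dCpGrid[1]
        lower <- c(lower, dCpBounds[1])
        upper <- c(upper, dCpBounds[2])
        dat <- list(T = Tw, Y = Yw, idx = ci)
    } else {
        dat <- list(T = Tw, Y = Yw, idx = ci, dCp = dCpFixed)
    }
    res <- .tryNls(form, dat, start, lower, upper)
    if (is.null(res$par))
        stop("global fit failed: ", res$message)
    p <- res$par; s <- res$se
    pick <- function(nm) {
        j <- grep(paste0("^", nm, "[0-9]*$"), names(p))
        list(v = unname(p[j]), e = unname(s[j]))
    }
    Tm <- pick("Tm"); dH <- pick("dH"); bf <- pick("bf"); bu <- pick("bu")
    dCpV <- if (fitDCp) unname(p[["dCp"]]) else dCpFixed
    dCpSe <- if (fitDCp) unname(s[["dCp"]]) else NA_real_
    cp <- data.frame(label = cp0$label[use], L0 = cp0$L0[use],
                     Tm = Tm$v, TmSe = Tm$e, dH = dH$v, dHSe = dH$e,
                     bf = bf$v, bfSe = bf$e, bu = bu$v, buSe = bu$e,
                     converged = res$converged, row.names = NULL)
    new("MeltFit", curveParams = cp,
        shared = list(mf = unname(p[["mf"]]), mu = unname(p[["mu"]]),
                      dCp = dCpV, mf.se = unname(s[["mf"]]),
                      mu.se = unname(s[["mu"]]), dCp.se = dCpSe,
                      dCpFitted = fitDCp),
        type = "global", dCp = dCpV, window = as.numeric(window),
        P0 = proteinConcentration(study), converged = res$converged,
        rss = res$rss)
}

#' Per-curve estimates of a melt fit
#' @param fit a \linkS4class{MeltFit}.
#' @return data.frame, one row per curve.
#' @export
curveParams <- function(fit) {
    stopifnot(is(fit, "MeltFit"))
    fit@curveParams
}

#' Shared (study-global) parameters of a melt fit
#' @param fit a \linkS4class{MeltFit}.
#' @return Named list with `mf`, `mu`, `dCp` and their standard errors.
#' @export
sharedParams <- function(fit) {
    stopifnot(is(fit, "MeltFit"))
    fit@shared
}

setMethod("show", "MeltFit", function(object) {
    cp <- object@curveParams
    cat(sprintf("MeltFit (%s) of %d curves, window %.1f-%.1f degC\n",
                object@type, nrow(cp), object@window[1], object@window[2]))
    if (object@type == "global") {
        sh <- object@shared
        cat(sprintf("  shared: mf = %.4g, mu = %.4g, dCp = %.3g%s kcal/(mol K)\n",
                    sh$mf, sh$mu, sh$dCp,
                    if (sh$dCpFitted) " (fitted)" else " (fixed)"))
    }
    cat(sprintf("  Tm range %.2f-%.2f degC; rss = %.4g; converged: %s\n",
                min(cp$Tm, na.rm = TRUE), max(cp$Tm, na.rm = TRUE),
                object@rss, object@converged))
})

#' Fraction unfolded per curve at one temperature
#'
#' Evaluates, for every fitted curve, the fraction of unfolded protein at a
#' chosen analysis temperature from the curve's fitted (Tm, dH) and the
#' study-level dCp. The per-curve Tm and dH already absorb the ligand
#' effect, so no explicit ligand term enters here. Uncertainties are
#' propagated from the Tm and dH standard errors by the delta method using
#' marginal variances (parameter covariance is ignored; a documented
#' approximation).
#'
#' @param fit a \linkS4class{MeltFit} (normally the global fit).
#' @param Tiso analysis temperature (degC), inside the fit window.
#' @return data.frame with columns `label`, `L0`, `fu`, `fuErr`.
#' @examples
#' study <- simulateStudy(simulationSpec(noisePct = 0))
#' gf <- fitGlobal(study, fitLocal(study))
#' fuProfile(gf, 50)
#' @export
fuProfile <- function(fit, Tiso) {
    stopifnot(is(fit, "MeltFit"))
    if (Tiso < fit@window[1] || Tiso > fit@window[2])
        stop("'Tiso' lies outside the analysis window")
    cp <- fit@curveParams
    TK <- .CtoK(Tiso)
    fuOf <- function(Tm, dH) {
        fractionUnfolded(apparentKu(
            dGUnfolding(TK, .CtoK(Tm), dH, fit@dCp), TK))
    }
    fu <- mapply(fuOf, cp$Tm, cp$dH)
    hT <- 1e-4; hH <- 1e-3
    dTm <- (mapply(fuOf, cp$Tm + hT, cp$dH) -
            mapply(fuOf, cp$Tm - hT, cp$dH)) / (2 * hT)
    ddH <- (mapply(fuOf, cp$Tm, cp$dH + hH) -
            mapply(fuOf, cp$Tm, cp$dH - hH)) / (2 * hH)
    fuErr <- sqrt((dTm * cp$TmSe)^2 + (ddH * cp$dHSe)^2)
    data.frame(label = cp$label, L0 = cp$L0, fu = fu, fuErr = fuErr,
               row.names = NULL)
}
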