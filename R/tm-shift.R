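## "Apparent Kd" estimation from melting temperatures. Model 1 is the
## empirical single-site interpolation between two limiting melting
## temperatures; model 2 is the thermodynamic Tm-shift expression. Both
## approximate and both reported with caveats; isothermal analysis is the
## recommended route, especially below 1 uM affinity.

#' Extract a Tm-versus-ligand series from a melt fit
#'
#' @param fit a \linkS4class{MeltFit}, normally the global fit.
#' @return data.frame with columns `L0` (M), `Tm` (K) and `TmSe` (K); the
#'   protein concentration is attached as attribute `"P0"`.
#' @export
tmSeries <- function(fit) {
    stopifnot(is(fit, "MeltFit"))
    cp <- fit@curveParams
    out <- data.frame(L0 = cp$L0, Tm = .CtoK(cp$Tm), TmSe = cp$TmSe)
    out <- out[is.finite(out$Tm), ]
    if (nrow(out) < 4L) stop("need at least 4 fitted melting temperatures")
    if (sum(out$L0 == 0) < 1L) stop("series must contain an apo (L0 = 0) point")
    attr(out, "P0") <- fit@P0
    out
}

## Free-protein fraction of the exact 1:1 quadratic; (1 - a) is then the
## bound fraction interpolating Tm between its two limits.
.freeProteinFraction <- function(L0, P0, Kd) {
    (P0 - Kd - L0 + sqrt((P0 + L0 + Kd)^2 - 4 * P0 * L0)) / (2 * P0)
}

#' Apparent Kd from melting temperatures: empirical single-site model
#'
#' Fits \deqn{T_m([L]_0) = T_{m,unbound} + (T_{m,upper} - T_{m,unbound})
#' (1 - a([L]_0))} where `a` is the free-protein fraction of the exact 1:1
#' binding quadratic at the given protein concentration. The model directly
#' interpolates melting temperatures with a complexation ratio; it has no
#' physico-chemical foundation (a Kd is defined at one temperature, and Tm
#' does not converge to a well-defined upper limit) and should not be used
#' to report binding affinities. It is provided because of its popularity,
#' for comparison, and every result carries a caveat.
#'
#' @param series data.frame from [tmSeries()] (columns `L0`, `Tm` in K),
#'   with `attr(. , "P0")` or an explicit `P0` argument.
#' @param P0 protein concentration (M); default from the series attribute.
#' @return An \linkS4class{ApparentKdResult} with `model = 1`.
#' @export
fitTmModel1 <- function(series, P0 = attr(series, "P0")) {
    stopifnot(is.data.frame(series), nrow(series) >= 4L)
    .assertScalarNumeric(P0, "P0", positive = TRUE)
    Tm0 <- mean(series$Tm[series$L0 == 0])
    model <- function(L0, TmUnbound, TmUpper, log10Kd) {
        a <- .freeProteinFraction(L0, P0, 10^log10Kd)
        TmUnbound + (TmUpper - TmUnbound) * (1 - a)
    }
    Kd0 <- exp(mean(log(series$L0[series$L0 > 0])))
    res <- .tryNls(Tm ~ model(L0, TmUnbound, TmUpper, log10Kd),
                   data = series,
                   start = list(TmUnbound = Tm0,
                                TmUpper = max(series$Tm) + 1,
                                log10Kd = log10(Kd0)),
                   lower = c(0, 0, -12), upper = c(Inf, Inf, 0))
    if (is.null(res$par))
        return(new("ApparentKdResult", model = 1L, Kd = NA_real_,
                   KdStderr = NA_real_, params = c(TmUnbound = NA_real_,
                   TmUpper = NA_real_), residuals = numeric(),
                   converged = FALSE,
                   caveat = paste("model 1 has no physico-chemical foundation;",
                                  res$message)))
    p <- res$par
    se <- res$se
    Kd <- 10^p[["log10Kd"]]
    new("ApparentKdResult", model = 1L, Kd = unname(Kd),
        KdStderr = unname(Kd * log(10) * se[["log10Kd"]]),
        params = c(TmUnbound = unname(p[["TmUnbound"]]),
                   TmUpper = unname(p[["TmUpper"]]),
                   TmUnbound.se = unname(se[["TmUnbound"]]),
                   TmUpper.se = unname(se[["TmUpper"]])),
        residuals = as.numeric(stats::resid(res$fit)),
        converged = res$converged,
        caveat = paste("model 1 has no physico-chemical foundation;",
                       "apparent Kd values should not be reported as",
                       "binding affinities"))
}

#' Apparent Kd from melting temperatures: thermodynamic Tm-shift model
#'
#' Fits the rearranged Tm-shift expression
#' \deqn{T_m([L]_0) = \frac{T_{m0}}{1 - \frac{R T_{m0}}{\Delta H_{Tm0}}
#' \ln(1 + [L]_0/K_d)}} with temperatures strictly in Kelvin (the
#' \eqn{R T_{m0}/\Delta H} term is meaningless on the Celsius scale). By
#' default the apo melting temperature Tm0 and enthalpy dH_Tm0 are fixed
#' from the melt fit's apo curve and only Kd is fitted; `coFit = TRUE`
#' releases all three. The model approximates the free ligand concentration
#' by the total ligand concentration, which biases results for tight (sub
#' micromolar) binders or low ligand concentrations.
#'
#' @param series data.frame from [tmSeries()] (columns `L0`, `Tm` in K).
#' @param Tm0 apo melting temperature (K); default the series' apo Tm.
#' @param dH0 apo unfolding enthalpy at Tm0 (kcal/mol).
#' @param coFit logical: co-fit Tm0 and dH0 along with Kd?
#' @return An \linkS4class{ApparentKdResult} with `model = 2`.
#' @export
fitTmModel2 <- function(series, Tm0 = NULL, dH0 = 100, coFit = FALSE) {
    stopifnot(is.data.frame(series), nrow(series) >= 4L)
    if (is.null(Tm0)) Tm0 <- mean(series$Tm[series$L0 == 0])
    .assertScalarNumeric(Tm0, "Tm0", positive = TRUE)
    .assertScalarNumeric(dH0, "dH0", positive = TRUE)
    model2 <- function(L0, Tm0, dH0, log10Kd) {
        den <- 1 - (.RGAS * Tm0 / dH0) * log(1 + L0 / 10^log10Kd)
        Tm0 / den
    }
    Kd0 <- exp(mean(log(series$L0[series$L0 > 0])))
    ## bounds keep the denominator positive: R*Tm0/dH0 * ln(1+L0max/Kd) < 1
    if (coFit) {
        start <- list(Tm0 = Tm0, dH0 = dH0, log10Kd = log10(Kd0))
        lower <- c(200, 10, -12); upper <- c(500, 1000, 0)
    } else {
        start <- list(log10Kd = log10(Kd0))
        lmax <- max(series$L0)
        kdMin <- lmax / (exp(dH0 / (.RGAS * Tm0) * 0.999) - 1)
        lower <- max(-12, log10(kdMin)); upper <- 0
    }
    dat <- c(series[c("L0", "Tm")], if (!coFit) list(Tm0 = Tm0, dH0 = dH0))
    res <- .tryNls(Tm ~ model2(L0, Tm0, dH0, log10Kd), data = dat,
                   start = start, lower = lower, upper = upper)
    if (is.null(res$par))
        return(new("ApparentKdResult", model = 2L, Kd = NA_real_,
                   KdStderr = NA_real_,
                   params = c(Tm0 = Tm0, dHTm0 = dH0), residuals = numeric(),
                   converged = FALSE, caveat = res$message))
    p <- res$par
    Kd <- 10^p[["log10Kd"]]
    if (coFit) { Tm0 <- unname(p[["Tm0"]]); dH0 <- unname(p[["dH0"]]) }
    new("ApparentKdResult", model = 2L, Kd = unname(Kd),
        KdStderr = unname(Kd * log(10) * res$se[["log10Kd"]]),
        params = c(Tm0 = Tm0, dHTm0 = dH0),
        residuals = as.numeric(stats::resid(res$fit)),
        converged = res$converged,
        caveat = "model 2 approximates [L]free by [L]0; treat sub-uM results with caution")
}

#' Apparent Kd of a Tm-shift fit
#' @param x an \linkS4class{ApparentKdResult}.
#' @return Kd in molar units.
#' @export
apparentKd <- function(x) {
    stopifnot(is(x, "ApparentKdResult"))
    x@Kd
}

setMethod("show", "ApparentKdResult", function(object) {
    cat(sprintf("ApparentKdResult (model %d): Kd,app = %.3g M +/- %.1f%%\n",
                object@model, object@Kd,
                100 * object@KdStderr / object@Kd))
    cat("  ", paste(sprintf("%s = %.4g", names(object@params),
                            object@params), collapse = ", "), "\n")
    if (nzchar(object@caveat)) cat("  caveat:", object@caveat, "\n")
})
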