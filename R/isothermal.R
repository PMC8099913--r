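## Isothermal analysis: fit the 1:1 coupled-equilibrium binding model to
## fraction-unfolded vs ligand-concentration data at fixed temperature(s),
## and select the temperature with minimal relative Kd fitting error.

## fu([L]0) for the coupled folding/binding equilibrium. Ku and Kd are
## fitted on the log10 scale for conditioning.
.fuBindingModel <- function(L0, log10Kd, log10Ku, P0) {
    Kd <- 10^log10Kd
    Ku <- 10^log10Ku
    Lfree <- freeLigand(L0, P0, Ku, Kd)
    Ku / (Ku + 1 + Lfree / Kd)
}

#' Fit a 1:1 binding model to fraction unfolded versus ligand concentration
#'
#' At a fixed temperature the unfolding and binding equilibria give
#' \deqn{f_u([L]_0) = \frac{K_u}{K_u + 1 + [L]_{free}/K_d}} with the free
#' ligand from the mass balance ([freeLigand()]). Both Kd and Ku are fitted
#' (internally as log10 values): Ku is initialized from the apo point via
#' \eqn{K_u = f_u(0)/(1-f_u(0))} (clipped to `[1e-4, 1e4]`), Kd from the
#' geometric mean of the non-zero ligand concentrations. Standard errors are
#' taken from the covariance diagonal and the relative error reported as
#' `100 * stderr / estimate`. If the fraction unfolded barely varies with
#' ligand (max - min < 0.02) the fit is not attempted and the result is
#' flagged `"no shift detected"`; a fit ending on a parameter bound is also
#' flagged.
#'
#' @param fu data.frame with columns `L0` (M) and `fu` (and optionally
#'   `fuErr`), e.g. from [fuProfile()].
#' @param P0 protein concentration (M).
#' @param weights `"none"` (default) or `"inverse-variance"` (uses
#'   `1/fuErr^2` where finite and positive).
#' @return Named list: `Kd`, `KdStderr`, `KdRelError` (percent), `Ku`,
#'   `KuStderr`, `converged`, `flag` (empty string when clean).
#' @export
fitBindingIsothermal <- function(fu, P0, weights = c("none", "inverse-variance")) {
    weights <- match.arg(weights)
    stopifnot(is.data.frame(fu), all(c("L0", "fu") %in% names(fu)))
    .assertScalarNumeric(P0, "P0", positive = TRUE)
    bad <- list(Kd = NA_real_, KdStderr = NA_real_, KdRelError = NA_real_,
                Ku = NA_real_, KuStderr = NA_real_, converged = FALSE,
                flag = "")
    if (any(fu$fu < -1e-6 | fu$fu > 1 + 1e-6))
        stop("'fu' values must lie in [0, 1]")
    if (diff(range(fu$fu)) < 0.02) {
        bad$flag <- "no shift detected"
        return(bad)
    }
    fuApo <- if (any(fu$L0 == 0)) mean(fu$fu[fu$L0 == 0]) else min(fu$fu)
    fuApo <- min(max(fuApo, 1e-6), 1 - 1e-6)
    Ku0 <- min(max(fuApo / (1 - fuApo), 1e-4), 1e4)
    Kd0 <- exp(mean(log(fu$L0[fu$L0 > 0])))
    w <- rep(1, nrow(fu))
    if (weights == "inverse-variance" && !is.null(fu$fuErr)) {
        ok <- is.finite(fu$fuErr) & fu$fuErr > 0
        if (all(ok)) w <- 1 / fu$fuErr^2
    }
    lower <- c(-12, -6)
    upper <- c(0, 6)
    res <- .tryNls(y ~ .fuBindingModel(L0, log10Kd, log10Ku, P0),
                   data = list(L0 = fu$L0, y = fu$fu, P0 = P0),
                   start = list(log10Kd = log10(Kd0), log10Ku = log10(Ku0)),
                   lower = lower, upper = upper, weights = w)
    if (is.null(res$par)) {
        bad$flag <- res$message
        return(bad)
    }
    p <- res$par
    se <- res$se
    Kd <- 10^p[["log10Kd"]]
    Ku <- 10^p[["log10Ku"]]
    KdSe <- Kd * log(10) * se[["log10Kd"]]
    KuSe <- Ku * log(10) * se[["log10Ku"]]
    flag <- ""
    tol <- 1e-6
    if (any(abs(p - lower) < tol) || any(abs(p - upper) < tol))
        flag <- "estimate at parameter bound"
    else if (!res$converged) flag <- res$message
    list(Kd = unname(Kd), KdStderr = unname(KdSe),
         KdRelError = unname(100 * KdSe / Kd), Ku = unname(Ku),
         KuStderr = unname(KuSe),
         converged = res$converged && flag == "",
         flag = flag)
}

#' Isothermal Kd over a grid of analysis temperatures
#'
#' Runs [fuProfile()] and [fitBindingIsothermal()] at every temperature of
#' the grid and selects `Tsel`, the temperature with the smallest relative
#' Kd fitting error among converged fits. The Kd fitting error typically
#' passes through a minimum for temperatures around the melting temperature
#' of the apo protein, which motivates this selection rule.
#'
#' @param fit a global \linkS4class{MeltFit}.
#' @param study the \linkS4class{BindingStudy} the fit came from (supplies
#'   P0).
#' @param Tgrid temperatures to scan (degC), all inside the fit window.
#' @param weights passed to [fitBindingIsothermal()].
#' @return An \linkS4class{IsothermalResult}.
#' @examples
#' study <- simulateStudy(simulationSpec(KdTrue = 1e-5, noisePct = 0))
#' gf <- fitGlobal(study, fitLocal(study))
#' iso <- scanTemperatures(gf, study, seq(45, 55, by = 1))
#' selectedTemperature(iso)
#' @export
scanTemperatures <- function(fit, study, Tgrid, weights = "none") {
    stopifnot(is(fit, "MeltFit"))
    P0 <- if (is(study, "BindingStudy")) proteinConcentration(study)
          else as.numeric(study)
    if (any(Tgrid < fit@window[1] | Tgrid > fit@window[2]))
        stop("'Tgrid' must lie inside the analysis window")
    fuTabs <- list()
    rows <- vector("list", length(Tgrid))
    for (i in seq_along(Tgrid)) {
        tab <- fuProfile(fit, Tgrid[i])
        fuTabs[[sprintf("%.6g", Tgrid[i])]] <- tab
        r <- fitBindingIsothermal(tab, P0, weights = weights)
        rows[[i]] <- data.frame(T = Tgrid[i], Kd = r$Kd,
                                KdStderr = r$KdStderr,
                                KdRelError = r$KdRelError, Ku = r$Ku,
                                KuStderr = r$KuStderr,
                                converged = r$converged, flag = r$flag)
    }
    scan <- do.call(rbind, rows)
    ok <- which(scan$converged & is.finite(scan$KdRelError))
    if (!length(ok)) {
        diag <- paste(sprintf("T=%.1f: %s", scan$T,
                              ifelse(scan$flag == "", "not converged",
                                     scan$flag)),
                      collapse = "; ")
        stop("isothermal fit converged at no scanned temperature [", diag, "]")
    }
    Tsel <- scan$T[ok[which.min(scan$KdRelError[ok])]]
    new("IsothermalResult", scan = scan, Tsel = Tsel, fuTables = fuTabs,
        P0 = P0)
}

#' @describeIn scanTemperatures Selected temperature (degC) with minimal
#'   relative Kd fitting error.
#' @param x an \linkS4class{IsothermalResult}.
#' @export
selectedTemperature <- function(x) {
    stopifnot(is(x, "IsothermalResult"))
    x@Tsel
}

#' @describeIn scanTemperatures Kd (M) at the selected temperature.
#' @export
selectedKd <- function(x) {
    stopifnot(is(x, "IsothermalResult"))
    x@scan$Kd[x@scan$T == x@Tsel]
}

#' @describeIn scanTemperatures Full per-temperature scan table.
#' @export
scanTable <- function(x) {
    stopifnot(is(x, "IsothermalResult"))
    x@scan
}

setMethod("show", "IsothermalResult", function(object) {
    sc <- object@scan
    cat(sprintf("IsothermalResult over %d temperatures (%.1f-%.1f degC)\n",
                nrow(sc), min(sc$T), max(sc$T)))
    i <- which(sc$T == object@Tsel)
    cat(sprintf("  Tsel = %.1f degC: Kd = %.3g M +/- %.1f%%, Ku = %.3g\n",
                object@Tsel, sc$Kd[i], sc$KdRelError[i], sc$Ku[i]))
})
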