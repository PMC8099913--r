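## End-to-end analysis pipeline: read -> local fit -> global fit -> fraction
## unfolded -> isothermal temperature scan -> Tm-shift models -> results
## bundle with provenance.

#' Run the full isothermal analysis pipeline
#'
#' Executes the complete analysis chain on a binding study: per-curve local
#' fits, global fit (with the heat-capacity change fixed or fitted),
#' fraction-unfolded profiles, the isothermal temperature scan with
#' minimal-error temperature selection, and both Tm-shift models for
#' comparison. Output files (fit tables, scan CSV, JSON summary) are written
#' when `outDir` is given. A stage failure yields a partial bundle whose
#' provenance records `status` and the diagnostic instead of aborting.
#'
#' @param config named list or path to a JSON file with fields:
#'   `curves`, `sheet` (input paths; alternatively pass a ready `study`),
#'   optional `window` (`[Tmin, Tmax]` degC), `dcp` (a number, or the string
#'   `"fit"` to fit it globally), `TisoGrid` (temperatures to scan, degC;
#'   default apo-Tm +/- 10 degC in 1 degC steps clipped to the window),
#'   `weights` for the binding fit, `out` (output directory).
#' @param study optional \linkS4class{BindingStudy}, bypassing file input.
#' @return A \linkS4class{ResultsBundle}. Check
#'   `provenance(bundle)$status`: `"ok"` or the failed stage.
#' @examples
#' study <- simulateStudy(simulationSpec(KdTrue = 1e-5, noisePct = 0))
#' bundle <- runPipeline(list(dcp = 0), study = study)
#' provenance(bundle)$status
#' @export
runPipeline <- function(config = list(), study = NULL) {
    if (is.character(config)) config <- jsonlite::fromJSON(config)
    prov <- list(package = "DSFbinding",
                 version = as.character(utils::packageVersion("DSFbinding")),
                 config = config, status = "ok", message = "",
                 inputHashes = list())
    if (is.null(study)) {
        if (is.null(config$curves) || is.null(config$sheet))
            stop("config must name 'curves' and 'sheet' files (or pass a study)")
        prov$inputHashes <- list(
            curves = unname(tools::md5sum(config$curves)),
            sheet = unname(tools::md5sum(config$sheet)))
        study <- readCurves(config$curves, config$sheet)
    }
    if (!is.null(config$window)) analysisWindow(study) <- as.numeric(config$window)
    fitDCp <- identical(config$dcp, "fit")
    dCpFixed <- if (!fitDCp && !is.null(config$dcp)) as.numeric(config$dcp) else 0
    emptyMelt <- new("MeltFit", curveParams = data.frame(), shared = list(),
                     type = "local", dCp = 0, window = c(0, 1), P0 = 1,
                     converged = FALSE, rss = NA_real_)
    emptyIso <- new("IsothermalResult",
                    scan = data.frame(T = numeric(), Kd = numeric()),
                    Tsel = NA_real_, fuTables = list(), P0 = 1)
    bundle <- new("ResultsBundle", localFit = emptyMelt, globalFit = emptyMelt,
                  isothermal = emptyIso, tmModels = list(), provenance = prov)
    fail <- function(stage, e) {
        bundle@provenance$status <<- stage
        bundle@provenance$message <<- conditionMessage(e)
        NULL
    }
    lf <- tryCatch(fitLocal(study, dCp = dCpFixed),
                   error = function(e) fail("local-fit", e))
    if (!is.null(lf)) {
        bundle@localFit <- lf
        gf <- tryCatch(fitGlobal(study, lf, fitDCp = fitDCp,
                                 dCpFixed = dCpFixed),
                       error = function(e) fail("global-fit", e))
    } else gf <- NULL
    if (!is.null(gf)) {
        bundle@globalFit <- gf
        ## transition must sit inside the analysis window: Tm estimates
        ## pinned at a window edge mean the melting step was excluded
        w <- gf@window
        tol <- max(0.1, 0.005 * diff(w))
        atEdge <- gf@curveParams$Tm < w[1] + tol |
                  gf@curveParams$Tm > w[2] - tol
        if (mean(atEdge, na.rm = TRUE) > 0.5) {
            bundle@provenance$status <- "no-shift"
            bundle@provenance$message <-
                paste("no melting transition detected inside the analysis",
                      "window (Tm estimates pinned at the window edge)")
            if (!is.null(config$out)) writeResultsBundle(bundle, config$out)
            return(bundle)
        }
        Tg <- config$TisoGrid
        if (is.null(Tg)) {
            apoTm <- gf@curveParams$Tm[gf@curveParams$L0 == 0][1]
            if (!length(apoTm) || !is.finite(apoTm))
                apoTm <- stats::median(gf@curveParams$Tm, na.rm = TRUE)
            Tg <- seq(apoTm - 10, apoTm + 10, by = 1)
        }
        Tg <- Tg[Tg >= gf@window[1] & Tg <= gf@window[2]]
        iso <- tryCatch(
            scanTemperatures(gf, study, Tg,
                             weights = if (is.null(config$weights)) "none"
                                       else config$weights),
            error = function(e) fail("isothermal", e))
        if (!is.null(iso)) bundle@isothermal <- iso
        tms <- tryCatch(tmSeries(gf), error = function(e) fail("tm-series", e))
        if (!is.null(tms)) {
            apo <- gf@curveParams[gf@curveParams$L0 == 0, ][1, ]
            bundle@tmModels <- list(
                model1 = fitTmModel1(tms),
                model2 = fitTmModel2(tms, Tm0 = .CtoK(apo$Tm), dH0 = apo$dH))
        }
    }
    if (!is.null(config$out)) writeResultsBundle(bundle, config$out)
    bundle
}

#' Provenance block of a results bundle
#' @param bundle a \linkS4class{ResultsBundle}.
#' @return Named list (package version, config, input hashes, status).
#' @export
provenance <- function(bundle) {
    stopifnot(is(bundle, "ResultsBundle"))
    bundle@provenance
}

#' Write a results bundle to a directory
#'
#' Emits `local_fit.csv`, `global_fit.csv`, `isothermal_scan.csv` and
#' `summary.json` (selected temperature and Kd, Tm-shift model results,
#' provenance).
#'
#' @param bundle a \linkS4class{ResultsBundle}.
#' @param outDir output directory, created if needed.
#' @return Invisibly, `outDir`.
#' @export
writeResultsBundle <- function(bundle, outDir) {
    stopifnot(is(bundle, "ResultsBundle"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(bundle@localFit@curveParams))
        writeMeltFitCsv(bundle@localFit, file.path(outDir, "local_fit.csv"))
    if (nrow(bundle@globalFit@curveParams))
        writeMeltFitCsv(bundle@globalFit, file.path(outDir, "global_fit.csv"))
    sc <- bundle@isothermal@scan
    if (nrow(sc))
        utils::write.csv(sc, file.path(outDir, "isothermal_scan.csv"),
                         row.names = FALSE)
    summ <- list(status = bundle@provenance$status,
                 message = bundle@provenance$message)
    if (nrow(sc) && is.finite(bundle@isothermal@Tsel)) {
        i <- which(sc$T == bundle@isothermal@Tsel)
        summ$Tsel <- sc$T[i]
        summ$Kd <- sc$Kd[i]
        summ$KdRelErrorPct <- sc$KdRelError[i]
        summ$Ku <- sc$Ku[i]
    }
    if (length(bundle@tmModels)) {
        summ$tmModels <- lapply(bundle@tmModels, function(m)
            list(model = m@model, KdApp = m@Kd, KdAppStderr = m@KdStderr,
                 converged = m@converged, caveat = m@caveat))
    }
    sh <- bundle@globalFit@shared
    if (length(sh))
        summ$dCp <- list(value = sh$dCp, stderr = sh$dCp.se,
                         fitted = isTRUE(sh$dCpFitted))
    summ$provenance <- bundle@provenance[c("package", "version",
                                           "inputHashes")]
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(outDir)
}

setMethod("show", "ResultsBundle", function(object) {
    cat("ResultsBundle (status:", object@provenance$status, ")\n")
    if (is.finite(object@isothermal@Tsel)) {
        show(object@isothermal)
    }
    for (m in object@tmModels) show(m)
})
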