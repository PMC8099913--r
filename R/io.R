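## File I/O: the curve-table CSV contract and the JSON sample sheet.
##
## Curves CSV: one "Temperature" column (degC) plus one column per
## capillary. Sample sheet (JSON): study-level P0, signalType, window and a
## "columns" map from capillary column name to its ligand concentration
## (molar, SI suffixes such as "2mM"/"610nM" accepted). Vendor xlsx exports
## are out of scope; convert to this CSV contract first.

#' Read a binding study from a curves CSV and a sample sheet
#'
#' @param curvesPath CSV with a `Temperature` column (degC) and one signal
#'   column per capillary.
#' @param sheetPath JSON sample sheet: fields `P0` (molar, SI suffix
#'   allowed), `signalType`, optional `window` (`[Tmin, Tmax]` degC) and
#'   `columns` (capillary name -> L0). Every data column must be mapped;
#'   unmapped or missing columns are hard errors naming the offenders.
#' @return A \linkS4class{BindingStudy}. Rows with non-finite values are
#'   dropped with a message; non-monotone or duplicated temperatures are
#'   hard errors.
#' @seealso [writeStudy()] for the inverse.
#' @export
readCurves <- function(curvesPath, sheetPath) {
    tab <- utils::read.csv(curvesPath, check.names = FALSE)
    if (!"Temperature" %in% names(tab))
        stop("curves file must contain a 'Temperature' column")
    sheet <- jsonlite::fromJSON(sheetPath)
    if (is.null(sheet$columns) || !length(sheet$columns))
        stop("sample sheet must map data columns to ligand concentrations")
    cols <- names(sheet$columns)
    dataCols <- setdiff(names(tab), "Temperature")
    missing <- setdiff(cols, dataCols)
    if (length(missing))
        stop("sample sheet references missing column(s): ",
             paste(missing, collapse = ", "))
    unmapped <- setdiff(dataCols, cols)
    if (length(unmapped))
        stop("unmapped data column(s): ", paste(unmapped, collapse = ", "))
    Tc <- tab$Temperature
    if (anyDuplicated(Tc[is.finite(Tc)]))
        stop("duplicate temperatures in curves file")
    if (is.unsorted(Tc[is.finite(Tc)], strictly = TRUE))
        stop("temperature column must be strictly increasing")
    L0 <- parseConcentration(unlist(sheet$columns))
    sig <- as.matrix(tab[, cols, drop = FALSE])
    window <- if (!is.null(sheet$window)) as.numeric(sheet$window)
              else range(Tc, na.rm = TRUE)
    bindingStudy(Tc, sig, L0, P0 = parseConcentration(sheet$P0),
                 signalType = if (is.null(sheet$signalType)) "Ratio"
                              else sheet$signalType,
                 window = window, labels = cols)
}

#' Write a binding study as a curves CSV plus sample sheet
#'
#' Inverse of [readCurves()]: produces a CSV/JSON pair that reads back into
#' an identical study.
#'
#' @param study a \linkS4class{BindingStudy}.
#' @param curvesPath,sheetPath output paths.
#' @return Invisibly, `c(curvesPath, sheetPath)`.
#' @export
writeStudy <- function(study, curvesPath, sheetPath) {
    stopifnot(is(study, "BindingStudy"))
    tab <- data.frame(Temperature = temperatures(study), check.names = FALSE)
    tab <- cbind(tab, as.data.frame(assay(study), check.names = FALSE))
    utils::write.csv(tab, curvesPath, row.names = FALSE)
    cols <- as.list(ligandConcentrations(study))
    names(cols) <- colData(study)$label
    sheet <- list(P0 = proteinConcentration(study),
                  signalType = signalType(study),
                  window = analysisWindow(study), columns = cols)
    jsonlite::write_json(sheet, sheetPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(curvesPath, sheetPath))
}

#' Write a melt-fit table as CSV
#'
#' One row per curve (`L0`, `Tm`, `dH`, `bf`, `bu` with standard errors)
#' followed by one `shared` footer row carrying the global parameters
#' (`mf`, `mu`, `dCp` with errors).
#'
#' @param fit a \linkS4class{MeltFit}.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeMeltFitCsv <- function(fit, path) {
    stopifnot(is(fit, "MeltFit"))
    cp <- fit@curveParams
    keep <- intersect(c("label", "L0", "Tm", "TmSe", "dH", "dHSe", "bf",
                        "bfSe", "bu", "buSe", "converged"), names(cp))
    out <- cp[, keep]
    sh <- fit@shared
    footer <- out[1, ]
    footer[1, ] <- NA
    footer$label <- "shared"
    footer$converged <- fit@converged
    out <- rbind(out, footer)
    out$mf <- c(rep(NA_real_, nrow(cp)), sh$mf)
    out$mfSe <- c(rep(NA_real_, nrow(cp)), sh$mf.se)
    out$mu <- c(rep(NA_real_, nrow(cp)), sh$mu)
    out$muSe <- c(rep(NA_real_, nrow(cp)), sh$mu.se)
    out$dCp <- c(rep(NA_real_, nrow(cp)), sh$dCp)
    out$dCpSe <- c(rep(NA_real_, nrow(cp)), sh$dCp.se)
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}
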