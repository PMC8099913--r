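#' Construct a BindingStudy
#'
#' Assembles melting curves measured on a common temperature grid into a
#' \linkS4class{BindingStudy}. Rows with non-finite values in any curve are
#' dropped with a message.
#'
#' @param temperature numeric vector of temperatures (degC, strictly
#'   increasing).
#' @param signal numeric matrix of fluorescence values, one column per
#'   capillary, `length(temperature)` rows.
#' @param L0 numeric vector of ligand concentrations (M), one per column;
#'   the apo sample has `L0 = 0`.
#' @param P0 protein concentration (M), shared by all curves.
#' @param signalType `"Ratio"` (default), `"F330"` or `"F350"`.
#' @param window analysis window `c(Tmin, Tmax)` in degC; defaults to the
#'   full temperature range.
#' @param labels optional curve labels; default from column names or L0.
#' @return A \linkS4class{BindingStudy}.
#' @examples
#' spec <- simulationSpec(KdTrue = 1e-6, P0 = 1e-7)
#' study <- simulateStudy(spec)
#' ligandConcentrations(study)
#' @export
bindingStudy <- function(temperature, signal, L0, P0, signalType = "Ratio",
                         window = range(temperature), labels = NULL) {
    signal <- as.matrix(signal)
    if (length(temperature) != nrow(signal))
        stop("'temperature' and 'signal' rows differ in length")
    if (length(L0) != ncol(signal))
        stop("need one 'L0' per signal column")
    keep <- is.finite(temperature) & apply(is.finite(signal), 1L, all)
    if (!all(keep)) {
        message(sum(!keep), " row(s) with non-finite values dropped")
        temperature <- temperature[keep]
        signal <- signal[keep, , drop = FALSE]
    }
    if (anyDuplicated(temperature))
        stop("duplicate temperatures in the grid")
    if (is.null(labels)) {
        labels <- colnames(signal)
        if (is.null(labels)) labels <- sprintf("curve%02d", seq_along(L0))
    }
    colnames(signal) <- labels
    se <- SummarizedExperiment(
        assays = S4Vectors::SimpleList(signal = signal),
        rowData = S4Vectors::DataFrame(Temperature = temperature),
        colData = S4Vectors::DataFrame(L0 = as.numeric(L0), label = labels,
                                       row.names = labels))
    md <- list(P0 = P0, signalType = signalType, window = as.numeric(window))
    metadata(se) <- md
    new("BindingStudy", se)
}

#' @describeIn bindingStudy Temperature grid (degC).
#' @param x,object a `BindingStudy`.
#' @export
temperatures <- function(x) rowData(x)$Temperature

#' @describeIn bindingStudy Ligand concentrations (M), one per curve.
#' @export
ligandConcentrations <- function(x) colData(x)$L0

#' @describeIn bindingStudy Protein concentration (M).
#' @export
proteinConcentration <- function(x) metadata(x)$P0

#' @describeIn bindingStudy Signal type (`"Ratio"`, `"F330"` or `"F350"`).
#' @export
signalType <- function(x) metadata(x)$signalType

#' @describeIn bindingStudy Analysis window `c(Tmin, Tmax)` in degC.
#' @export
analysisWindow <- function(x) metadata(x)$window

#' Replace the analysis window of a study
#'
#' @param x a \linkS4class{BindingStudy}.
#' @param value numeric `c(Tmin, Tmax)` in degC.
#' @return The modified study.
#' @export
`analysisWindow<-` <- function(x, value) {
    metadata(x)$window <- as.numeric(value)
    validObject(x)
    x
}

setMethod("show", "BindingStudy", function(object) {
    Tc <- temperatures(object)
    cat("BindingStudy with", ncol(object), "curves (",
        sum(ligandConcentrations(object) == 0), "apo )\n")
    cat(sprintf("  signal: %s, %d points %.1f-%.1f degC\n",
                signalType(object), length(Tc), min(Tc), max(Tc)))
    cat(sprintf("  P0 = %.3g M, [L]0 range %.3g-%.3g M\n",
                proteinConcentration(object),
                min(ligandConcentrations(object)),
                max(ligandConcentrations(object))))
    w <- analysisWindow(object)
    if (!is.null(w))
        cat(sprintf("  analysis window: %.1f-%.1f degC\n", w[1], w[2]))
})

#' Plot the melting curves of a study
#'
#' Simple overview plot: signal versus temperature, curves coloured from low
#' (blue) to high (red) ligand concentration; the analysis window is shaded.
#'
#' @param x a \linkS4class{BindingStudy}.
#' @param y ignored.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @importFrom graphics matplot rect legend
#' @importFrom grDevices adjustcolor colorRampPalette
#' @export
setMethod("plot", signature(x = "BindingStudy", y = "missing"),
    function(x, y, ...) {
    L0 <- ligandConcentrations(x)
    cols <- colorRampPalette(c("black", "blue", "red"))(length(L0))
    cols <- cols[rank(L0, ties.method = "first")]
    matplot(temperatures(x), assay(x), type = "l", lty = 1, col = cols,
            xlab = "Temperature (degC)",
            ylab = paste0("Signal (", signalType(x), ")"), ...)
    w <- analysisWindow(x)
    if (!is.null(w)) {
        usr <- graphics::par("usr")
        rect(w[1], usr[3], w[2], usr[4],
             col = adjustcolor("grey", 0.2), border = NA)
    }
    invisible(x)
})

#' Construct a SimulationSpec
#'
#' Ground truth for one virtual binding study; see
#' \linkS4class{SimulationSpec} for the meaning and defaults of each
#' parameter.
#'
#' @param KdTrue true Kd (M).
#' @param P0 protein concentration (M).
#' @param dCpTrue true heat-capacity change (kcal/(mol K)).
#' @param noisePct Gaussian noise sigma as a fraction of the study dynamic
#'   range, in \[0, 0.10\].
#' @param TmApo,dHApo apo melting temperature (degC) / enthalpy (kcal/mol).
#' @param mf,bf,mu,bu baseline parameters (Celsius-scale convention).
#' @param L0 ligand series (M), must include 0.
#' @param Tgrid temperature grid (degC).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(KdTrue = 1e-6, P0 = 1e-7, dCpTrue = 0,
                           noisePct = 0.02, TmApo = 50, dHApo = 120,
                           mf = -0.002, bf = 1.5, mu = 0.001, bu = 1.1,
                           L0 = c(2e-3 / 2^(0:13), 0),
                           Tgrid = seq(20, 95, by = 0.5), seed = 1L) {
    new("SimulationSpec", KdTrue = KdTrue, P0 = P0, dCpTrue = dCpTrue,
        noisePct = noisePct, TmApo = TmApo, dHApo = dHApo, mf = mf, bf = bf,
        mu = mu, bu = bu, L0 = L0, Tgrid = Tgrid, seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:\n")
    cat(sprintf("  Kd = %.3g M, P0 = %.3g M, dCp = %g kcal/(mol K), noise = %g%%\n",
                object@KdTrue, object@P0, object@dCpTrue,
                100 * object@noisePct))
    cat(sprintf("  apo Tm = %g degC, dH = %g kcal/mol, %d ligand conc., %d T points, seed %d\n",
                object@TmApo, object@dHApo, length(object@L0),
                length(object@Tgrid), object@seed))
})
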