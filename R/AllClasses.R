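#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' BindingStudy: a dilution series of melting curves
#'
#' Container for one nDSF binding study: fluorescence melting curves recorded
#' on a common temperature grid for a two-fold (or arbitrary) dilution series
#' of ligand at constant protein concentration. Extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are temperature points
#' (`rowData()$Temperature`, degC, strictly increasing), columns are
#' capillaries with `colData()$L0` (molar ligand concentration) and
#' `colData()$label`. Study-level metadata holds the protein concentration
#' `P0` (M), the `signalType` (`"Ratio"`, `"F330"` or `"F350"`) and the
#' analysis `window` (degC).
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}.
#' @seealso [bindingStudy()], [simulateStudy()], [readCurves()]
#' @aliases BindingStudy
#' @export
setClass("BindingStudy", contains = "SummarizedExperiment")

setValidity("BindingStudy", function(object) {
    msg <- character()
    Tc <- rowData(object)$Temperature
    if (is.null(Tc)) msg <- c(msg, "rowData must contain a 'Temperature' column (degC)")
    else {
        if (length(Tc) < 20L) msg <- c(msg, "need at least 20 temperature points")
        if (any(!is.finite(Tc)) || is.unsorted(Tc, strictly = TRUE))
            msg <- c(msg, "'Temperature' must be finite and strictly increasing")
    }
    cd <- colData(object)
    if (is.null(cd$L0)) msg <- c(msg, "colData must contain 'L0' (molar)")
    else if (any(!is.finite(cd$L0)) || any(cd$L0 < 0))
        msg <- c(msg, "'L0' must be finite and non-negative")
    md <- metadata(object)
    if (is.null(md$P0) || !is.finite(md$P0) || md$P0 <= 0)
        msg <- c(msg, "metadata 'P0' must be a positive molar concentration")
    if (is.null(md$signalType) ||
        !md$signalType %in% c("Ratio", "F330", "F350"))
        msg <- c(msg, "metadata 'signalType' must be one of Ratio/F330/F350")
    if (!is.null(md$window) &&
        (length(md$window) != 2L || any(!is.finite(md$window)) ||
         diff(md$window) <= 0))
        msg <- c(msg, "'window' must be (Tmin, Tmax) with Tmin < Tmax")
    a <- assay(object)
    if (!is.null(a) && any(!is.finite(a)))
        msg <- c(msg, "signal matrix must be finite after cleaning")
    if (length(msg)) msg else TRUE
})

#' SimulationSpec: ground truth for one virtual binding study
#'
#' Ground-truth parameters for the virtual-binding-study generator. Defaults
#' describe a realistic ratio-type nDSF study: apo melting temperature 50
#' degC, unfolding enthalpy 120 kcal/mol, 14 two-fold ligand dilutions from
#' 2 mM plus an apo sample, a 20--95 degC ramp sampled every 0.5 degC, and
#' additive Gaussian noise expressed as a fraction of the whole-study dynamic
#' range (default 2\%, the level typical of experimental spectra).
#'
#' @slot KdTrue true dissociation constant (M).
#' @slot P0 protein concentration (M).
#' @slot dCpTrue true heat-capacity change upon unfolding (kcal/(mol K)).
#' @slot noisePct noise sigma as a fraction of the study dynamic range, in
#'   \[0, 0.10\].
#' @slot TmApo,dHApo apo melting temperature (degC) and enthalpy (kcal/mol).
#' @slot mf,bf,mu,bu folded/unfolded baseline slopes and intercepts
#'   (Celsius-scale convention).
#' @slot L0 ligand dilution series (M), must include 0.
#' @slot Tgrid temperature grid (degC), spanning at least TmApo +/- 15.
#' @slot seed integer RNG seed.
#' @seealso [simulationSpec()], [simulateStudy()]
#' @export
setClass("SimulationSpec",
    representation(KdTrue = "numeric", P0 = "numeric", dCpTrue = "numeric",
                   noisePct = "numeric", TmApo = "numeric", dHApo = "numeric",
                   mf = "numeric", bf = "numeric", mu = "numeric",
                   bu = "numeric", L0 = "numeric", Tgrid = "numeric",
                   seed = "integer"),
    prototype(KdTrue = 1e-6, P0 = 1e-7, dCpTrue = 0, noisePct = 0.02,
              TmApo = 50, dHApo = 120, mf = -0.002, bf = 1.5, mu = 0.001,
              bu = 1.1, L0 = c(2e-3 / 2^(0:13), 0),
              Tgrid = seq(20, 95, by = 0.5), seed = 1L))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@KdTrue <= 0) msg <- c(msg, "KdTrue must be > 0")
    if (object@P0 <= 0) msg <- c(msg, "P0 must be > 0")
    if (object@noisePct < 0 || object@noisePct > 0.10)
        msg <- c(msg, "noisePct must lie in [0, 0.10]")
    if (object@dHApo <= 0) msg <- c(msg, "dHApo must be > 0")
    if (!any(object@L0 == 0)) msg <- c(msg, "L0 series must include 0 (apo)")
    if (any(object@L0 < 0)) msg <- c(msg, "L0 must be non-negative")
    Tg <- object@Tgrid
    if (is.unsorted(Tg, strictly = TRUE)) msg <- c(msg, "Tgrid must be strictly increasing")
    if (min(Tg) > object@TmApo - 15 || max(Tg) < object@TmApo + 15)
        msg <- c(msg, "Tgrid must span TmApo +/- 15 degC")
    if (length(msg)) msg else TRUE
})

#' MeltFit: local or global melting-curve fit result
#'
#' Result of fitting the two-state signal model to the curves of a
#' [BindingStudy]. `curveParams` holds one row per curve (label, L0, Tm, dH,
#' bf, bu and, for local fits, mf/mu, each with a standard error, plus a
#' convergence flag and residual norm). `shared` holds the study-global
#' parameters of a global fit (mf, mu and optionally dCp) with their errors.
#'
#' @slot curveParams data.frame of per-curve estimates and standard errors.
#' @slot shared named list of shared-parameter estimates (`mf`, `mu`, `dCp`,
#'   `mf.se`, `mu.se`, `dCp.se`, `dCpFitted` flag).
#' @slot type `"local"` or `"global"`.
#' @slot dCp the heat-capacity change used (fixed) or fitted (kcal/(mol K)).
#' @slot window analysis window (degC).
#' @slot P0 protein concentration (M).
#' @slot converged overall convergence flag.
#' @slot rss total residual sum of squares.
#' @seealso [fitLocal()], [fitGlobal()], [fuProfile()]
#' @export
setClass("MeltFit",
    representation(curveParams = "data.frame", shared = "list",
                   type = "character", dCp = "numeric", window = "numeric",
                   P0 = "numeric", converged = "logical", rss = "numeric"))

#' IsothermalResult: Kd as a function of analysis temperature
#'
#' Result of scanning isothermal binding fits over a temperature grid.
#' `scan` has one row per temperature (`T`, `Kd`, `KdStderr`, `KdRelError`
#' in percent, `Ku`, `KuStderr`, `converged`, `flag`); `Tsel` is the scanned
#' temperature with the smallest relative Kd fitting error; `fuTables` keeps
#' the fraction-unfolded dose-response table per temperature.
#'
#' @slot scan data.frame of per-temperature fit results.
#' @slot Tsel selected temperature (degC).
#' @slot fuTables named list of data.frames (L0, fu, fuErr).
#' @slot P0 protein concentration (M).
#' @seealso [scanTemperatures()], [fitBindingIsothermal()]
#' @export
setClass("IsothermalResult",
    representation(scan = "data.frame", Tsel = "numeric",
                   fuTables = "list", P0 = "numeric"))

setValidity("IsothermalResult", function(object) {
    if (length(object@Tsel) == 1L && is.finite(object@Tsel) &&
        !object@Tsel %in% object@scan$T)
        return("Tsel must be a member of the scanned temperatures")
    TRUE
})

#' ApparentKdResult: Tm-shift model fit
#'
#' Apparent dissociation constant obtained by fitting melting temperatures
#' versus ligand concentration, either with the empirical single-site
#' interpolation (model 1) or the thermodynamic Tm-shift expression
#' (model 2). Model 1 has no physico-chemical foundation and its results
#' carry a caveat; it is provided for comparison only.
#'
#' @slot model integer, 1 or 2.
#' @slot Kd apparent Kd (M) and @slot KdStderr its standard error (M).
#' @slot params named numeric of model-specific parameters (model 1:
#'   TmUnbound, TmUpper (K); model 2: Tm0 (K), dHTm0 (kcal/mol)) and errors.
#' @slot residuals fit residuals (K).
#' @slot converged convergence flag.
#' @slot caveat character; non-empty for model 1.
#' @seealso [fitTmModel1()], [fitTmModel2()]
#' @export
setClass("ApparentKdResult",
    representation(model = "integer", Kd = "numeric", KdStderr = "numeric",
                   params = "numeric", residuals = "numeric",
                   converged = "logical", caveat = "character"))

#' ResultsBundle: full pipeline output
#'
#' Everything produced by one [runPipeline()] invocation: the local and
#' global fit tables, the isothermal temperature scan, both Tm-shift model
#' fits, and a provenance block (input hashes, configuration, seed, package
#' version).
#'
#' @slot localFit,globalFit [MeltFit] objects.
#' @slot isothermal [IsothermalResult].
#' @slot tmModels list of [ApparentKdResult] (models 1 and 2).
#' @slot provenance named list.
#' @export
setClass("ResultsBundle",
    representation(localFit = "MeltFit", globalFit = "MeltFit",
                   isothermal = "IsothermalResult", tmModels = "list",
                   provenance = "list"))
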