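## Shared fixtures and independent forward models used as oracles.

## Faster simulation grid for tests: 25-75 degC at 0.5 degC (101 points),
## still spanning the default apo Tm (50 degC) by +/- 15 degC.
fastSpec <- function(...) {
    simulationSpec(Tgrid = seq(25, 75, by = 0.5), ...)
}

## Analyse one study end to end; returns list(gf, iso).
runStudy <- function(study, fitDCp = FALSE, dCpFixed = 0,
                     Tgrid = seq(42, 58, by = 1)) {
    gf <- suppressWarnings(
        fitGlobal(study, fitLocal(study, dCp = dCpFixed),
                  fitDCp = fitDCp, dCpFixed = dCpFixed))
    iso <- scanTemperatures(gf, study, Tgrid)
    list(gf = gf, iso = iso)
}

## Forward Tm-shift models, written independently of the package internals
## (plain transcriptions used as round-trip oracles).
model1Forward <- function(L0, P0, Kd, TmUnbound, TmUpper) {
    a <- (P0 - Kd - L0 + sqrt((P0 + L0 + Kd)^2 - 4 * P0 * L0)) / (2 * P0)
    TmUnbound + (TmUpper - TmUnbound) * (1 - a)
}

model2Forward <- function(L0, Tm0, dH0, Kd) {
    R <- 1.987204e-3
    Tm0 / (1 - (R * Tm0 / dH0) * log(1 + L0 / Kd))
}

## Memoized reduced benchmark grid (3x3 Kd x P0, true dCp = 8, 2% noise,
## 5 reps, both analysis modes) shared by the acceptance checks.
.fixtureCache <- new.env(parent = emptyenv())
benchRecords <- function() {
    if (is.null(.fixtureCache$rec))
        .fixtureCache$rec <- suppressWarnings(
            runBenchmark(Kd = c(1e-7, 1e-6, 1e-5),
                         P0 = c(1e-7, 1e-6, 1e-5),
                         dCp = 8, noise = 0.02, fitDCp = c(FALSE, TRUE),
                         reps = 5, seed = 2024, spec = fastSpec()))
    .fixtureCache$rec
}

## Ground-truth fraction unfolded of the simulator's world at a temperature.
simTruthFu <- function(spec, TisoC) {
    R <- 1.987204e-3
    TK <- TisoC + 273.15
    dGapo <- dGUnfolding(TK, spec@TmApo + 273.15, spec@dHApo, spec@dCpTrue)
    KuT <- apparentKu(dGapo, TK)
    vapply(spec@L0, function(l0) {
        Lf <- freeLigand(l0, spec@P0, KuT, spec@KdTrue)
        fractionUnfolded(apparentKu(dGapo + R * TK * log(1 + Lf / spec@KdTrue),
                                    TK))
    }, numeric(1))
}
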