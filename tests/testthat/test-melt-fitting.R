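## Local and global melting-curve fitting.

test_that("local fit recovers all six parameters from a noiseless curve", {
    ## a 1 M Kd study is exactly two-state for every curve
    spec <- fastSpec(KdTrue = 1, noisePct = 0)
    st <- simulateStudy(spec)
    lf <- fitLocal(st)
    cp <- curveParams(lf)
    expect_true(all(cp$converged))
    expect_equal(cp$Tm, rep(50, nrow(cp)), tolerance = 1e-5)
    expect_equal(cp$dH, rep(120, nrow(cp)), tolerance = 1e-3)
    expect_equal(cp$mf, rep(-0.002, nrow(cp)), tolerance = 1e-3)
    expect_equal(cp$mu, rep(0.001, nrow(cp)), tolerance = 1e-3)
    expect_equal(cp$bf, rep(1.5, nrow(cp)), tolerance = 1e-3)
    expect_equal(cp$bu, rep(1.1, nrow(cp)), tolerance = 1e-3)
})

test_that("a transitionless curve is flagged, not fitted", {
    Tc <- seq(25, 75, by = 0.5)
    Y <- matrix(rep(1.2, 2 * length(Tc)), ncol = 2)
    st <- bindingStudy(Tc, Y, L0 = c(0, 1e-6), P0 = 1e-6)
    lf <- fitLocal(st)
    expect_false(any(curveParams(lf)$converged))
    expect_match(curveParams(lf)$message[1], "no transition")
})

test_that("local Tm survives 2% dynamic-range noise within 0.3 degC", {
    for (seed in c(1L, 2L, 3L)) {
        st <- simulateStudy(fastSpec(KdTrue = 1, noisePct = 0.02,
                                     seed = seed))
        cp <- curveParams(fitLocal(st))
        expect_lt(max(abs(cp$Tm - 50)), 0.3)
    }
})

test_that("noiseless global fit reproduces shared slopes and Tm", {
    spec <- fastSpec(KdTrue = 1, noisePct = 0)
    st <- simulateStudy(spec)
    gf <- fitGlobal(st, fitLocal(st))
    expect_true(gf@converged)
    sh <- sharedParams(gf)
    expect_equal(sh$mf, -0.002, tolerance = 1e-6)
    expect_equal(sh$mu, 0.001, tolerance = 1e-6)
    expect_equal(curveParams(gf)$Tm, rep(50, ncol(st)), tolerance = 1e-4)
    ## per-curve estimates do not depend on which other curves are present
    sub <- st[, 1:5]
    gfSub <- fitGlobal(sub, fitLocal(sub))
    expect_equal(curveParams(gfSub)$Tm, curveParams(gf)$Tm[1:5],
                 tolerance = 1e-6)
    expect_equal(curveParams(gfSub)$dH, curveParams(gf)$dH[1:5],
                 tolerance = 1e-4)
})

test_that("global dCp fitting recovers the true value and nests the fixed fit", {
    spec <- fastSpec(KdTrue = 1e-6, P0 = 1e-7, dCpTrue = 8,
                     noisePct = 0.02, seed = 17L)
    st <- simulateStudy(spec)
    lf <- fitLocal(st)
    gfOn <- suppressWarnings(fitGlobal(st, lf, fitDCp = TRUE))
    expect_equal(sharedParams(gfOn)$dCp, 8, tolerance = 1.5 / 8)
    expect_true(is.finite(sharedParams(gfOn)$dCp.se))
    ## releasing dCp can only improve the residual norm (nested models)
    gfOff <- suppressWarnings(fitGlobal(st, lf, fitDCp = FALSE,
                                        dCpFixed = 0))
    expect_lte(gfOn@rss, gfOff@rss)
})

test_that("fuProfile matches definition, truth and monotonicity", {
    spec <- fastSpec(KdTrue = 1e-6, P0 = 1e-7, noisePct = 0)
    st <- simulateStudy(spec)
    gf <- fitGlobal(st, fitLocal(st))
    cp <- curveParams(gf)
    ## fu = 0.5 exactly at each curve's own Tm
    for (i in c(1L, nrow(cp))) {
        expect_equal(fuProfile(gf, cp$Tm[i])$fu[i], 0.5, tolerance = 1e-9)
    }
    ## far below all Tm everything is folded
    expect_lt(max(fuProfile(gf, 30)$fu), 0.01)
    ## noiseless profile tracks the generator's ground truth
    expect_lt(max(abs(fuProfile(gf, 50)$fu - simTruthFu(spec, 50))), 1e-3)
    ## monotone in the analysis temperature, per curve
    fuT <- sapply(c(44, 47, 50, 53, 56), function(T) fuProfile(gf, T)$fu)
    expect_true(all(apply(fuT, 1, function(z) all(diff(z) > 0))))
    expect_error(fuProfile(gf, 99), "window")
})
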