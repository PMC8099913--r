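## Apparent-Kd models fitted to melting temperatures.

test_that("model 1 round-trips a series generated from its own equations", {
    P0 <- 2e-6; Kd <- 1e-5
    L0 <- c(0, 2e-3 / 2^(0:12))
    series <- data.frame(L0 = L0,
                         Tm = model1Forward(L0, P0, Kd, 320, 330),
                         TmSe = 0.01)
    attr(series, "P0") <- P0
    r <- fitTmModel1(series)
    expect_true(r@converged)
    expect_equal(r@Kd, Kd, tolerance = 1e-3)
    expect_equal(unname(r@params["TmUnbound"]), 320, tolerance = 1e-5)
    expect_equal(unname(r@params["TmUpper"]), 330, tolerance = 1e-4)
    expect_match(r@caveat, "no physico-chemical foundation")
    ## limits of the forward model itself
    expect_equal(model1Forward(0, P0, Kd, 320, 330), 320)
    expect_gt(model1Forward(1, P0, Kd, 320, 330), 329.99)
    ## order invariance
    sh <- series[sample(nrow(series)), ]
    attr(sh, "P0") <- P0
    expect_equal(fitTmModel1(sh)@Kd, r@Kd, tolerance = 1e-9)
})

test_that("model 2 round-trips and is monotone in ligand", {
    Tm0 <- 323.15; dH0 <- 120; Kd <- 1e-5
    L0 <- c(0, 2e-3 / 2^(0:12))
    series <- data.frame(L0 = L0, Tm = model2Forward(L0, Tm0, dH0, Kd),
                         TmSe = 0.01)
    expect_true(all(diff(series$Tm[order(series$L0)]) >= 0))
    r <- fitTmModel2(series, Tm0 = Tm0, dH0 = dH0)
    expect_true(r@converged)
    expect_equal(r@Kd, Kd, tolerance = 5e-3)
    ## apo point is left unshifted
    expect_equal(model2Forward(0, Tm0, dH0, Kd), Tm0)
    ## co-fitting all three parameters also recovers Kd on clean data
    rCo <- fitTmModel2(series, Tm0 = Tm0 + 0.5, dH0 = 100, coFit = TRUE)
    expect_equal(rCo@Kd, Kd, tolerance = 0.05)
    ## order invariance
    expect_equal(fitTmModel2(series[sample(nrow(series)), ],
                             Tm0 = Tm0, dH0 = dH0)@Kd, r@Kd,
                 tolerance = 1e-9)
})

test_that("model 2 agrees with truth for a weak binder in the simulator world", {
    ## Kd = 1e-5 >> P0 = 1e-7, temperature-independent Kd: the [L] = [L]0
    ## approximation is benign and model 2 lands within a factor 3
    st <- simulateStudy(fastSpec(KdTrue = 1e-5, P0 = 1e-7, noisePct = 0))
    gf <- fitGlobal(st, fitLocal(st))
    tms <- tmSeries(gf)
    apo <- curveParams(gf)[curveParams(gf)$L0 == 0, ][1, ]
    r <- fitTmModel2(tms, Tm0 = apo$Tm + 273.15, dH0 = apo$dH)
    expect_true(r@converged)
    expect_lt(abs(log10(r@Kd / 1e-5)), log10(3))
})

test_that("tmSeries extracts Kelvin melting temperatures with an apo anchor", {
    st <- simulateStudy(fastSpec(KdTrue = 1e-5, P0 = 1e-6, noisePct = 0))
    gf <- fitGlobal(st, fitLocal(st))
    tms <- tmSeries(gf)
    expect_true(all(tms$Tm > 250))
    expect_equal(sum(tms$L0 == 0), 1L)
    expect_equal(attr(tms, "P0"), 1e-6)
})
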