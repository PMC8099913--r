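## Isothermal Kd extraction from fraction-unfolded dose response.

test_that("binding fit round-trips its own model exactly", {
    P0 <- 5e-6; Kd <- 1e-5; Ku <- 1
    L0 <- c(0, 1e-5 * 2^(-6:7))
    fu <- vapply(L0, function(l0) {
        Lf <- freeLigand(l0, P0, Ku, Kd)
        Ku / (Ku + 1 + Lf / Kd)
    }, numeric(1))
    r <- fitBindingIsothermal(data.frame(L0 = L0, fu = fu), P0)
    expect_true(r$converged)
    expect_equal(r$Kd, Kd, tolerance = 1e-3)
    expect_equal(r$Ku, Ku, tolerance = 1e-3)
    expect_lt(r$KdRelError, 1)
})

test_that("the apo point pins Ku via fu(0) = Ku/(Ku+1)", {
    P0 <- 1e-6; Kd <- 1e-6
    L0 <- c(0, 10^seq(-7.5, -3.5, length.out = 10))
    fu <- vapply(L0, function(l0) {
        Lf <- freeLigand(l0, P0, 1, Kd)   # Ku = 1 <=> fu(0) = 0.5
        1 / (2 + Lf / Kd)
    }, numeric(1))
    expect_equal(fu[1], 0.5)
    r <- fitBindingIsothermal(data.frame(L0 = L0, fu = fu), P0)
    expect_equal(r$Ku, 1, tolerance = 1e-3)
})

test_that("ligand-independent fu is flagged as no shift", {
    tab <- data.frame(L0 = c(0, 1e-6, 1e-5, 1e-4), fu = rep(0.41, 4))
    r <- fitBindingIsothermal(tab, 1e-6)
    expect_false(r$converged)
    expect_match(r$flag, "no shift")
})

test_that("temperature scan selects the minimal-error temperature", {
    st <- simulateStudy(fastSpec(KdTrue = 1e-5, P0 = 5e-6, noisePct = 0))
    gf <- fitGlobal(st, fitLocal(st))
    iso <- scanTemperatures(gf, st, seq(42, 58, by = 1))
    sc <- scanTable(iso)
    expect_equal(selectedTemperature(iso),
                 sc$T[which.min(ifelse(sc$converged, sc$KdRelError, Inf))])
    ## Kd at the selected temperature close to truth, Tsel near apo Tm
    expect_lt(abs(log10(selectedKd(iso) / 1e-5)), log10(1.3))
    expect_lt(abs(selectedTemperature(iso) - 50), 4)
    ## a one-temperature grid degenerates to that temperature
    iso1 <- scanTemperatures(gf, st, 50)
    expect_equal(selectedTemperature(iso1), 50)
    expect_equal(nrow(scanTable(iso1)), 1L)
    expect_error(scanTemperatures(gf, st, c(10, 50)), "window")
})

test_that("with dCp mismatch the smallest deviation sits near the apo Tm", {
    ## truth dCp = 8, analysed with dCp = 0: deviation at the apo Tm must
    ## not exceed the deviation 5 degC away on either side
    st <- simulateStudy(fastSpec(KdTrue = 1e-6, P0 = 1e-7, dCpTrue = 8,
                                 noisePct = 0))
    gf <- fitGlobal(st, fitLocal(st), fitDCp = FALSE, dCpFixed = 0)
    dev <- vapply(c(45, 50, 55), function(T) {
        r <- fitBindingIsothermal(fuProfile(gf, T), 1e-7)
        abs(log10(r$Kd / 1e-6))
    }, numeric(1))
    expect_lte(dev[2], dev[1])
    expect_lte(dev[2], dev[3])
})
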