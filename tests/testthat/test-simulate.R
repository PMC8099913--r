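## Virtual binding-study generator and benchmark driver.

test_that("simulateStudy produces the stated world", {
    ## a 1 M Kd is effectively non-binding at mM ligand: all curves are
    ## within the residual RT*ln(1 + L0/Kd) ~ 1e-3 kcal/mol of the apo
    ## curve, and the ligand term vanishes entirely in the Kd -> Inf limit
    spec <- fastSpec(KdTrue = 1, noisePct = 0)
    st <- simulateStudy(spec)
    Y <- assay(st)
    apo <- Y[, ligandConcentrations(st) == 0]
    expect_lt(max(abs(Y - apo)), 1e-3)
    spec2 <- fastSpec(KdTrue = 1e6, noisePct = 0)
    Y2 <- assay(simulateStudy(spec2))
    expect_lt(max(abs(Y2 - Y2[, ligandConcentrations(st) == 0])), 1e-9)
    ## determinism: identical spec and seed give bit-identical output
    s2 <- fastSpec(KdTrue = 1e-6, P0 = 1e-6, noisePct = 0.02, seed = 99L)
    expect_identical(assay(simulateStudy(s2)), assay(simulateStudy(s2)))
    ## different seed changes the noise
    s3 <- fastSpec(KdTrue = 1e-6, P0 = 1e-6, noisePct = 0.02, seed = 100L)
    expect_false(identical(assay(simulateStudy(s2)), assay(simulateStudy(s3))))
})

test_that("apparent melting midpoint increases with ligand concentration", {
    spec <- fastSpec(KdTrue = 1e-6, P0 = 1e-6, noisePct = 0)
    st <- simulateStudy(spec)
    Tc <- temperatures(st)
    ## locate the fu = 0.5 crossing from the known baselines, per curve
    midpoint <- apply(assay(st), 2, function(y) {
        fu <- (y - (spec@mf * Tc + spec@bf)) /
              ((spec@mu * Tc + spec@bu) - (spec@mf * Tc + spec@bf))
        stats::approx(fu, Tc, xout = 0.5, ties = "ordered")$y
    })
    ord <- order(ligandConcentrations(st))
    expect_true(all(diff(midpoint[ord]) > 0))
})

test_that("noise amplitude follows the study dynamic range", {
    spec0 <- fastSpec(KdTrue = 1e-6, P0 = 1e-7, noisePct = 0)
    specN <- fastSpec(KdTrue = 1e-6, P0 = 1e-7, noisePct = 0.02, seed = 5L)
    clean <- assay(simulateStudy(spec0))
    noisy <- assay(simulateStudy(specN))
    sigma <- sd(noisy - clean)
    expect_equal(sigma, 0.02 * diff(range(clean)), tolerance = 0.05)
})

test_that("simulationSpec validity catches bad worlds", {
    expect_error(simulationSpec(noisePct = 0.5), "noisePct")
    expect_error(simulationSpec(L0 = c(1e-6, 1e-5)), "apo")
    expect_error(simulationSpec(Tgrid = seq(45, 60, 0.5)), "span")
})

test_that("single-cell noiseless benchmark recovers Kd", {
    rec <- suppressWarnings(
        runBenchmark(Kd = 1e-6, P0 = 1e-7, dCp = 0, noise = 0,
                     fitDCp = FALSE, reps = 1, seed = 3,
                     spec = fastSpec()))
    expect_equal(nrow(rec), 1L)
    expect_true(rec$converged)
    expect_gt(rec$deviation, 0.9)
    expect_lt(rec$deviation, 1.1)
    ## reproducible under the same root seed
    rec2 <- suppressWarnings(
        runBenchmark(Kd = 1e-6, P0 = 1e-7, dCp = 0, noise = 0,
                     fitDCp = FALSE, reps = 1, seed = 3,
                     spec = fastSpec()))
    expect_identical(rec, rec2)
})
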