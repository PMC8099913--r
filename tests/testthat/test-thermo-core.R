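## Closed-form thermodynamic primitives.

test_that("dGUnfolding matches its closed forms and vanishes at Tm", {
    ## zero at the midpoint, by construction, for any dCp
    expect_equal(dGUnfolding(323.15, Tm = 323.15, dH = 100, dCp = 5), 0)
    ## dCp = 0 reduces to dH * (1 - T/Tm)
    expect_equal(dGUnfolding(313.15, Tm = 323.15, dH = 100),
                 3.0945381402, tolerance = 1e-9)
    ## dCp = 8: frozen from an independent term-by-term evaluation
    ## (dH) + (dCp*(T-Tm)) + (-T*(dH/Tm + dCp*log(T/Tm)))
    expect_equal(dGUnfolding(313.15, Tm = 323.15, dH = 100, dCp = 8),
                 1.8437533581, tolerance = 1e-9)
    ## property: dG(Tm) = 0 over a random parameter sweep
    set.seed(7)
    for (i in 1:50) {
        Tm <- runif(1, 290, 370)
        expect_equal(dGUnfolding(Tm, Tm, dH = runif(1, 20, 500),
                                 dCp = runif(1, -5, 15)), 0)
    }
    expect_error(dGUnfolding(-1, 323.15, 100), "positive")
    expect_error(dGUnfolding(313, Tm = 323, dH = -5), "dH")
})

test_that("dGTotal adds the ligand stabilisation term", {
    p <- list(Tm = 323.15, dH = 100)
    expect_equal(dGTotal(313.15, p$Tm, p$dH, Lfree = 0, Kd = 1e-6),
                 dGUnfolding(313.15, p$Tm, p$dH))
    R <- gasConstant()
    expect_equal(dGTotal(313.15, p$Tm, p$dH, Lfree = 1e-6, Kd = 1e-6),
                 dGUnfolding(313.15, p$Tm, p$dH) + R * 313.15 * log(2))
    ## with dG_U = 0 (T = Tm): R*T*ln(1 + 10) frozen independently
    expect_equal(dGTotal(323.15, 323.15, 100, Lfree = 1e-5, Kd = 1e-6),
                 1.5398443522, tolerance = 1e-9)
    ## ligand never destabilises
    set.seed(11)
    for (i in 1:50) {
        T <- runif(1, 280, 360)
        Lf <- 10^runif(1, -9, -3)
        Kd <- 10^runif(1, -9, -3)
        expect_gte(dGTotal(T, 323.15, 120, Lfree = Lf, Kd = Kd),
                   dGUnfolding(T, 323.15, 120))
    }
    expect_error(dGTotal(313.15, 323.15, 100, Lfree = 1, Kd = -1), "Kd")
})

test_that("freeLigand agrees with the quadratic-root oracle", {
    ## the printed expression must equal the positive root of
    ## L^2 + (P0/(Ku+1) + Kd - L0) L - Kd L0 = 0 (realistic assay ranges)
    set.seed(42)
    n <- 1e4
    L0 <- 10^runif(n, -9, -2.5)
    P0 <- 10^runif(n, -8, -4.5)
    Ku <- 10^runif(n, -4, 4)
    Kd <- 10^runif(n, -9, -3)
    bq <- P0 / (Ku + 1) + Kd - L0
    cq <- -Kd * L0
    root <- ifelse(bq <= 0, (-bq + sqrt(bq^2 - 4 * cq)) / 2,
                   -2 * cq / (bq + sqrt(bq^2 - 4 * cq)))
    relDev <- abs(freeLigand(L0, P0, Ku, Kd) - root) / root
    expect_lt(max(relDev), 1e-12)
})

test_that("freeLigand limits and monotonicity", {
    expect_equal(freeLigand(0, 1e-6, 2, 1e-6), 0)
    ## fully unfolded protein binds nothing
    expect_equal(freeLigand(1e-5, 1e-5, 1e12, 1e-6), 1e-5, tolerance = 1e-6)
    L <- freeLigand(c(1e-7, 1e-6, 1e-5), 5e-6, 1, 1e-6)
    expect_true(all(diff(L) > 0))
    expect_true(all(L >= 0 & L <= c(1e-7, 1e-6, 1e-5)))
    ## monotone in Ku and Kd
    expect_lte(freeLigand(1e-6, 5e-6, 0.1, 1e-6),
               freeLigand(1e-6, 5e-6, 10, 1e-6))
    expect_lte(freeLigand(1e-6, 5e-6, 1, 1e-7),
               freeLigand(1e-6, 5e-6, 1, 1e-5))
})

test_that("freeLigandExact solves the full three-species mass balance", {
    ## numeric oracle: solve L*(1 + P0/(Kd*(1+Ku)+L)) = L0 by bisection
    set.seed(13)
    for (i in 1:200) {
        L0 <- 10^runif(1, -8, -3)
        P0 <- 10^runif(1, -8, -4)
        Ku <- 10^runif(1, -3, 3)
        Kd <- 10^runif(1, -9, -4)
        f <- function(L) L * (1 + P0 / (Kd * (1 + Ku) + L)) - L0
        oracle <- uniroot(f, c(0, L0), tol = 1e-18)$root
        expect_equal(freeLigandExact(L0, P0, Ku, Kd), oracle,
                     tolerance = 1e-6)
        ## exact >= printed expression: the printed form scales the protein
        ## pool, the exact form scales Kd, so they differ when Ku is large
        expect_lte(abs(freeLigandExact(L0, P0, Ku, Kd) - oracle), L0 * 1e-6)
    }
})

test_that("apparentKu and fractionUnfolded behave as stated", {
    expect_equal(apparentKu(0, 300), 1)
    expect_equal(apparentKu(gasConstant() * 300 * log(2), 300), 0.5)
    ## frozen scalar oracle: exp(-3.0946 / (R * 313.15))
    expect_equal(apparentKu(3.0946, 313.15), 0.006923047909,
                 tolerance = 1e-9)
    expect_equal(fractionUnfolded(1), 0.5)
    expect_equal(fractionUnfolded(0), 0)
    expect_equal(fractionUnfolded(3), 0.75)
    ## composition is a monotone sigmoid in T for dCp = 0
    T <- seq(290, 360, by = 0.5)
    fu <- fractionUnfolded(apparentKu(dGUnfolding(T, 323.15, 120), T))
    expect_true(all(diff(fu) > 0))
    expect_true(all(fu >= 0 & fu <= 1))
})

test_that("signalModel is the convex combination of the baselines", {
    b <- list(mf = -0.002, bf = 1.5, mu = 0.001, bu = 1.1)
    T <- c(25, 50, 75)
    expect_equal(signalModel(T, 0, b$mf, b$bf, b$mu, b$bu), b$mf * T + b$bf)
    expect_equal(signalModel(T, 1, b$mf, b$bf, b$mu, b$bu), b$mu * T + b$bu)
    expect_equal(signalModel(T, 0.5, b$mf, b$bf, b$mu, b$bu),
                 (b$mf * T + b$bf + b$mu * T + b$bu) / 2)
    expect_error(signalModel(50, 1.2, b$mf, b$bf, b$mu, b$bu), "fu")
})

test_that("estimateDCp rejects invalid residue counts", {
    expect_error(estimateDCp(0), "positive")
    expect_error(estimateDCp(10.5), "integer")
    expect_equal(estimateDCp(1000), 13.88)
})
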