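test_that("calibration refits collinear points exactly", {
    lv <- data.frame(conc = c(0.5, 1, 2.5, 5, 10))
    lv$response <- 114212 * lv$conc - 27802
    fit <- fitCalibration(lv, "Citric acid")
    expect_equal(fit$a, 114212, tolerance = 1e-10)
    expect_equal(fit$b, -27802, tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
    expect_error(fitCalibration(lv[1:2, ]), "insufficient levels")
    expect_error(fitCalibration(data.frame(conc = c(1, 1, 1),
                                           response = c(1, 2, 3))),
                 "insufficient levels")
})

test_that("standard errors follow the classical OLS formulas", {
    set.seed(5)
    lv <- data.frame(conc = c(0.5, 1, 2.5, 5, 10))
    lv$response <- 1000 * lv$conc + 50 + rnorm(5, 0, 30)
    fit <- fitCalibration(lv)
    # independent computation from the residuals
    res <- lv$response - (fit$a * lv$conc + fit$b)
    s2 <- sum(res^2) / (nrow(lv) - 2)
    sxx <- sum((lv$conc - mean(lv$conc))^2)
    expect_equal(fit$sa, sqrt(s2 / sxx), tolerance = 1e-10)
    expect_equal(fit$sb, sqrt(s2 * (1 / nrow(lv) +
                                    mean(lv$conc)^2 / sxx)),
                 tolerance = 1e-10)
})

test_that("inversion is the exact algebraic inverse", {
    lv <- data.frame(conc = c(0.5, 1, 2.5, 5, 10))
    lv$response <- 114212 * lv$conc - 27802
    fit <- fitCalibration(lv)
    expect_equal(invertConcentration(fit, 543258), 5, tolerance = 1e-10)
    expect_equal(invertConcentration(fit, fit$b), 0)
    expect_equal(invertConcentration(fit, 114212 * lv$conc - 27802),
                 lv$conc, tolerance = 1e-10)
    fit$a <- 0
    expect_error(invertConcentration(fit, 100), "zero")
})

test_that("quantification is invariant under common response scaling", {
    qf <- quantFixture()
    cal <- qf$calibration[qf$calibration$analyte == "Quercetin", ]
    resp <- qf$responses[qf$responses$analyte == "Quercetin", ]
    base <- quantifySamples(fitCalibration(cal, "Quercetin"), resp)
    cal2 <- cal; cal2$response <- cal2$response * 3.7
    resp2 <- resp; resp2$response <- resp2$response * 3.7
    scaled <- quantifySamples(fitCalibration(cal2, "Quercetin"), resp2)
    expect_equal(scaled$concentration, base$concentration,
                 tolerance = 1e-10)
})

test_that("the zero-noise fixture reproduces the reference table", {
    qf <- quantFixture()
    curves <- lapply(split(qf$calibration, qf$calibration$analyte),
                     function(g) fitCalibration(g, g$analyte[1]))
    q <- quantifySamples(curves, qf$responses)
    m <- merge(q, qf$reference, by = c("analyte", "sample"))
    expect_equal(nrow(m), nrow(qf$reference))
    relErr <- abs(m$concentration.x - m$concentration.y) /
        m$concentration.y
    expect_true(all(relErr < 0.005))
    expect_equal(m$sd.x, m$sd.y, tolerance = 1e-9)
    expect_equal(m$belowLoq.x, m$belowLoq.y)
    expect_true(all(m$n == 3))
    cit <- q[q$analyte == "Citric acid" & q$sample == "80", ]
    expect_equal(cit$concentration, 203, tolerance = 1e-9)
    # below-LOQ analytes are flagged, not dropped
    expect_true(q$belowLoq[q$analyte == "Abscisic acid" & q$sample == "90"])
    # single replicate: sd 0, n 1
    one <- quantifySamples(curves,
                           qf$responses[qf$responses$analyte ==
                                        "Citric acid", ][1, ])
    expect_equal(one$sd, 0)
    expect_equal(one$n, 1)
    expect_error(
        quantifySamples(curves["Citric acid"],
                        data.frame(analyte = "Unknown", sample = "80",
                                   replicate = 1, response = 1)),
        "no calibration curve")
})

test_that("noisy seeded calibrations keep R2 at or above 0.97", {
    qn <- quantFixture(noiseFraction = 0.02, seed = 17L)
    r2 <- vapply(split(qn$calibration, qn$calibration$analyte),
                 function(g) fitCalibration(g)$r2, numeric(1))
    expect_true(all(r2 >= 0.97))
    expect_true(all(r2 < 1))
    # same seed, same series
    qn2 <- quantFixture(noiseFraction = 0.02, seed = 17L)
    expect_identical(qn$calibration, qn2$calibration)
})
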