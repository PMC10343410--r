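test_that("generated EIC area recovers the specified area within 2%", {
    for (dt in c(0.02, 0.01)) {
        run <- generateRun(tinyRecipe(area = 1e6, scanInterval = dt))
        eic <- extractEic(run, 301.0354)
        # independent trapezoid oracle over the full trace
        area <- sum(diff(eic$rt) * (head(eic$intensity, -1) +
                                    tail(eic$intensity, -1)) / 2)
        expect_equal(area, 1e6, tolerance = 0.02)
    }
})

test_that("runs are byte-identical under a fixed seed", {
    r1 <- generateRun(tinyRecipe(noiseLevel = 50, seed = 99L))
    r2 <- generateRun(tinyRecipe(noiseLevel = 50, seed = 99L))
    p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
    writeRunJson(r1, p1); writeRunJson(r2, p2)
    expect_identical(readLines(p1), readLines(p2))
    r3 <- generateRun(tinyRecipe(noiseLevel = 50, seed = 100L))
    p3 <- withr::local_tempfile(); writeRunJson(r3, p3)
    expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("a zero-noise, zero-compound recipe yields empty spectra", {
    rec <- tinyRecipe(noiseLevel = 0, scanInterval = 0.1)
    rec$compounds <- rec$compounds[integer(), ]
    run <- generateRun(rec)
    expect_true(all(vapply(spectraOf(run), function(s)
        nrow(s@peaks) == 0, logical(1))))
})

test_that("DDA and DIA recipes share the same MS1-level features", {
    fx <- juiceFixture(scanInterval = 0.02, noiseLevel = 0)
    dda <- generateRun(fx$recipes[["100_negative_DDA"]])
    dia <- generateRun(fx$recipes[["100_negative_DIA"]])
    fDda <- screenRun(dda, fx$suspects)
    fDia <- screenRun(dia, fx$suspects)
    expect_equal(fDda$suspect, fDia$suspect)
    expect_equal(fDda$rtApex, fDia$rtApex)
    expect_equal(fDda$area, fDia$area, tolerance = 1e-6)
})

test_that("the juice fixture encodes the study layout", {
    fx <- juiceFixture()
    expect_gte(nrow(fx$suspects), 29)
    expect_equal(sort(intersectSuspectLists(fx$vmsl, fx$lbl)$name),
                 sort(c("Quercetin", "Kaempferol", "Apigenin",
                        "Gentisic acid", "Gallic acid",
                        "Chlorogenic acid")))
    cmp <- fx$compounds
    expect_equal(nrow(cmp), 29)
    expect_equal(sum(table(fx$expectedLevels$level)), 29)
    expect_equal(as.vector(table(fx$expectedLevels$level)[c("1", "2a", "2b", "3")]),
                 c(17L, 10L, 1L, 1L))
    # citric acid row: RT, standard RT and fragment set
    cit <- cmp[cmp$name == "Citric acid", ]
    expect_equal(cit$rtObs, 1.2)
    expect_equal(fx$standards$rt[fx$standards$name == "Citric acid"], 1.2)
    expect_equal(cit$sampleFrags[[1]],
                 c(57.0353, 87.0092, 111.0094, 191.0198))
    expect_equal(nrow(fx$standards), 17)
    # abundance patterns: ethyl gallate decreasing with secondary-juice
    # percentage, quercetin increasing, fructose flat
    areaOf <- function(name, sample) {
        r <- fx$recipes[[paste0(sample, "_negative_DDA")]]$compounds
        r$area[r$name == name]
    }
    expect_true(areaOf("Ethyl gallate", "80") <
                areaOf("Ethyl gallate", "90"))
    expect_true(areaOf("Ethyl gallate", "90") <
                areaOf("Ethyl gallate", "100"))
    expect_true(areaOf("Quercetin", "80") > areaOf("Quercetin", "90"))
    expect_equal(areaOf("Fructose", "80"), areaOf("Fructose", "100"))
    # blank: tenfold below the 100% sample except the two probes (threefold)
    blank <- fx$recipes[["blank_negative_DDA"]]$compounds
    s100 <- fx$recipes[["100_negative_DDA"]]$compounds
    ratio <- s100$area / blank$area[match(s100$name, blank$name)]
    expect_equal(unname(ratio[s100$name %in% fx$probes]), c(3, 3))
    expect_true(all(ratio[!s100$name %in% fx$probes] >= 5))
})

test_that("quantification fixture reproduces its generating equations", {
    qf <- quantFixture()
    cit <- qf$calibration[qf$calibration$analyte == "Citric acid", ]
    expect_equal(cit$response[cit$conc == 5], 114212 * 5 - 27802)
    fit <- fitCalibration(cit)
    expect_equal(fit$a, 114212, tolerance = 1e-9)
    expect_equal(fit$b, -27802, tolerance = 1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
    # gallic acid sample concentrations recoverable from the responses
    g <- qf$responses[qf$responses$analyte == "Gallic acid", ]
    conc <- (g$response - 57556) / 46623
    means <- tapply(conc, g$sample, mean)
    expect_equal(as.numeric(means[c("80", "90", "100")]),
                 c(5.72, 4.57, 5.11), tolerance = 1e-9)
})
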