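test_that("the level cascade reproduces the canonical evidence patterns", {
    # confirmed by standard: RT agreement + spectral match to the standard
    citric <- evidence(TRUE, referenceAvailable = TRUE, referenceRt = 1.2,
                       referenceScore = 0.76, rtObserved = 1.2,
                       spectrumRoute = "DDA")
    expect_equal(assignLevel(citric)$level, "1")
    # library match above the 0.7 gate, no standard
    kaempferol <- evidence(TRUE, spectrumRoute = "DDA", libraryScore = 0.78)
    expect_equal(assignLevel(kaempferol)$level, "2a")
    # diagnostic ions only
    glucoside <- evidence(TRUE, spectrumRoute = "DDA",
                          diagnosticIonsOk = TRUE)
    expect_equal(assignLevel(glucoside)$level, "2b")
    # in-silico support only
    ethylGallate <- evidence(TRUE, spectrumRoute = "DIA",
                             inSilicoSupport = TRUE)
    expect_equal(assignLevel(ethylGallate)$level, "3")
    # formula confirmed
    expect_equal(assignLevel(evidence(TRUE, formulaConfirmed = TRUE))$level,
                 "4")
    # exact mass only
    expect_equal(assignLevel(evidence(TRUE))$level, "5")
    expect_error(assignLevel(evidence(FALSE)), "mass match")
})

test_that("gates sit exactly where specified", {
    # the 0.7 library gate is strict
    at07 <- evidence(TRUE, spectrumRoute = "DDA", libraryScore = 0.70)
    expect_equal(assignLevel(at07)$level, "5")
    over <- evidence(TRUE, spectrumRoute = "DDA", libraryScore = 0.701)
    expect_equal(assignLevel(over)$level, "2a")
    # level 1 accepts standard-spectrum scores down to 0.6 and RT within tol
    low <- evidence(TRUE, referenceAvailable = TRUE, referenceRt = 8.3,
                    referenceScore = 0.61, rtObserved = 7.9,
                    spectrumRoute = "DDA")
    expect_equal(assignLevel(low)$level, "1")
    drift <- evidence(TRUE, referenceAvailable = TRUE, referenceRt = 8.3,
                      referenceScore = 0.61, rtObserved = 7.2,
                      spectrumRoute = "DDA", libraryScore = 0.9)
    expect_equal(assignLevel(drift)$level, "2a")  # RT off: falls through
})

test_that("adding evidence never worsens the assigned level", {
    levelRank <- function(l) match(l, c("1", "2a", "2b", "3", "4", "5"))
    base <- list(massMatch = TRUE)
    upgrades <- list(
        list(formulaConfirmed = TRUE),
        list(spectrumRoute = "DDA", inSilicoSupport = TRUE),
        list(spectrumRoute = "DDA", diagnosticIonsOk = TRUE),
        list(spectrumRoute = "DDA", libraryScore = 0.9),
        list(referenceAvailable = TRUE, referenceRt = 2, rtObserved = 2,
             referenceScore = 0.8, spectrumRoute = "DDA"))
    # cumulative evidence: each addition keeps or lowers the level
    acc <- base
    prev <- levelRank(assignLevel(do.call(evidence, acc))$level)
    for (up in upgrades) {
        acc <- utils::modifyList(acc, up)
        cur <- levelRank(assignLevel(do.call(evidence, acc))$level)
        expect_lte(cur, prev)
        prev <- cur
    }
})

test_that("rationales are reproducible and name the fired rule", {
    ev <- evidence(TRUE, spectrumRoute = "DDA", libraryScore = 0.83)
    a1 <- assignLevel(ev); a2 <- assignLevel(ev)
    expect_identical(a1, a2)
    expect_match(a1$rationale, "^L2a")
    expect_match(assignLevel(evidence(TRUE))$rationale, "^L5")
    expect_error(evidence(TRUE, libraryScore = 0.8), "requires a spectrum")
    expect_error(evidence(TRUE, referenceRt = 2), "without a standard")
})

test_that("dataset annotation aggregates to best level per compound", {
    features <- data.frame(
        suspect = c("A", "A", "B"), sample = c("s1", "s2", "s1"),
        rtApex = c(1, 1, 2), mz = c(100.05, 100.05, 200.1))
    suspects <- suspectTable(c("A", "B"), c("C6H8O7", "C7H6O5"))
    suspects$precursorMz <- c(100.05, 200.1)  # align to the toy features
    reports <- data.frame(
        suspect = c("A", "A", "B"), sample = c("s1", "s2", "s1"),
        route = "DDA", libraryScore = c(0.9, NA, NA),
        referenceScore = NA_real_, diagnosticOk = NA, inSilicoOk = NA)
    res <- annotateDataset(features, reports, suspects,
                           data.frame(name = character(), rt = numeric()))
    expect_equal(nrow(res$annotations), 3)
    lev <- res$annotations
    expect_equal(lev$level[lev$suspect == "A" & lev$sample == "s1"], "2a")
    expect_equal(lev$level[lev$suspect == "A" & lev$sample == "s2"], "4")
    # best level across samples wins per compound
    expect_equal(res$byCompound$level[res$byCompound$suspect == "A"], "2a")
    expect_equal(unname(unclass(res$summary)), c(1, 1),
                 ignore_attr = TRUE)
    empty <- annotateDataset(features[integer(), ], reports, suspects,
                             data.frame(name = character(), rt = numeric()))
    expect_equal(nrow(empty$annotations), 0)
})

test_that("isobaric co-candidates collapse onto one compound per feature", {
    features <- data.frame(
        suspect = c("Rutin", "Kaempferol diglucoside"),
        sample = "s1", rtApex = c(5.7, 5.7), mz = c(609.1461, 609.1461))
    suspects <- suspectTable(c("Rutin", "Kaempferol diglucoside"),
                             c("C27H30O16", "C27H30O16"))
    reports <- data.frame(
        suspect = "Rutin", sample = "s1", route = "DDA",
        libraryScore = NA_real_, referenceScore = 0.9,
        diagnosticOk = NA, inSilicoOk = NA)
    res <- annotateDataset(features, reports, suspects,
                           data.frame(name = "Rutin", rt = 5.7))
    expect_equal(nrow(res$byCompound), 1)
    expect_equal(res$byCompound$suspect, "Rutin")
    expect_true(res$annotations$coCandidate[
        res$annotations$suspect == "Kaempferol diglucoside"])
})
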