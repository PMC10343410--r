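test_that("suspect CSV round-trips and fills missing masses", {
    sus <- suspectTable(
        name = c("Citric acid", "Leucine"),
        formula = c("C6H8O7", "C6H13NO2"),
        adduct = c("[M-H]-", "[M+H]+"),
        predictedRt = c(1.1, 1.8), source = c("BDSL", "LBL"),
        referenceStandard = c(TRUE, FALSE))
    expect_equal(round(sus$precursorMz[1], 4), 191.0197)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSuspectCsv(sus, path)
    back <- readSuspectCsv(path)
    expect_equal(back[names(back) != "diagnosticIons"],
                 sus[names(sus) != "diagnosticIons"], tolerance = 1e-9)
    # a second round trip is byte-identical
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeSuspectCsv(back, path2)
    expect_identical(readLines(path), readLines(path2))
})

test_that("the 734-entry list loads with recomputed precursor m/z", {
    full <- bdslFull()
    expect_equal(nrow(full), 734)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSuspectCsv(full, path)
    expect_equal(nrow(readSuspectCsv(path)), 734)
})

test_that("suspect CSV errors are row-addressed and schema-checked", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines("name,formula\nGood,C6H8O7\nBad,Qq7", path)
    expect_error(readSuspectCsv(path), "row 2")
    writeLines("name,mass\nX,100", path)
    expect_error(readSuspectCsv(path), "missing required column")
    writeLines("name,formula", path)
    expect_equal(nrow(readSuspectCsv(path)), 0)
    # inconsistent supplied precursor m/z is rejected
    expect_error(suspectTable("X", "C6H8O7", precursorMz = 191.5),
                 "inconsistent")
})

test_that("MSP files round-trip losslessly over randomized records", {
    set.seed(4)
    recs <- lapply(1:12, randomMspRecord)
    path <- withr::local_tempfile(fileext = ".msp")
    writeMsp(recs, path)
    back <- readMsp(path)
    expect_length(back, 12)
    for (i in seq_along(recs)) {
        expect_equal(back[[i]]@name, recs[[i]]@name)
        expect_equal(back[[i]]@formula, recs[[i]]@formula)
        expect_equal(back[[i]]@precursorMz, recs[[i]]@precursorMz,
                     tolerance = 1e-4)
        expect_equal(back[[i]]@ionMode, recs[[i]]@ionMode)
        expect_equal(unname(back[[i]]@peaks), unname(recs[[i]]@peaks),
                     tolerance = 1e-4)
        expect_equal(back[[i]]@extra, recs[[i]]@extra)  # unknown keys kept
    }
})

test_that("MSP peak-count mismatches and bad peak lines are errors", {
    path <- withr::local_tempfile(fileext = ".msp")
    writeLines(c("NAME: x", "FORMULA: C6H8O7", "PRECURSORMZ: 191.0197",
                 "PRECURSORTYPE: [M-H]-", "IONMODE: negative",
                 "Num Peaks: 3", "57.03\t100", "87.01\t50"), path)
    expect_error(readMsp(path), "peak count mismatch")
    writeLines(c("NAME: x", "Num Peaks: 1", "not-a-peak"), path)
    expect_error(readMsp(path), "peak")
})

test_that("kaempferol-style library entries parse with all fragments", {
    rec <- mspRecord("Kaempferol", "C15H10O6", 285.0405, "[M-H]-",
                     "negative", 7.6,
                     peaks = cbind(c(133.0297, 151.0039, 175.0388, 285.04),
                                   c(100, 80, 60, 40)),
                     extra = c(LibraryType = "experimental_library"))
    path <- withr::local_tempfile(fileext = ".msp")
    writeMsp(list(rec), path)
    back <- readMsp(path)[[1]]
    expect_equal(nrow(back@peaks), 4)
    expect_equal(grep("Num Peaks: 4", readLines(path)), 8)
})

test_that("merge unions source tags and is order-insensitive on keys", {
    a <- suspectTable(c("A", "B"), c("C6H8O7", "C7H6O5"), source = "BDSL")
    b <- suspectTable(c("B", "C"), c("C7H6O5", "C4H4O4"), source = "LBL")
    m <- mergeSuspectLists(a, b)
    expect_equal(m$name, c("A", "B", "C"))
    expect_equal(m$source[m$name == "B"], "BDSL;LBL")
    # commutative and associative up to ordering
    m2 <- mergeSuspectLists(b, a)
    expect_setequal(paste(m$name, m$source),
                    paste(m2$name, sub("LBL;BDSL", "BDSL;LBL", m2$source)))
    disjoint <- mergeSuspectLists(a[1, ], b[2, ])
    expect_equal(nrow(disjoint), 2)
    # same name, different formula: both kept, collision messaged
    expect_message(
        dup <- mergeSuspectLists(suspectTable("X", "C6H8O7"),
                                 suspectTable("X", "C7H6O5")),
        "name collision")
    expect_equal(nrow(dup), 2)
})

test_that("intersection is the cross-list confirmation", {
    a <- suspectTable(c("A", "B", "C"), c("C6H8O7", "C7H6O5", "C4H4O4"))
    b <- suspectTable(c("b", "c"), c("C7H6O5", "C4H4O4"))
    b$name <- c("B", "C")
    i <- intersectSuspectLists(a, b)
    expect_equal(i$name, c("B", "C"))
    expect_equal(intersectSuspectLists(a, a)$name, a$name)  # idempotent
    expect_equal(nrow(intersectSuspectLists(a, suspectTable())), 0)
    # subset property on both sides
    expect_true(all(paste(i$formula, tolower(i$name)) %in%
                    paste(a$formula, tolower(a$name))))
    expect_true(all(paste(i$formula, tolower(i$name)) %in%
                    paste(b$formula, tolower(b$name))))
})
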