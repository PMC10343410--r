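# ---- compound catalogue for the juice fixture ----------------------------
#
# The fixture emulates three pomegranate-based juice samples (80/90/100%
# pomegranate) and a procedure blank. Each compound carries: the adduct, the
# observed apex RT and (when a reference standard exists) the standard's RT,
# the experimental precursor m/z planted in the runs, the top fragment m/z of
# the sample spectra and of the library/reference spectra, the expected
# confidence level, and an abundance pattern across the samples ("up80":
# higher with more secondary juices; "down80": lower; "flat": unchanged).

.frag <- function(...) c(...)

.juiceCompounds <- function() {
    rows <- list(
    list("Citric acid", "C6H8O7", "[M-H]-", 1.2, 1.2, 191.0213, "1",
         "reference_standard", "", "flat", 5.0e7,
         .frag(57.0353, 87.0092, 111.0094, 191.0198),
         .frag(57.0354, 87.0089, 111.0088, 191.0199)),
    list("Malic acid", "C4H6O5", "[M-H]-", 1.2, 1.1, 133.0131, "1",
         "reference_standard", "", "flat", 1.2e7,
         .frag(71.0144, 115.0047, 133.0127),
         .frag(71.0139, 115.0022, 133.0138)),
    list("Fructose", "C6H12O6", "[M-H]-", 1.4, 1.3, 179.05754, "1",
         "reference_standard", "", "flat", 3.0e7,
         .frag(89.0224, 179.0560), .frag(89.0246, 179.0558)),
    list("Gallic acid", "C7H6O5", "[M-H]-", 1.6, 1.5, 169.0151, "1",
         "reference_standard", "", "flat", 2.6e6,
         .frag(69.0354, 97.0271, 125.0245),
         .frag(69.0346, 97.0295, 125.0244)),
    list("Gentisic acid", "C7H6O4", "[M-H]-", 2.2, 2.4, 153.0199, "1",
         "reference_standard", "", "flat", 8.0e5,
         .frag(108.0191, 109.0289), .frag(108.0217, 109.0295)),
    list("Chlorogenic acid", "C16H18O9", "[M-H]-", 2.9, 2.9, 353.0896, "1",
         "reference_standard", "", "up80", 2.2e6,
         .frag(161.0264, 173.0479, 191.0557, 192.0564),
         .frag(161.0233, 173.0447, 191.0555, 192.0589)),
    list("Fumaric acid", "C4H4O4", "[M-H]-", 1.3, NA, 115.0035, "2a",
         "experimental_library", "MzCloud no 1274", "flat", 3.5e6,
         .frag(71.0136, 72.9928, 115.0035),
         .frag(71.0136, 72.9925, 115.0040)),
    list("Quinic acid", "C7H12O6", "[M-H]-", 1.3, 1.3, 191.0564, "1",
         "reference_standard", "", "up80", 4.0e6,
         .frag(85.0291, 191.0564), .frag(85.0299, 191.0558)),
    list("Phenylalanine", "C9H11NO2", "[M-H]-", 3.0, 3.0, 164.0726, "1",
         "reference_standard", "", "flat", 2.8e6,
         .frag(72.0091, 147.0447, 164.0728),
         .frag(72.0099, 147.0448, 164.0712)),
    list("Leucine", "C6H13NO2", "[M+H]+", 2.8, 2.8, 132.1020, "1",
         "reference_standard", "", "flat", 3.2e6,
         .frag(58.0654, 69.0697, 86.0964, 87.0989, 132.1019),
         .frag(58.0634, 69.0686, 86.0956, 87.0987, 132.1013)),
    list("Norvaline", "C5H11NO2", "[M+H]+", 4.5, NA, NA, "2a",
         "experimental_library", "MoNA ID: FiehnHILIC002191", "flat", 6.0e5,
         .frag(65.03932, 117.0584, 118.0658),
         .frag(65.036, 117.057, 118.062)),
    list("Quercetin", "C15H10O7", "[M-H]-", 7.3, 7.3, 301.0361, "1",
         "reference_standard", "", "up80", 1.8e6,
         .frag(151.0042, 169.0170, 179.0004),
         .frag(151.0037, 169.0135, 178.9996)),
    list("Rutin", "C27H30O16", "[M-H]-", 5.7, 5.7, 609.1472, "1",
         "reference_standard", "", "up80", 1.5e6,
         .frag(300.028, 301.0312), .frag(300.0256, 301.0366)),
    list("Apigenin", "C15H10O5", "[M-H]-", 8.3, 7.9, 269.0460, "1",
         "reference_standard", "", "flat", 7.0e5,
         .frag(117.0359, 151.0077, 269.0463),
         .frag(117.0341, 151.0029, 269.0459)),
    list("Kaempferol", "C15H10O6", "[M-H]-", 7.6, NA, 285.042, "2a",
         "experimental_library", "GNPS ID: VF-NPL-QEHF014174", "up80", 9.0e5,
         .frag(133.0305, 151.0030, 175.0386, 285.0421),
         .frag(133.0297, 151.0039, 175.0388, 285.0400)),
    list("Verbascoside", "C29H36O15", "[M-H]-", 5.0, 4.8, 623.1993, "1",
         "reference_standard", "", "up80", 8.5e5,
         .frag(161.0319, 162.0263), .frag(161.0244, 162.0278)),
    list("Phloridzin", "C21H24O10", "[M-H]-", 5.9, 5.8, 435.1291, "1",
         "reference_standard", "", "flat", 6.5e5,
         .frag(167.0362), .frag(167.0340)),
    list("Ethyl gallate", "C9H10O5", "[M-H]-", 4.9, NA, 197.0473, "3",
         "in_silico", "FoodB ID:FDB012004", "down80", 1.1e6,
         .frag(123.0061, 140.0102, 168.0066, 169.0149, 197.0460),
         .frag(123.0086, 140.0118, 168.0074, 169.0146, 197.0460)),
    list("Linoleic acid", "C18H32O2", "[M-H]-", 13.5, 13.5, 279.2336, "1",
         "reference_standard", "", "flat", 4.5e6,
         .frag(279.2327, 280.2345), .frag(279.2328, 280.2333)),
    list("Oleic acid", "C18H34O2", "[M-H]-", 14.0, 14.0, 281.2486, "1",
         "reference_standard", "", "flat", 5.5e6,
         .frag(281.2484, 282.2526), .frag(281.2468, 282.2508)),
    list("Palmitic acid", "C16H32O2", "[M-H]-", 13.8, 13.8, 255.2334, "1",
         "reference_standard", "", "flat", 4.8e6,
         .frag(255.2329, 256.2366, 257.2349),
         .frag(255.2327, 256.2364, 257.2395)),
    list("Linolenic acid", "C18H30O2", "[M-H]-", 13.0, NA, 277.2170, "2a",
         "experimental_library", "MoNA ID: MetaboBASE0976", "flat", 1.6e6,
         .frag(277.2198), .frag(277.2180)),
    list("Ellagic acid", "C14H6O8", "[M-H]-", 4.6, NA, 300.9993, "2a",
         "experimental_library", "MoNA ID:FiehnHILIC001170", "flat", 2.4e6,
         .frag(201.0183, 229.0143, 283.9960, 299.9924, 300.9992),
         .frag(201.0200, 229.0144, 283.9950, 299.9900, 300.9994)),
    list("Glucosamine", "C6H13NO5", "[M-H2O+H]+", 1.8, NA, 162.0764, "2a",
         "experimental_library", "GNPS ID: CCMSLIB00005464276", "flat",
         1.9e6,
         .frag(60.0450, 72.0450, 84.0450, 85.0290, 162.0760),
         .frag(60.0443, 72.0435, 84.0445, 85.0284, 162.0744)),
    list("2-Phenylethyl beta-D-glucopyranoside", "C14H20O6", "[M+NH4]+",
         6.5, NA, 302.1616, "2a", "experimental_library",
         "GNPS ID:CCMSLIB00000854907", "flat", 5.5e5,
         .frag(81.0337, 85.0287, 97.0289, 105.0707, 127.0340),
         .frag(81.0330, 85.0270, 97.0280, 105.0710, 127.0400)),
    list("Pyroglutamic acid", "C5H7NO3", "[M+H]+", 2.4, NA, 130.0511, "2a",
         "experimental_library", "MassBank ID: PR311148", "flat", 2.1e6,
         .frag(84.0455, 85.0483, 129.0190, 130.0508),
         .frag(84.0460, 85.0450, 129.0220, 130.0510)),
    list("4-Hydroxyquinoline", "C9H7NO", "[M+H]+", 4.5, NA, 146.0606, "2a",
         "experimental_library", "RIKEN PLaSMA ID:RIKENPlaSMA000824",
         "flat", 4.0e5,
         .frag(77.0389, 91.0541, 101.0395, 146.0598),
         .frag(77.0370, 91.0560, 101.0440, 146.0610)),
    list("Dihydrozeatin", "C10H15N5O", "[M+H]+", 5.8, NA, 222.1351, "2a",
         "experimental_library", "MoNA ID: FiehnHILIC000308", "flat", 3.0e5,
         .frag(69.0699, 136.0615, 148.0626, 204.1227, 222.1347),
         .frag(69.0710, 136.0620, 148.0620, 204.1250, 222.1349)),
    list("Ellagic acid glucoside", "C20H16O13", "[M-H]-", 3.7, NA,
         463.0514, "2b", "diagnostic_only", "Using Smilib", "flat", 4.5e5,
         .frag(300.9976, 463.0514), numeric())
    )
    df <- data.frame(
        name = vapply(rows, `[[`, "", 1L),
        formula = vapply(rows, `[[`, "", 2L),
        adduct = vapply(rows, `[[`, "", 3L),
        rtObs = vapply(rows, function(r) as.numeric(r[[4L]]), numeric(1)),
        rtStd = vapply(rows, function(r) as.numeric(r[[5L]]), numeric(1)),
        expMz = vapply(rows, function(r) as.numeric(r[[6L]]), numeric(1)),
        level = vapply(rows, `[[`, "", 7L),
        libraryType = vapply(rows, `[[`, "", 8L),
        dbRef = vapply(rows, `[[`, "", 9L),
        pattern = vapply(rows, `[[`, "", 10L),
        baseArea = vapply(rows, function(r) as.numeric(r[[11L]]),
                          numeric(1)),
        stringsAsFactors = FALSE)
    df$theorMz <- mapply(function(f, a) adductMz(f, a), df$formula,
                         df$adduct)
    df$expMz[is.na(df$expMz)] <- df$theorMz[is.na(df$expMz)]
    df$polarity <- vapply(df$adduct, function(a) adductSpec(a)$polarity, "")
    df$sampleFrags <- lapply(rows, `[[`, 12L)
    df$refFrags <- lapply(rows, `[[`, 13L)
    df
}

# two planted procedure-blank false positives: common lab contaminants whose
# sample/blank area ratio (3) fails the five-fold rule
.blankProbes <- function() {
    df <- data.frame(
        name = c("Dodecyl sulfate", "Azelaic acid"),
        formula = c("C12H26O4S", "C9H16O4"),
        adduct = "[M-H]-", rtObs = c(9.5, 6.8), rtStd = NA_real_,
        level = NA_character_, libraryType = "none", dbRef = "",
        pattern = "flat", baseArea = c(4.0e5, 2.5e5),
        stringsAsFactors = FALSE)
    df$theorMz <- mapply(function(f, a) adductMz(f, a), df$formula,
                         df$adduct)
    df$expMz <- df$theorMz
    df$polarity <- "negative"
    df$sampleFrags <- list(numeric(), numeric())
    df$refFrags <- list(numeric(), numeric())
    df
}

.SAMPLE_MULT <- list(
    flat   = c("80" = 1.00, "90" = 1.00, "100" = 1.00),
    up80   = c("80" = 1.30, "90" = 1.15, "100" = 1.00),
    down80 = c("80" = 0.70, "90" = 0.85, "100" = 1.00))

.FRAG_INTENSITIES <- c(100, 80, 60, 40, 20)

.fragMatrix <- function(mzs) {
    if (!length(mzs)) return(matrix(numeric(), 0, 2))
    cbind(mz = mzs,
          intensity = .FRAG_INTENSITIES[seq_along(mzs)])
}

# ---- run generation ------------------------------------------------------

#' Build a synthetic run recipe
#'
#' @param sampleId sample label.
#' @param compounds data.frame with columns `name`, `mz` (planted precursor
#'   m/z), `rt` (apex, minutes), `sigma` (Gaussian peak width, minutes),
#'   `area` (chromatographic area, arbitrary units) and the list-column
#'   `frags` (two-column matrices of fragment m/z and relative intensity).
#' @param gradientLength run length (minutes).
#' @param scanInterval survey-scan spacing (minutes).
#' @param noiseLevel maximum intensity of the uniform chemical-noise
#'   centroids (0 = noise-free).
#' @param seed RNG seed; a fixed seed makes [generateRun()] byte-identical.
#' @param acquisition "DDA" or "DIA".
#' @param polarity "negative" or "positive".
#' @param ddaTopN how many compounds (by area) trigger a DDA MS2 scan.
#' @param metadata named list stored in the run.
#' @return list of class `"RunRecipe"`.
#' @export
runRecipe <- function(sampleId, compounds, gradientLength = 15,
                      scanInterval = 0.02, noiseLevel = 20, seed = 1L,
                      acquisition = c("DDA", "DIA"),
                      polarity = c("negative", "positive"),
                      ddaTopN = 40L, metadata = list()) {
    acquisition <- match.arg(acquisition)
    polarity <- match.arg(polarity)
    stopifnot(scanInterval > 0, gradientLength > 0)
    structure(list(sampleId = sampleId, compounds = compounds,
                   gradientLength = gradientLength,
                   scanInterval = scanInterval, noiseLevel = noiseLevel,
                   seed = as.integer(seed), acquisition = acquisition,
                   polarity = polarity, ddaTopN = ddaTopN,
                   metadata = metadata),
              class = "RunRecipe")
}

#' Generate a synthetic LC-MS run
#'
#' Survey scans contain one Gaussian chromatographic peak per compound at its
#' precursor m/z (apex RT, width sigma, integrated area as specified) plus
#' uniform random noise centroids. DDA recipes trigger one MS2 scan at each
#' compound's apex for the `ddaTopN` largest compounds, containing its
#' fragments scaled to the precursor apex intensity. DIA recipes alternate
#' low-energy survey scans with high-energy scans holding the superposition
#' of the fragments of all co-eluting compounds, each fragment trace
#' proportional to its precursor's elution profile. Output is reproducible
#' under the recipe seed; compounds whose precursors collide within 0.005 Da
#' are flagged with a warning.
#'
#' @param recipe a [runRecipe()].
#' @return A [Run-class].
#' @export
generateRun <- function(recipe) {
    stopifnot(inherits(recipe, "RunRecipe"))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(recipe$seed)
    cmp <- recipe$compounds
    if (nrow(cmp) > 1L) {
        mzs <- sort(cmp$mz)
        if (any(diff(mzs) < 0.005))
            warning("precursor m/z collision within 0.005 Da between compounds")
    }
    tMs1 <- seq(recipe$scanInterval, recipe$gradientLength,
                by = recipe$scanInterval)
    gauss <- function(t, rt, sigma, area) {
        y <- area * stats::dnorm(t, rt, sigma)
        apex <- area / (sigma * sqrt(2 * pi))
        y[y < apex * 1e-4] <- 0
        y
    }
    # survey-scan peak lists (long format, then split by scan)
    scanIdx <- integer(); mz <- numeric(); intensity <- numeric()
    for (i in seq_len(nrow(cmp))) {
        y <- gauss(tMs1, cmp$rt[i], cmp$sigma[i], cmp$area[i])
        keep <- which(y > 0)
        scanIdx <- c(scanIdx, keep)
        mz <- c(mz, rep(cmp$mz[i], length(keep)))
        intensity <- c(intensity, y[keep])
    }
    if (recipe$noiseLevel > 0) {
        nNoise <- 3L
        ns <- rep(seq_along(tMs1), each = nNoise)
        scanIdx <- c(scanIdx, ns)
        mz <- c(mz, stats::runif(length(ns), 50, 700))
        intensity <- c(intensity, stats::runif(length(ns), 0,
                                               recipe$noiseLevel))
    }
    surveyPeaks <- lapply(seq_along(tMs1), function(j) {
        sel <- scanIdx == j
        cbind(mz[sel], intensity[sel])
    })
    surveyAcq <- if (recipe$acquisition == "DIA") "DIA_LOW" else "MS1"
    scans <- lapply(seq_along(tMs1), function(j)
        list(rt = tMs1[j], msLevel = 1L, acquisition = surveyAcq,
             precursorMz = NA_real_, isolationWidth = NA_real_,
             peaks = surveyPeaks[[j]]))
    if (recipe$acquisition == "DDA" && nrow(cmp)) {
        topIdx <- order(-cmp$area)[seq_len(min(recipe$ddaTopN, nrow(cmp)))]
        for (i in topIdx) {
            fr <- cmp$frags[[i]]
            if (!nrow(fr)) next
            apexH <- cmp$area[i] / (cmp$sigma[i] * sqrt(2 * pi))
            scans[[length(scans) + 1L]] <- list(
                rt = cmp$rt[i] + recipe$scanInterval / 2, msLevel = 2L,
                acquisition = "DDA_MS2", precursorMz = cmp$mz[i],
                isolationWidth = 1.0,
                peaks = cbind(fr[, 1L], fr[, 2L] / 100 * apexH))
        }
    }
    if (recipe$acquisition == "DIA" && nrow(cmp)) {
        tHigh <- tMs1 + recipe$scanInterval / 2
        hIdx <- integer(); hMz <- numeric(); hInt <- numeric()
        for (i in seq_len(nrow(cmp))) {
            fr <- cmp$frags[[i]]
            if (!nrow(fr)) next
            y <- gauss(tHigh, cmp$rt[i], cmp$sigma[i], cmp$area[i])
            keep <- which(y > 0)
            for (k in seq_len(nrow(fr))) {
                hIdx <- c(hIdx, keep)
                hMz <- c(hMz, rep(fr[k, 1L], length(keep)))
                hInt <- c(hInt, fr[k, 2L] / 100 * y[keep])
            }
        }
        for (j in unique(hIdx)) {
            sel <- hIdx == j
            scans[[length(scans) + 1L]] <- list(
                rt = tHigh[j], msLevel = 1L, acquisition = "DIA_HIGH",
                precursorMz = NA_real_, isolationWidth = NA_real_,
                peaks = cbind(hMz[sel], hInt[sel]))
        }
    }
    ord <- order(vapply(scans, `[[`, numeric(1), "rt"))
    spectra <- lapply(seq_along(ord), function(k) {
        s <- scans[[ord[k]]]
        msSpectrum(scanId = k, msLevel = s$msLevel,
                 acquisition = s$acquisition, rt = s$rt,
                 polarity = recipe$polarity, peaks = s$peaks,
                 precursorMz = s$precursorMz,
                 isolationWidth = s$isolationWidth)
    })
    lcmsRun(recipe$sampleId, spectra, recipe$metadata)
}

# ---- fixtures ------------------------------------------------------------

.FIXTURE_SAMPLES <- c("80", "90", "100")
.VMSL_LBL_COMMON <- c("Quercetin", "Kaempferol", "Apigenin",
                      "Gentisic acid", "Gallic acid", "Chlorogenic acid")

#' The juice fixture: suspect lists, spectral library, run recipes
#'
#' Builds the complete synthetic study: suspect lists (a bioactivity-driven
#' subset, a literature-based list, and a virtual-metabolite list enumerated
#' from seven scaffolds — the six compounds common to the VMSL and LBL plus
#' ellagic acid, whose glucoside is the diagnostic-ion identification), the
#' MSP library (reference-standard spectra for the 17 compounds with
#' standards, experimental library spectra for the ten library-matched
#' compounds, an in-silico fragment list for ethyl gallate), the standards
#' registry, run recipes for the 80/90/100% pomegranate samples and the
#' procedure blank in both polarities and both acquisition modes, the
#' expected per-compound confidence levels, and the names of the two planted
#' blank false positives. Blank areas are one tenth of the 100% sample for
#' genuine compounds and one third for the two probes, so the five-fold rule
#' removes exactly the probes.
#'
#' @param seed base RNG seed for the run recipes.
#' @param scanInterval survey-scan spacing (minutes).
#' @param noiseLevel uniform-noise ceiling for survey scans.
#' @return A list with elements `compounds`, `bdsl`, `lbl`, `vmsl`,
#'   `suspects` (merged screening list), `library`, `standards`, `recipes`
#'   (named list, `<sample>_<polarity>_<acq>`), `expectedLevels`, `probes`.
#' @export
juiceFixture <- function(seed = 1L, scanInterval = 0.02, noiseLevel = 20) {
    cmp <- .juiceCompounds()
    probes <- .blankProbes()

    # --- suspect lists
    lblRows <- !(cmp$name %in% c("Ellagic acid", "Ellagic acid glucoside"))
    lbl <- suspectTable(
        name = cmp$name[lblRows], formula = cmp$formula[lblRows],
        adduct = cmp$adduct[lblRows], predictedRt = cmp$rtObs[lblRows],
        source = "LBL",
        referenceStandard = cmp$libraryType[lblRows] == "reference_standard")
    bdsl <- suspectTable(
        name = c(cmp$name[cmp$name == "Ellagic acid"], probes$name),
        formula = c(cmp$formula[cmp$name == "Ellagic acid"],
                    probes$formula),
        adduct = "[M-H]-", source = "BDSL")
    scaffolds <- data.frame(
        name = c(.VMSL_LBL_COMMON, "Ellagic acid"),
        formula = cmp$formula[match(c(.VMSL_LBL_COMMON, "Ellagic acid"),
                                    cmp$name)],
        stringsAsFactors = FALSE)
    vmsl <- productsToSuspects(enumerateProducts(scaffolds), "[M-H]-")
    suspects <- mergeSuspectLists(bdsl, lbl, vmsl)

    # --- MSP library and standards registry
    library <- list()
    for (i in seq_len(nrow(cmp))) {
        if (cmp$libraryType[i] %in% c("none", "diagnostic_only")) next
        if (!length(cmp$refFrags[[i]])) next
        library[[length(library) + 1L]] <- mspRecord(
            name = cmp$name[i], formula = cmp$formula[i],
            precursorMz = cmp$theorMz[i], precursorType = cmp$adduct[i],
            ionMode = cmp$polarity[i],
            retentionTime = if (!is.na(cmp$rtStd[i])) cmp$rtStd[i]
                            else cmp$rtObs[i],
            peaks = .fragMatrix(cmp$refFrags[[i]]),
            extra = c(LibraryType = cmp$libraryType[i],
                      DatabaseRef = cmp$dbRef[i]))
    }
    standards <- data.frame(
        name = cmp$name[!is.na(cmp$rtStd)],
        rt = cmp$rtStd[!is.na(cmp$rtStd)], stringsAsFactors = FALSE)

    # --- run recipes
    all <- rbind(cmp[, c("name", "expMz", "rtObs", "polarity", "pattern",
                         "baseArea")],
                 probes[, c("name", "expMz", "rtObs", "polarity", "pattern",
                            "baseArea")])
    frags <- c(lapply(cmp$sampleFrags, .fragMatrix),
               lapply(probes$sampleFrags, .fragMatrix))
    recipes <- list()
    mkCompounds <- function(pol, areas) {
        sel <- which(all$polarity == pol)
        out <- data.frame(name = all$name[sel], mz = all$expMz[sel],
                          rt = all$rtObs[sel], sigma = 0.05,
                          area = areas[sel], stringsAsFactors = FALSE)
        out$frags <- frags[sel]
        out
    }
    sampleArea <- function(sample)
        all$baseArea * vapply(all$pattern, function(p)
            .SAMPLE_MULT[[p]][[sample]], numeric(1))
    blankArea <- all$baseArea *
        ifelse(all$name %in% probes$name, 1 / 3, 1 / 10)
    gradFor <- function(pol) if (pol == "negative") 15 else 8
    k <- 0L
    for (sample in .FIXTURE_SAMPLES) for (pol in c("negative", "positive"))
        for (acq in c("DDA", "DIA")) {
            k <- k + 1L
            recipes[[sprintf("%s_%s_%s", sample, pol, acq)]] <- runRecipe(
                sampleId = sample,
                compounds = mkCompounds(pol, sampleArea(sample)),
                gradientLength = gradFor(pol),
                scanInterval = scanInterval, noiseLevel = noiseLevel,
                seed = seed + k, acquisition = acq, polarity = pol,
                metadata = list(percentLabel = sample, blank = FALSE))
        }
    for (pol in c("negative", "positive")) {
        k <- k + 1L
        recipes[[sprintf("blank_%s_DDA", pol)]] <- runRecipe(
            sampleId = "blank", compounds = mkCompounds(pol, blankArea),
            gradientLength = gradFor(pol), scanInterval = scanInterval,
            noiseLevel = noiseLevel, seed = seed + k, acquisition = "DDA",
            polarity = pol, metadata = list(blank = TRUE))
    }

    list(compounds = cmp, bdsl = bdsl, lbl = lbl, vmsl = vmsl,
         suspects = suspects, library = library, standards = standards,
         recipes = recipes,
         expectedLevels = cmp[, c("name", "level")],
         probes = probes$name)
}

#' A 734-entry bioactivity-driven suspect list
#'
#' The genuine compounds of the fixture padded with deterministic filler
#' entries to the full list size of 734 antioxidant substances; the filler
#' compounds carry valid CHNO formulas but are absent from the synthetic
#' runs. Entirely synthetic: models the schema and size of a text-mined
#' suspect list, not its content.
#'
#' @return A suspect table with 734 rows.
#' @export
bdslFull <- function() {
    cmp <- .juiceCompounds()
    n <- 734L - nrow(cmp)
    i <- seq_len(n)
    filler <- suspectTable(
        name = sprintf("Antioxidant %03d", i),
        formula = sprintf("C%dH%dN%dO%d", 6L + (i * 7L) %% 25L,
                          8L + (i * 5L) %% 30L, i %% 3L, 2L + (i * 3L) %% 12L),
        adduct = "[M-H]-", source = "BDSL")
    rbind(suspectTable(name = cmp$name, formula = cmp$formula,
                       adduct = cmp$adduct, source = "BDSL"),
          filler)
}

# ---- quantification fixture ----------------------------------------------

.quantAnalytes <- function() {
    data.frame(
        analyte = c("Abscisic acid", "Chlorogenic acid", "Citric acid",
                    "Galangin", "Gallic acid", "Phloridzin", "Quinic acid",
                    "Verbascoside", "Quercetin"),
        a = c(29407, 299437, 114212, 179124, 46623, 304319, 121371, 58119,
              71193),
        sa = c(1108, 17948, 3871, 11301, 3535, 25920, 1970, 1053, 4859),
        b = c(13932, 236799, -27802, -9729, 57556, 287534, 431844, -14120,
              51014),
        sb = c(5655, 91609, 19759, 57678, 18043, 132294, 10055, 5376,
               24802),
        r2 = c(0.994, 0.98, 0.991, 0.98, 0.98, 0.97, 0.993, 0.996, 0.992),
        c80 = c(0.28, 4.07, 203, 1.41, 5.72, 1.01, 0.75, 0.87, 13.1),
        s80 = c(0.02, 0.33, 18.9, 0.86, 0.41, 0.09, 0.09, 0.12, 0.45),
        c90 = c(NA, 1.35, 204, 0.65, 4.57, 0.65, 0.38, 0.51, 11.6),
        s90 = c(NA, 0.08, 21.2, 0.05, 0.41, 0.05, 0.04, 0.05, 0.56),
        c100 = c(NA, 0.52, 199, NA, 5.11, 0.65, NA, NA, 11),
        s100 = c(NA, 0.05, 18.4, NA, 0.47, 0.06, NA, NA, 0.48),
        stringsAsFactors = FALSE)
}

.CAL_LEVELS <- c(0.5, 1, 2.5, 5, 10)  # working solutions, mg/L
.SUB_LOQ_CONC <- 0.30                 # stand-in level for "< LOQ" cells
.SUB_LOQ_SD <- 0.02

#' Calibration series and triplicate sample responses
#'
#' For each quantified analyte, calibration responses are computed from its
#' external calibration equation at the five working-solution levels (0.5,
#' 1, 2.5, 5, 10 mg/L), optionally with seeded proportional Gaussian noise.
#' Triplicate sample responses are computed from the same equation at the
#' concentrations (c - SD, c, c + SD), so at zero noise the replicate mean
#' and standard deviation reproduce the reported concentration and SD
#' exactly. Below-LOQ entries are generated at a stand-in concentration of
#' 0.30 mg/kg.
#'
#' @param noiseFraction relative standard deviation of the calibration
#'   response noise (0 = exact collinear points).
#' @param seed RNG seed used when `noiseFraction > 0`.
#' @return list with `calibration` (analyte, conc, response), `responses`
#'   (analyte, sample, replicate, response), and `reference` (the expected
#'   concentration table with `belowLoq` flags).
#' @export
quantFixture <- function(noiseFraction = 0, seed = 1L) {
    tab <- .quantAnalytes()
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    cal <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        y <- tab$a[i] * .CAL_LEVELS + tab$b[i]
        if (noiseFraction > 0)
            y <- y + stats::rnorm(length(y), 0, noiseFraction * abs(y))
        data.frame(analyte = tab$analyte[i], conc = .CAL_LEVELS,
                   response = y, stringsAsFactors = FALSE)
    }))
    resp <- list(); ref <- list()
    for (i in seq_len(nrow(tab))) for (s in .FIXTURE_SAMPLES) {
        conc <- tab[[paste0("c", s)]][i]
        sd <- tab[[paste0("s", s)]][i]
        below <- is.na(conc)
        if (below) { conc <- .SUB_LOQ_CONC; sd <- .SUB_LOQ_SD }
        reps <- conc + c(-1, 0, 1) * sd
        resp[[length(resp) + 1L]] <- data.frame(
            analyte = tab$analyte[i], sample = s, replicate = 1:3,
            response = tab$a[i] * reps + tab$b[i], stringsAsFactors = FALSE)
        ref[[length(ref) + 1L]] <- data.frame(
            analyte = tab$analyte[i], sample = s, concentration = conc,
            sd = sd, belowLoq = below || conc < 0.5,
            stringsAsFactors = FALSE)
    }
    list(calibration = cal, responses = do.call(rbind, resp),
         reference = do.call(rbind, ref))
}
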