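#' Acquire fragmentation evidence for screened features
#'
#' For every kept feature, acquires a fragmentation-derived spectrum — the
#' DDA route for the `maaK` most abundant compounds per sample and polarity,
#' the correlation-gated DIA pseudo-spectrum otherwise (and as fallback when
#' no DDA scan matched) — and scores it against the MSP library: the best
#' cosine against experimental library entries, the best cosine against
#' reference-standard spectra, a diagnostic-ion check for suspects carrying
#' required diagnostic ions, and an in-silico support flag (at least one
#' fragment of an in-silico record matched).
#'
#' @param features kept feature table (`suspect`, `sample`, `rtApex`,
#'   `rtStart`, `rtEnd`, `area`).
#' @param runs named list of [Run-class], keyed `<sample>_<polarity>_<acq>`
#'   with acq in DDA/DIA.
#' @param suspects merged suspect table.
#' @param library list of [MspRecord-class]; records may carry a
#'   `LibraryType` extra key (`reference_standard`, `experimental_library`,
#'   `in_silico`); untyped records count as experimental library entries.
#' @param maaK number of most-abundant compounds routed to DDA.
#' @param mzTol precursor tolerance (Da).
#' @param fragTol fragment tolerance (Da).
#' @param diaMinCorr DIA pseudo-spectrum correlation gate.
#' @return data.frame with one row per feature: `suspect`, `sample`,
#'   `route`, `libraryScore`, `referenceScore`, `nMatched`, `matchedMzs`,
#'   `diagnosticOk`, `inSilicoOk`.
#' @export
matchFeatures <- function(features, runs, suspects, library, maaK = 15,
                          mzTol = 0.005, fragTol = 0.01, diaMinCorr = 0.8) {
    out <- data.frame(suspect = character(), sample = character(),
                      route = character(), libraryScore = numeric(),
                      referenceScore = numeric(), nMatched = integer(),
                      matchedMzs = character(), diagnosticOk = logical(),
                      inSilicoOk = logical(), stringsAsFactors = FALSE)
    if (!nrow(features)) return(out)
    libType <- vapply(library, function(r)
        unname(r@extra["LibraryType"]) %||NA% "experimental_library", "")
    libNames <- vapply(library, function(r) tolower(r@name), "")
    pol <- suspects$polarity[match(features$suspect, suspects$name)]
    ddaSet <- rep(FALSE, nrow(features))
    for (grp in split(seq_len(nrow(features)),
                      paste(features$sample, pol))) {
        top <- selectMostAbundant(cbind(features[grp, , drop = FALSE],
                                        idx = grp), maaK)
        ddaSet[top$idx] <- TRUE
    }
    rows <- vector("list", nrow(features))
    for (i in seq_len(nrow(features))) {
        f <- features[i, ]
        si <- match(f$suspect, suspects$name)
        theor <- suspects$precursorMz[si]
        ddaRun <- runs[[sprintf("%s_%s_DDA", f$sample, pol[i])]]
        diaRun <- runs[[sprintf("%s_%s_DIA", f$sample, pol[i])]]
        spec <- NULL; route <- NA_character_
        if (ddaSet[i] && !is.null(ddaRun)) {
            s <- selectDdaSpectrum(ddaRun, theor,
                                   c(f$rtStart, f$rtEnd), mzTol)
            if (!is.null(s)) { spec <- s@peaks; route <- "DDA" }
        }
        if (is.null(spec) && !is.null(diaRun)) {
            eic <- extractEic(diaRun, theor, mzTol)
            ps <- diaPseudoSpectrum(diaRun, eic, f, diaMinCorr, fragTol)
            if (nrow(ps)) { spec <- ps; route <- "DIA" }
        }
        libScore <- NA_real_; refScore <- NA_real_
        nMatched <- 0L; matched <- numeric(); inSilico <- NA
        if (!is.null(spec) && nrow(spec)) {
            hits <- which(libNames == tolower(f$suspect))
            for (h in hits) {
                cs <- cosineScore(spec, library[[h]], fragTol)
                if (libType[h] == "reference_standard") {
                    if (is.na(refScore) || cs$score > refScore) {
                        refScore <- cs$score
                    }
                } else if (libType[h] == "in_silico") {
                    inSilico <- isTRUE(inSilico) || cs$nMatched >= 1L
                } else if (is.na(libScore) || cs$score > libScore) {
                    libScore <- cs$score
                }
                if (cs$nMatched > nMatched) {
                    nMatched <- cs$nMatched
                    matched <- cs$matchedMzs
                }
            }
        }
        ions <- suspects$diagnosticIons[[si]]
        diagOk <- NA
        if (!is.null(ions) && nrow(ions) && any(ions$required)) {
            diagOk <- if (is.null(spec) || !nrow(spec)) FALSE
                      else diagnosticIonCheck(
                          spec, unique(ions$mz[ions$required]), fragTol)$ok
        }
        rows[[i]] <- data.frame(
            suspect = f$suspect, sample = f$sample, route = route,
            libraryScore = libScore, referenceScore = refScore,
            nMatched = nMatched,
            matchedMzs = paste(sprintf("%.4f", matched), collapse = ";"),
            diagnosticOk = diagOk, inSilicoOk = inSilico,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Screen, blank-filter, match and annotate a set of runs
#'
#' The full qualitative workflow on in-memory objects: targeted MS1
#' screening of each sample's survey scans against the merged suspect list,
#' five-fold procedure-blank filtering, fragmentation matching (DDA for the
#' `maaK` most abundant compounds, DIA otherwise) and confidence-level
#' assignment.
#'
#' @param runs named list of [Run-class] keyed `<sample>_<polarity>_<acq>`;
#'   the blank's keys start with `blank_`.
#' @param suspects merged suspect table.
#' @param library list of [MspRecord-class].
#' @param standards data.frame (`name`, `rt`).
#' @param samples sample ids to screen (default: all non-blank keys).
#' @param maaK,mzTol,fragTol,diaMinCorr see [matchFeatures()].
#' @param blankRatio five-fold rule threshold.
#' @param minHeightSnr see [detectPeaks()].
#' @param ... thresholds forwarded to [assignLevel()].
#' @return list with `features` (pre-filter), `kept`, `excluded`,
#'   `matchReports`, `annotations`, `byCompound`, `summary`.
#' @export
screenAndAnnotate <- function(runs, suspects, library, standards,
                              samples = NULL, maaK = 15, mzTol = 0.005,
                              fragTol = 0.01, diaMinCorr = 0.8,
                              blankRatio = 5, minHeightSnr = 3, ...) {
    keys <- names(runs)
    sampleOf <- sub("_(negative|positive)_(DDA|DIA)$", "", keys)
    if (is.null(samples))
        samples <- setdiff(unique(sampleOf), "blank")
    feats <- list(); blankFeats <- list()
    for (k in seq_along(runs)) {
        if (!grepl("_DDA$", keys[k])) next
        ft <- screenRun(runs[[k]], suspects, mzTol, minHeightSnr)
        if (sampleOf[k] == "blank") blankFeats[[length(blankFeats) + 1L]] <- ft
        else if (sampleOf[k] %in% samples) feats[[length(feats) + 1L]] <- ft
    }
    features <- do.call(rbind, feats)
    blank <- if (length(blankFeats)) do.call(rbind, blankFeats)
             else data.frame(suspect = character(), rtApex = numeric(),
                             area = numeric())
    kept <- list(); excluded <- list()
    for (s in unique(features$sample)) {
        bf <- blankFilter(features[features$sample == s, , drop = FALSE],
                          blank, blankRatio)
        kept[[s]] <- bf$kept
        excluded[[s]] <- bf$excluded
    }
    kept <- do.call(rbind, kept)
    excluded <- do.call(rbind, excluded)
    rownames(kept) <- rownames(excluded) <- NULL
    matchReports <- matchFeatures(kept, runs, suspects, library, maaK,
                                  mzTol, fragTol, diaMinCorr)
    ann <- annotateDataset(kept, matchReports, suspects, standards,
                           mzTol, ...)
    list(features = features, kept = kept, excluded = excluded,
         matchReports = matchReports, annotations = ann$annotations,
         byCompound = ann$byCompound, summary = ann$summary)
}

#' Run the full juice study end-to-end
#'
#' Generates the synthetic runs of [juiceFixture()] and executes
#' [screenAndAnnotate()] on them; the canonical end-to-end exercise of the
#' whole pipeline.
#'
#' @param fixture a [juiceFixture()] (built with default seed when absent).
#' @param ... forwarded to [screenAndAnnotate()].
#' @return The [screenAndAnnotate()] result, plus `intersection` (the
#'   VMSL/LBL cross-list confirmation) and `fixture`.
#' @export
runJuicePipeline <- function(fixture = juiceFixture(), ...) {
    runs <- lapply(fixture$recipes, generateRun)
    res <- screenAndAnnotate(runs, fixture$suspects, fixture$library,
                             fixture$standards, ...)
    res$intersection <- intersectSuspectLists(fixture$vmsl, fixture$lbl)
    res$fixture <- fixture
    res
}

# ---- file-based pipeline -------------------------------------------------

#' Pipeline configuration
#'
#' @param runFiles character vector of run files (`.json` in the package
#'   run format, or `.mzML`); keys are derived from each run's sample id,
#'   polarity and acquisition mode.
#' @param suspectCsvs character vector of suspect-list CSV paths (merged).
#' @param mspFile MSP library path (optional).
#' @param standardsCsv CSV with columns `name`, `rt` (optional).
#' @param calibrationCsv,responsesCsv quantification inputs (optional).
#' @param outDir output directory.
#' @param mzTol,fragTol,diaMinCorr,blankRatio,maaK,rtTol,level1ScoreMin,score2a,loq,seed
#'   tolerances and gates; defaults are the package-wide values
#'   (+/-0.005 Da precursor window, 0.01 Da fragment window, 0.8 DIA
#'   correlation, five-fold blank rule, 0.7 library gate, 0.6 level-1 gate,
#'   0.5 mg/kg LOQ).
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(runFiles, suspectCsvs, mspFile = NULL,
                           standardsCsv = NULL, calibrationCsv = NULL,
                           responsesCsv = NULL, outDir = ".",
                           mzTol = 0.005, fragTol = 0.01, diaMinCorr = 0.8,
                           blankRatio = 5, maaK = 15, rtTol = 0.5,
                           level1ScoreMin = 0.6, score2a = 0.7, loq = 0.5,
                           seed = 1L) {
    stopifnot(mzTol > 0, fragTol > 0, diaMinCorr > 0, blankRatio > 0,
              score2a >= 0, score2a <= 1, level1ScoreMin >= 0,
              level1ScoreMin <= 1, loq >= 0)
    structure(as.list(environment()), class = "PipelineConfig")
}

.readRunAuto <- function(path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) readRunJson(path)
    else readMzml(path)
}

.runKey <- function(run) {
    acq <- if (any(vapply(spectraOf(run), function(s)
        s@acquisition %in% c("DIA_LOW", "DIA_HIGH"), logical(1)))) "DIA"
        else "DDA"
    sprintf("%s_%s_%s", sampleId(run), runPolarity(run), acq)
}

#' Execute the file-based screening pipeline
#'
#' Reads every input declared in the config, runs
#' enumeration-free screening (suspect lists are consumed as given), blank
#' filtering, fragmentation matching, annotation and (when calibration
#' inputs are present) quantification, and writes the result tables
#' (`features.tsv`, `exclusions.tsv`, `matches.tsv`, `annotations.tsv`,
#' `quant.tsv`), a `summary.json` with the level histogram, and a
#' `manifest.json` echoing the configuration, input checksums and package
#' version. Deterministic for a fixed config and inputs.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, the [screenAndAnnotate()] result (plus `quant` when
#'   quantification ran).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    runs <- lapply(config$runFiles, .readRunAuto)
    names(runs) <- vapply(runs, .runKey, "")
    suspects <- mergeSuspectLists(lapply(config$suspectCsvs, readSuspectCsv))
    library <- if (!is.null(config$mspFile)) readMsp(config$mspFile)
               else list()
    standards <- if (!is.null(config$standardsCsv))
        utils::read.csv(config$standardsCsv, stringsAsFactors = FALSE)
    else data.frame(name = character(), rt = numeric())
    res <- screenAndAnnotate(
        runs, suspects, library, standards, maaK = config$maaK,
        mzTol = config$mzTol, fragTol = config$fragTol,
        diaMinCorr = config$diaMinCorr, blankRatio = config$blankRatio,
        rtTol = config$rtTol, level1ScoreMin = config$level1ScoreMin,
        score2a = config$score2a)
    if (!is.null(config$calibrationCsv) && !is.null(config$responsesCsv)) {
        curves <- readCalibrationCsv(config$calibrationCsv)
        res$quant <- quantifySamples(curves,
                                     readResponsesCsv(config$responsesCsv),
                                     loq = config$loq)
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, file) utils::write.table(
        df, file.path(config$outDir, file), sep = "\t", row.names = FALSE,
        quote = FALSE)
    wtsv(res$features, "features.tsv")
    wtsv(res$excluded, "exclusions.tsv")
    wtsv(res$matchReports, "matches.tsv")
    wtsv(res$annotations, "annotations.tsv")
    if (!is.null(res$quant)) wtsv(res$quant, "quant.tsv")
    jsonlite::write_json(
        list(nCompounds = nrow(res$byCompound),
             levelHistogram = as.list(res$summary),
             nExcluded = nrow(res$excluded)),
        file.path(config$outDir, "summary.json"), auto_unbox = TRUE)
    inputs <- c(config$runFiles, config$suspectCsvs, config$mspFile,
                config$standardsCsv, config$calibrationCsv,
                config$responsesCsv)
    jsonlite::write_json(
        list(package = "hrmscreen",
             version = as.character(utils::packageVersion("hrmscreen")),
             config = config[!vapply(config, is.null, logical(1))],
             inputs = as.list(tools::md5sum(inputs))),
        file.path(config$outDir, "manifest.json"), auto_unbox = TRUE)
    invisible(res)
}
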