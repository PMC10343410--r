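#' Construct a Spectrum
#'
#' @param scanId integer scan number.
#' @param msLevel 1 or 2.
#' @param acquisition "MS1", "DDA_MS2", "DIA_LOW" or "DIA_HIGH".
#' @param rt retention time (minutes).
#' @param polarity "positive" or "negative".
#' @param peaks two-column matrix/data.frame (mz, intensity); sorted by m/z
#'   on construction. Centroided data only.
#' @param precursorMz,isolationWidth DDA_MS2 only.
#' @return A [Spectrum-class].
#' @export
msSpectrum <- function(scanId, msLevel, acquisition, rt, polarity, peaks,
                     precursorMz = NA_real_, isolationWidth = NA_real_) {
    pk <- matrix(as.numeric(as.matrix(peaks)), ncol = 2)
    colnames(pk) <- c("mz", "intensity")
    if (nrow(pk)) pk <- pk[order(pk[, 1L]), , drop = FALSE]
    new("Spectrum", scanId = as.integer(scanId),
        msLevel = as.integer(msLevel), acquisition = acquisition,
        rt = as.numeric(rt), polarity = polarity,
        precursorMz = as.numeric(precursorMz),
        isolationWidth = as.numeric(isolationWidth), peaks = pk)
}

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum #%d %s rt=%.3f min, %d peaks%s\n", object@scanId,
                object@acquisition, object@rt, nrow(object@peaks),
                if (!is.na(object@precursorMz))
                    sprintf(", precursor %.4f", object@precursorMz) else ""))
})

#' Construct an LC-MS Run
#'
#' @param sampleId sample identifier.
#' @param spectra list of [Spectrum-class], ordered by rt.
#' @param metadata named list (e.g. `list(percentLabel = "80", blank = FALSE)`).
#' @return A [Run-class].
#' @export
lcmsRun <- function(sampleId, spectra = list(), metadata = list()) {
    new("Run", sampleId = sampleId, spectra = spectra, metadata = metadata)
}

setMethod("show", "Run", function(object) {
    acq <- table(vapply(object@spectra, function(s) s@acquisition,
                        character(1)))
    cat(sprintf("Run '%s': %d spectra (%s)\n", object@sampleId,
                length(object@spectra),
                paste(names(acq), acq, sep = "=", collapse = ", ")))
})

#' Run and spectrum accessors
#'
#' @param run A [Run-class].
#' @return `spectraOf`: list of [Spectrum-class]; `sampleId`: character;
#'   `runMetadata`: list; `runPolarity`: character;
#'   `totalIonCurrent`: the summed intensity over all scans.
#' @export
spectraOf <- function(run) run@spectra

#' @rdname spectraOf
#' @export
sampleId <- function(run) run@sampleId

#' @rdname spectraOf
#' @export
runMetadata <- function(run) run@metadata

#' @rdname spectraOf
#' @export
runPolarity <- function(run) {
    if (!length(run@spectra)) return(NA_character_)
    run@spectra[[1L]]@polarity
}

#' @rdname spectraOf
#' @export
totalIonCurrent <- function(run)
    sum(vapply(run@spectra, function(s) sum(s@peaks[, 2L]), numeric(1)))

#' Peak matrix of a spectrum
#' @param x A [Spectrum-class].
#' @return Two-column numeric matrix (mz, intensity).
#' @export
peaksOf <- function(x) x@peaks

# ---- JSON run format ----------------------------------------------------

.RUN_SCHEMA <- "hrmscreen-run/1"

#' Read / write the package JSON run format
#'
#' A compact, dependency-free serialization of a [Run-class] used for
#' fixtures and interchange; lossless (write-then-read is the identity, and
#' the total ion current is invariant under round-trips). The schema is
#' versioned; files with a different schema tag are rejected, as are files
#' whose scans are not rt-ordered.
#'
#' @param path file path.
#' @param run A [Run-class].
#' @return `readRunJson` returns a [Run-class]; `writeRunJson` invisibly
#'   returns `path`.
#' @export
readRunJson <- function(path) {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
    if (!identical(x$schema, .RUN_SCHEMA))
        stop("schema mismatch: expected '", .RUN_SCHEMA, "', got '",
             x$schema, "'")
    spectra <- lapply(x$spectra, function(s) {
        pk <- if (length(s$peaks))
            do.call(rbind, lapply(s$peaks, as.numeric))
        else matrix(numeric(), 0, 2)
        msSpectrum(scanId = s$scanId, msLevel = s$msLevel,
                 acquisition = s$acquisition, rt = s$rt,
                 polarity = x$polarity, peaks = pk,
                 precursorMz = s$precursorMz %||NA% NA_real_,
                 isolationWidth = s$isolationWidth %||NA% NA_real_)
    })
    lcmsRun(x$sampleId, spectra, as.list(x$metadata))
}

#' @rdname readRunJson
#' @export
writeRunJson <- function(run, path) {
    spectra <- lapply(run@spectra, function(s) {
        out <- list(scanId = s@scanId, msLevel = s@msLevel,
                    acquisition = s@acquisition, rt = s@rt,
                    peaks = unname(apply(s@peaks, 1L, as.numeric,
                                         simplify = FALSE)))
        if (!is.na(s@precursorMz)) out$precursorMz <- s@precursorMz
        if (!is.na(s@isolationWidth)) out$isolationWidth <- s@isolationWidth
        out
    })
    jsonlite::write_json(
        list(schema = .RUN_SCHEMA, sampleId = run@sampleId,
             polarity = runPolarity(run), metadata = run@metadata,
             spectra = spectra),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

# ---- mzML ---------------------------------------------------------------

#' Read a centroided mzML file
#'
#' Loads an mzML file through Bioconductor's mzR backend and labels each scan:
#' MS level 2 with a precursor becomes `DDA_MS2`; MS level 2 without a
#' precursor (the common bbCID convention), or MS level 1 whose collision
#' energy matches `diaHighEnergy`, becomes `DIA_HIGH` (broadband all-ion
#' fragmentation); remaining MS1 scans are `DIA_LOW` when the run contains
#' high-energy scans and `MS1` otherwise. Profile-mode data and
#' mixed-polarity files are rejected.
#'
#' @param path mzML file path.
#' @param sampleId optional sample identifier (default: file name).
#' @param diaHighEnergy collision energies (eV) labelling an MS1 scan as a
#'   high-energy DIA scan; instrument annotation schemes vary, so the mapping
#'   is configurable. Default: any energy > 15 eV.
#' @return A [Run-class].
#' @export
readMzml <- function(path, sampleId = NULL,
                     diaHighEnergy = function(ce) !is.na(ce) & ce > 15) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("the 'mzR' package is required to read mzML files")
    h <- NULL
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    h <- mzR::header(fh)
    if (!nrow(h)) return(lcmsRun(sampleId %||% basename(path)))
    if ("centroided" %in% names(h) &&
        any(!is.na(h$centroided) & !h$centroided))
        stop("profile-mode spectra found: centroided data required")
    pol <- unique(h$polarity[h$polarity %in% c(0, 1)])
    if (length(pol) > 1L) stop("mixed polarity runs are not supported")
    polarity <- if (length(pol) && pol == 0) "negative" else "positive"
    pks <- mzR::peaks(fh)
    if (is.matrix(pks)) pks <- list(pks)
    hasPrec <- !is.na(h$precursorMZ) & h$precursorMZ > 0
    isHigh <- (h$msLevel >= 2L & !hasPrec) |
        (h$msLevel == 1L & diaHighEnergy(h$collisionEnergy))
    anyDiaHigh <- any(isHigh)
    spectra <- vector("list", nrow(h))
    for (i in seq_len(nrow(h))) {
        lvl <- h$msLevel[i]
        acq <- if (lvl >= 2L && hasPrec[i]) "DDA_MS2"
               else if (isHigh[i]) "DIA_HIGH"
               else if (anyDiaHigh) "DIA_LOW" else "MS1"
        spectra[[i]] <- msSpectrum(
            scanId = h$acquisitionNum[i], msLevel = min(lvl, 2L),
            acquisition = acq, rt = h$retentionTime[i] / 60,
            polarity = polarity, peaks = pks[[i]],
            precursorMz = if (acq == "DDA_MS2") h$precursorMZ[i]
                          else NA_real_,
            isolationWidth = if (acq == "DDA_MS2" &&
                                 "isolationWindowUpperOffset" %in% names(h))
                h$isolationWindowUpperOffset[i] * 2 else NA_real_)
    }
    ord <- order(vapply(spectra, function(s) s@rt, numeric(1)))
    lcmsRun(sampleId %||% basename(path), spectra[ord])
}

#' Write a Run to mzML
#'
#' Serializes a [Run-class] through mzR's mzML writer; DIA high-energy scans
#' are written as precursor-less MS2 scans (the bbCID convention), which
#' [readMzml()]'s label inference recovers as `DIA_HIGH`.
#'
#' @param run A [Run-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMzml <- function(run, path) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("the 'mzR' package is required to write mzML files")
    sp <- run@spectra
    n <- length(sp)
    pol <- if (identical(runPolarity(run), "negative")) 0L else 1L
    hdr <- data.frame(
        seqNum = seq_len(n),
        acquisitionNum = vapply(sp, function(s) s@scanId, integer(1)),
        msLevel = vapply(sp, function(s)
            if (s@acquisition %in% c("DDA_MS2", "DIA_HIGH")) 2L else 1L,
            integer(1)),
        polarity = pol,
        peaksCount = vapply(sp, function(s) nrow(s@peaks), integer(1)),
        totIonCurrent = vapply(sp, function(s) sum(s@peaks[, 2L]),
                               numeric(1)),
        retentionTime = vapply(sp, function(s) s@rt * 60, numeric(1)),
        basePeakMZ = vapply(sp, function(s)
            if (nrow(s@peaks)) s@peaks[which.max(s@peaks[, 2L]), 1L]
            else 0, numeric(1)),
        basePeakIntensity = vapply(sp, function(s)
            if (nrow(s@peaks)) max(s@peaks[, 2L]) else 0, numeric(1)),
        collisionEnergy = vapply(sp, function(s)
            if (s@acquisition %in% c("DIA_HIGH", "DDA_MS2")) 30 else 0,
            numeric(1)),
        ionisationEnergy = 0,
        lowMZ = vapply(sp, function(s)
            if (nrow(s@peaks)) min(s@peaks[, 1L]) else 0, numeric(1)),
        highMZ = vapply(sp, function(s)
            if (nrow(s@peaks)) max(s@peaks[, 1L]) else 0, numeric(1)),
        precursorScanNum = 0L,
        precursorMZ = vapply(sp, function(s)
            if (is.na(s@precursorMz)) 0 else s@precursorMz, numeric(1)),
        precursorCharge = vapply(sp, function(s)
            if (s@acquisition == "DDA_MS2") {
                if (pol == 0L) -1L else 1L
            } else 0L, integer(1)),
        precursorIntensity = 0,
        mergedScan = 0L, mergedResultScanNum = 0L,
        mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
        injectionTime = 0, filterString = NA_character_,
        spectrumId = sprintf("scan=%d", seq_len(n)),
        centroided = TRUE,
        ionMobilityDriftTime = NA_real_,
        isolationWindowTargetMZ = vapply(sp, function(s)
            if (is.na(s@precursorMz)) NA_real_ else s@precursorMz,
            numeric(1)),
        isolationWindowLowerOffset = vapply(sp, function(s)
            if (is.na(s@isolationWidth)) NA_real_ else s@isolationWidth / 2,
            numeric(1)),
        isolationWindowUpperOffset = vapply(sp, function(s)
            if (is.na(s@isolationWidth)) NA_real_ else s@isolationWidth / 2,
            numeric(1)),
        scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
        stringsAsFactors = FALSE)
    pks <- lapply(sp, function(s) {
        m <- s@peaks
        colnames(m) <- c("mz", "intensity")
        m
    })
    mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
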