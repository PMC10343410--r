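#' @import methods
NULL

#' Molecular formula
#'
#' An elemental composition: a named integer vector of element counts over the
#' embedded monoisotopic mass table. Zero-count elements are dropped at
#' construction; counts are therefore always >= 1 (the empty formula is the
#' identity of formula addition and has mass 0).
#'
#' @slot counts Named integer vector, element symbol -> count.
#' @seealso [parseFormula()], [monoisotopicMass()], [formulaAdd()]
#' @export
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
    cnt <- object@counts
    if (length(cnt) == 0L) return(TRUE)
    if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
        return("all counts must be named by element symbols")
    unknown <- setdiff(names(cnt), names(.ELEMENT_MASSES))
    if (length(unknown))
        return(paste0("unknown element symbol(s): ",
                      paste(unknown, collapse = ", ")))
    if (anyDuplicated(names(cnt)))
        return("duplicated element symbols")
    if (any(is.na(cnt)) || any(cnt < 1L))
        return("all element counts must be >= 1")
    TRUE
})

#' A single centroided mass spectrum
#'
#' One acquisition event of an LC-MS run: a centroided peak list with retention
#' time, MS level and an acquisition label distinguishing survey scans
#' (`"MS1"`), data-dependent fragment scans (`"DDA_MS2"`, which carry a
#' precursor m/z and isolation width) and broadband data-independent scans
#' (`"DIA_LOW"` survey / `"DIA_HIGH"` all-ion fragmentation, no precursor).
#'
#' @slot scanId integer scan number.
#' @slot msLevel integer, 1 or 2.
#' @slot acquisition one of "MS1", "DDA_MS2", "DIA_LOW", "DIA_HIGH".
#' @slot rt retention time in minutes.
#' @slot polarity "positive" or "negative".
#' @slot precursorMz precursor m/z (Da); `NA` unless acquisition is DDA_MS2.
#' @slot isolationWidth isolation width (Da); `NA` unless DDA_MS2.
#' @slot peaks two-column numeric matrix (mz, intensity), sorted by mz.
#' @export
setClass("Spectrum", representation(
    scanId = "integer",
    msLevel = "integer",
    acquisition = "character",
    rt = "numeric",
    polarity = "character",
    precursorMz = "numeric",
    isolationWidth = "numeric",
    peaks = "matrix"
))

.ACQ_LABELS <- c("MS1", "DDA_MS2", "DIA_LOW", "DIA_HIGH")

setValidity("Spectrum", function(object) {
    msgs <- character()
    if (!object@acquisition %in% .ACQ_LABELS)
        msgs <- c(msgs, paste("acquisition must be one of",
                              paste(.ACQ_LABELS, collapse = "/")))
    if (!object@msLevel %in% c(1L, 2L))
        msgs <- c(msgs, "msLevel must be 1 or 2")
    if (is.na(object@rt) || object@rt < 0)
        msgs <- c(msgs, "rt must be >= 0")
    if (!object@polarity %in% c("positive", "negative"))
        msgs <- c(msgs, "polarity must be 'positive' or 'negative'")
    pk <- object@peaks
    if (ncol(pk) != 2L)
        msgs <- c(msgs, "peaks must be a two-column (mz, intensity) matrix")
    else if (nrow(pk) > 1L && is.unsorted(pk[, 1L]))
        msgs <- c(msgs, "peaks must be sorted by m/z")
    if (identical(object@acquisition, "DDA_MS2") && is.na(object@precursorMz))
        msgs <- c(msgs, "DDA_MS2 spectra require a precursorMz")
    if (identical(object@acquisition, "DIA_HIGH") && !is.na(object@precursorMz))
        msgs <- c(msgs, "DIA_HIGH spectra must not carry a precursorMz")
    if (length(msgs)) msgs else TRUE
})

#' An LC-MS run
#'
#' A time-ordered sequence of [Spectrum-class] scans from one injection of one
#' sample in one polarity, with free-form metadata (e.g. the pomegranate
#' percentage label or a procedure-blank flag).
#'
#' @slot sampleId sample identifier.
#' @slot spectra list of [Spectrum-class], non-decreasing in rt.
#' @slot metadata named list.
#' @export
setClass("Run", representation(
    sampleId = "character",
    spectra = "list",
    metadata = "list"
))

setValidity("Run", function(object) {
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        return("sampleId must be a single non-empty string")
    sp <- object@spectra
    if (length(sp)) {
        if (!all(vapply(sp, is, logical(1), class2 = "Spectrum")))
            return("spectra must all be Spectrum objects")
        rts <- vapply(sp, function(s) s@rt, numeric(1))
        if (is.unsorted(rts))
            return("spectra must be ordered by non-decreasing rt")
        pol <- unique(vapply(sp, function(s) s@polarity, character(1)))
        if (length(pol) > 1L)
            return("a Run must have a single polarity")
    }
    TRUE
})

#' An MSP spectral-database record
#'
#' One entry of a plain-text MSP library: compound name, formula, precursor
#' m/z and adduct label, ion mode, optional retention time, and the reference
#' fragment peak list. Unknown MSP keys are preserved verbatim in `extra` so
#' third-party files round-trip untouched.
#'
#' @slot name compound name.
#' @slot formula formula string (Hill order).
#' @slot precursorMz precursor m/z (Da).
#' @slot precursorType adduct label, e.g. "[M-H]-".
#' @slot ionMode "positive" or "negative".
#' @slot retentionTime minutes, `NA` if absent.
#' @slot peaks two-column numeric matrix (mz, intensity), sorted by mz.
#' @slot extra named character vector of unrecognized key/value pairs.
#' @export
setClass("MspRecord", representation(
    name = "character",
    formula = "character",
    precursorMz = "numeric",
    precursorType = "character",
    ionMode = "character",
    retentionTime = "numeric",
    peaks = "matrix",
    extra = "character"
))

setValidity("MspRecord", function(object) {
    pk <- object@peaks
    if (ncol(pk) != 2L)
        return("peaks must be a two-column (mz, intensity) matrix")
    if (nrow(pk)) {
        if (is.unsorted(pk[, 1L])) return("peaks must be sorted by m/z")
        if (any(pk[, 2L] <= 0)) return("peak intensities must be > 0")
    }
    TRUE
})
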