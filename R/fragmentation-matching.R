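.peakMatrix <- function(x) {
    if (is(x, "Spectrum") || is(x, "MspRecord")) return(x@peaks)
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.null(x)) return(matrix(numeric(), 0, 2))
    stopifnot(is.matrix(x), ncol(x) == 2L)
    x[order(x[, 1L]), , drop = FALSE]
}

#' Pair peaks of two centroided spectra
#'
#' Greedy one-to-one nearest-neighbour pairing: candidate pairs within
#' `tolDa` are accepted in order of increasing |delta m/z|, each peak used at
#' most once. Deterministic; on well-separated peak lists this equals the
#' optimal assignment.
#'
#' @param query,library two-column (mz, intensity) matrices, [Spectrum-class]
#'   or [MspRecord-class] objects.
#' @param tolDa pairing tolerance (Da), default 0.01.
#' @return list with `pairs` (data.frame queryIdx, libraryIdx, queryMz,
#'   libraryMz, deltaMz), `unmatchedQuery` and `unmatchedLibrary` (integer
#'   indices).
#' @export
matchPeaks <- function(query, library, tolDa = 0.01) {
    q <- .peakMatrix(query)
    l <- .peakMatrix(library)
    cand <- NULL
    if (nrow(q) && nrow(l)) {
        d <- outer(q[, 1L], l[, 1L], "-")
        hit <- which(abs(d) <= tolDa, arr.ind = TRUE)
        if (nrow(hit))
            cand <- data.frame(qi = hit[, 1L], li = hit[, 2L],
                               delta = d[hit])
    }
    pairs <- data.frame(queryIdx = integer(), libraryIdx = integer(),
                        queryMz = numeric(), libraryMz = numeric(),
                        deltaMz = numeric())
    if (!is.null(cand)) {
        cand <- cand[order(abs(cand$delta), cand$qi, cand$li), , drop = FALSE]
        usedQ <- logical(nrow(q)); usedL <- logical(nrow(l))
        for (i in seq_len(nrow(cand))) {
            qi <- cand$qi[i]; li <- cand$li[i]
            if (usedQ[qi] || usedL[li]) next
            usedQ[qi] <- TRUE; usedL[li] <- TRUE
            pairs <- rbind(pairs, data.frame(
                queryIdx = qi, libraryIdx = li,
                queryMz = q[qi, 1L], libraryMz = l[li, 1L],
                deltaMz = cand$delta[i]))
        }
    }
    list(pairs = pairs,
         unmatchedQuery = setdiff(seq_len(nrow(q)), pairs$queryIdx),
         unmatchedLibrary = setdiff(seq_len(nrow(l)), pairs$libraryIdx))
}

#' Cosine similarity between two spectra
#'
#' Plain intensity cosine (no m/z weighting): the normalized dot product of
#' the matched intensity pairs, with unmatched peaks contributing only to the
#' norms. Symmetric under argument swap, equal to 1 for identical spectra,
#' invariant to scaling either spectrum by a positive constant, and 0 when no
#' peaks match.
#'
#' @inheritParams matchPeaks
#' @return list with `score` in [0, 1], `nMatched`, and `matchedMzs` (query
#'   m/z values of the matched pairs).
#' @export
cosineScore <- function(query, library, tolDa = 0.01) {
    q <- .peakMatrix(query)
    l <- .peakMatrix(library)
    if (!nrow(q) || !nrow(l)) {
        warning("empty spectrum: cosine score is 0")
        return(list(score = 0, nMatched = 0L, matchedMzs = numeric()))
    }
    m <- matchPeaks(q, l, tolDa)
    if (!nrow(m$pairs))
        return(list(score = 0, nMatched = 0L, matchedMzs = numeric()))
    dot <- sum(q[m$pairs$queryIdx, 2L] * l[m$pairs$libraryIdx, 2L])
    score <- dot / (sqrt(sum(q[, 2L]^2)) * sqrt(sum(l[, 2L]^2)))
    list(score = min(score, 1), nMatched = nrow(m$pairs),
         matchedMzs = m$pairs$queryMz)
}

#' Select a DDA fragment spectrum for a precursor
#'
#' Among the run's DDA_MS2 scans whose precursor lies within `tolDa` of
#' `precursorMz` and whose RT falls inside `rtWindow`, returns the scan whose
#' RT is nearest the window centre (earlier scan wins ties); `NULL` when no
#' scan qualifies.
#'
#' @param run A [Run-class] containing DDA_MS2 scans.
#' @param precursorMz target precursor m/z (Da).
#' @param rtWindow length-2 numeric `(min, max)` in minutes.
#' @param tolDa precursor matching tolerance (Da).
#' @return A [Spectrum-class] or `NULL`.
#' @export
selectDdaSpectrum <- function(run, precursorMz, rtWindow, tolDa = 0.005) {
    sp <- spectraOf(run)
    cand <- Filter(function(s)
        s@acquisition == "DDA_MS2" &&
        abs(s@precursorMz - precursorMz) <= tolDa &&
        s@rt >= rtWindow[1L] && s@rt <= rtWindow[2L], sp)
    if (!length(cand)) return(NULL)
    centre <- mean(rtWindow)
    d <- vapply(cand, function(s) abs(s@rt - centre), numeric(1))
    cand[[which.min(d)]]
}

#' Correlation-gated DIA pseudo-spectrum
#'
#' A documented stand-in for full DIA spectral deconvolution: fragment m/z
#' bins observed in the DIA high-energy scans inside the feature's RT bounds
#' are retained iff (i) the Pearson correlation between the fragment's
#' high-energy trace and the precursor EIC is at least `minCorr` and (ii) the
#' fragment trace apex lies within `apexTol` minutes of the feature apex.
#' The reported intensity is the fragment trace apex.
#'
#' @param run A [Run-class] containing DIA_HIGH scans.
#' @param precursorEic the precursor `"EIC"` (from [extractEic()] on the
#'   DIA_LOW trace).
#' @param feature one feature row (needs `rtStart`, `rtEnd`, `rtApex`).
#' @param minCorr minimum fragment/precursor trace correlation.
#' @param tolDa fragment m/z binning width (Da).
#' @param apexTol maximum fragment-vs-feature apex RT offset (minutes).
#' @return two-column (mz, intensity) matrix, possibly empty.
#' @export
diaPseudoSpectrum <- function(run, precursorEic, feature, minCorr = 0.8,
                              tolDa = 0.01, apexTol = 0.1) {
    sp <- spectraOf(run)
    high <- Filter(function(s) s@acquisition == "DIA_HIGH", sp)
    if (!length(high)) stop("run has no DIA_HIGH scans")
    rts <- vapply(high, function(s) s@rt, numeric(1))
    inb <- rts >= feature$rtStart & rts <= feature$rtEnd
    high <- high[inb]
    rts <- rts[inb]
    empty <- matrix(numeric(), 0, 2,
                    dimnames = list(NULL, c("mz", "intensity")))
    if (length(high) < 3L) return(empty)
    mzs <- unlist(lapply(high, function(s) s@peaks[, 1L]))
    if (!length(mzs)) return(empty)
    ints <- unlist(lapply(high, function(s) s@peaks[, 2L]))
    scan <- rep(seq_along(high),
                vapply(high, function(s) nrow(s@peaks), integer(1)))
    ord <- order(mzs)
    mzs <- mzs[ord]; ints <- ints[ord]; scan <- scan[ord]
    bin <- cumsum(c(1, diff(mzs) > tolDa))
    precTrace <- stats::approx(precursorEic$rt, precursorEic$intensity,
                               xout = rts, rule = 2)$y
    rows <- list()
    for (b in unique(bin)) {
        sel <- bin == b
        trace <- numeric(length(high))
        tr <- tapply(ints[sel], scan[sel], sum)
        trace[as.integer(names(tr))] <- tr
        if (sum(trace > 0) < 3L) next
        r <- suppressWarnings(stats::cor(trace, precTrace))
        if (is.na(r) || r < minCorr) next
        apexIdx <- which.max(trace)
        if (abs(rts[apexIdx] - feature$rtApex) > apexTol) next
        mzCentre <- sum(mzs[sel] * ints[sel]) / sum(ints[sel])
        rows[[length(rows) + 1L]] <- c(mzCentre, max(trace))
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    colnames(out) <- c("mz", "intensity")
    out[order(out[, 1L]), , drop = FALSE]
}

#' Check diagnostic ions in a spectrum
#'
#' `TRUE` iff every required ion has a peak within `tolDa`; used to grant
#' confidence level 2b to enumerated metabolites whose fragmentation is
#' predicted from diagnostic ions only (e.g. the aglycone ion of a
#' glucoside).
#'
#' @param spectrum peak matrix, [Spectrum-class] or [MspRecord-class].
#' @param ions numeric vector of required ion m/z values (non-empty).
#' @param tolDa matching tolerance (Da).
#' @return list with `ok` (logical) and `matched` (the ions found).
#' @export
diagnosticIonCheck <- function(spectrum, ions, tolDa = 0.01) {
    if (!length(ions)) stop("no diagnostic ions to check")
    pk <- .peakMatrix(spectrum)
    found <- vapply(ions, function(ion)
        nrow(pk) > 0 && any(abs(pk[, 1L] - ion) <= tolDa), logical(1))
    list(ok = all(found), matched = ions[found])
}
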