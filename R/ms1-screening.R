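#' Extract an ion chromatogram
#'
#' Builds the EIC of a narrow m/z window from the survey scans (MS1, or
#' DIA_LOW when the run is a DIA acquisition) of a run: one point per scan,
#' the summed intensity of all centroids within `targetMz +/- tolDa`. The
#' +/-0.005 Da default window is the package-wide accurate-mass tolerance.
#'
#' @param run A [Run-class] with MS1-level scans.
#' @param targetMz target m/z (Da).
#' @param tolDa absolute window half-width (Da).
#' @return A list of class `"EIC"` with elements `targetMz`, `tolDa`, `rt`
#'   (minutes, strictly increasing) and `intensity`.
#' @export
extractEic <- function(run, targetMz, tolDa = 0.005) {
    sp <- .surveyScans(run)
    if (!length(sp)) stop("run has no MS1-level scans")
    rt <- vapply(sp, function(s) s@rt, numeric(1))
    lo <- targetMz - tolDa
    hi <- targetMz + tolDa
    intensity <- vapply(sp, function(s) {
        pk <- s@peaks
        if (!nrow(pk)) return(0)
        idx <- findInterval(c(lo, hi), pk[, 1L])
        # findInterval(lo) counts peaks <= lo; keep a peak sitting exactly at lo
        loIdx <- if (idx[1L] >= 1L && pk[idx[1L], 1L] >= lo) idx[1L]
                 else idx[1L] + 1L
        if (loIdx > idx[2L]) return(0)
        sum(pk[loIdx:idx[2L], 2L])
    }, numeric(1))
    structure(list(targetMz = targetMz, tolDa = tolDa, rt = rt,
                   intensity = intensity), class = "EIC")
}

.surveyScans <- function(run) {
    sp <- spectraOf(run)
    acq <- vapply(sp, function(s) s@acquisition, character(1))
    keep <- if (any(acq == "MS1")) acq == "MS1" else acq == "DIA_LOW"
    sp[keep]
}

#' Detect chromatographic peaks on an EIC
#'
#' Local maxima above `minHeightSnr` times the baseline noise (estimated as
#' the median trace intensity) are reported as features; an apex must also
#' be flanked by non-zero trace points, which suppresses single-scan noise
#' spikes (a chromatographic peak always spans several scans). Peak bounds
#' extend
#' from the apex until the trace descends to 5% of the apex height or turns
#' back up (a local minimum); the area is the trapezoid integral over the
#' bounds. Deterministic; an empty feature table is returned when nothing is
#' detected.
#'
#' @param eic an `"EIC"` from [extractEic()] (at least 5 points).
#' @param minHeightSnr signal-to-noise ratio an apex must exceed.
#' @return data.frame with columns `rtApex`, `height`, `area`, `rtStart`,
#'   `rtEnd`, `mz`.
#' @export
detectPeaks <- function(eic, minHeightSnr = 3) {
    rt <- eic$rt
    y <- eic$intensity
    n <- length(y)
    if (n < 5L) stop("EIC must have at least 5 points")
    noise <- stats::median(y)
    thr <- max(minHeightSnr * noise, .Machine$double.xmin)
    empty <- data.frame(rtApex = numeric(), height = numeric(),
                        area = numeric(), rtStart = numeric(),
                        rtEnd = numeric(), mz = numeric())
    flanked <- c(y[2L] > 0, y[-c(n - 1L, n)] > 0 & y[-c(1L, 2L)] > 0,
                 y[n - 1L] > 0)
    apexes <- which(y >= thr & y > 0 & flanked &
                    y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
    if (!length(apexes)) return(empty)
    claimed <- logical(n)
    rows <- list()
    for (a in apexes[order(-y[apexes])]) {
        if (claimed[a]) next
        cut <- 0.05 * y[a]
        lo <- a
        while (lo > 1L && !claimed[lo - 1L] && y[lo - 1L] > cut &&
               y[lo - 1L] <= y[lo]) lo <- lo - 1L
        if (lo > 1L && !claimed[lo - 1L] && y[lo - 1L] <= cut) lo <- lo - 1L
        hi <- a
        while (hi < n && !claimed[hi + 1L] && y[hi + 1L] > cut &&
               y[hi + 1L] <= y[hi]) hi <- hi + 1L
        if (hi < n && !claimed[hi + 1L] && y[hi + 1L] <= cut) hi <- hi + 1L
        claimed[lo:hi] <- TRUE
        seg <- lo:hi
        area <- sum(diff(rt[seg]) * (utils::head(y[seg], -1) +
                                     utils::tail(y[seg], -1)) / 2)
        rows[[length(rows) + 1L]] <- data.frame(
            rtApex = rt[a], height = y[a], area = area,
            rtStart = rt[lo], rtEnd = rt[hi], mz = eic$targetMz)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$rtApex), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Select the most abundant features
#'
#' Top-k features by chromatographic area (the "most abundant antioxidants"
#' prioritization); ties broken by earlier apex RT, then name. Stable and
#' deterministic.
#'
#' @param features a feature table (must contain `area` and `rtApex`;
#'   `suspect` used as final tie-break when present).
#' @param k number of features to keep; `k >= nrow` keeps all.
#' @return The selected rows of `features`.
#' @export
selectMostAbundant <- function(features, k) {
    if (k < 0) stop("k must be non-negative")
    if (!nrow(features) || k == 0)
        return(features[integer(), , drop = FALSE])
    nm <- if ("suspect" %in% names(features)) features$suspect
          else rep("", nrow(features))
    ord <- order(-features$area, features$rtApex, nm)
    out <- features[ord[seq_len(min(k, nrow(features)))], , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Procedure-blank filtering of screened features
#'
#' A sample feature is kept iff no blank feature matches it (same suspect,
#' apex RT within `rtTol`) or its area is at least `minRatio` times the
#' blank area — the five-fold procedure-blank rule. Exclusions are reported
#' with both areas. The kept set is a subset of the input and shrinks
#' monotonically as `minRatio` grows.
#'
#' @param sampleFeatures,blankFeatures feature tables with columns `suspect`,
#'   `rtApex`, `area`.
#' @param minRatio minimum sample/blank area ratio (default 5).
#' @param rtTol apex matching tolerance in minutes.
#' @return list with `kept` (feature table) and `excluded` (feature table
#'   with extra columns `blankArea` and `ratio`).
#' @export
blankFilter <- function(sampleFeatures, blankFeatures, minRatio = 5,
                        rtTol = 0.2) {
    if (!nrow(sampleFeatures))
        return(list(kept = sampleFeatures,
                    excluded = cbind(sampleFeatures,
                                     blankArea = numeric(),
                                     ratio = numeric())))
    blankArea <- rep(NA_real_, nrow(sampleFeatures))
    for (i in seq_len(nrow(sampleFeatures))) {
        hit <- blankFeatures$suspect == sampleFeatures$suspect[i] &
            abs(blankFeatures$rtApex - sampleFeatures$rtApex[i]) <= rtTol
        if (any(hit)) blankArea[i] <- max(blankFeatures$area[hit])
    }
    ratio <- sampleFeatures$area / blankArea
    keep <- is.na(blankArea) | ratio >= minRatio
    excluded <- cbind(sampleFeatures[!keep, , drop = FALSE],
                      blankArea = blankArea[!keep], ratio = ratio[!keep])
    rownames(excluded) <- NULL
    kept <- sampleFeatures[keep, , drop = FALSE]
    rownames(kept) <- NULL
    list(kept = kept, excluded = excluded)
}

#' Targeted MS1 screening of a run against a suspect list
#'
#' For every suspect whose adduct polarity matches the run, extracts the EIC
#' at the suspect's precursor m/z, detects peaks, and reports the detected
#' features; when several peaks are found for one suspect only the largest
#' (by area) is kept, the targeted-screening reading of one compound = one
#' chromatographic peak.
#'
#' @param run A [Run-class].
#' @param suspects a suspect table (see [suspectTable()]).
#' @param tolDa EIC window half-width (Da).
#' @param minHeightSnr see [detectPeaks()].
#' @return feature table with columns `suspect`, `sample`, `mz`, `rtApex`,
#'   `height`, `area`, `rtStart`, `rtEnd`.
#' @export
screenRun <- function(run, suspects, tolDa = 0.005, minHeightSnr = 3) {
    pol <- runPolarity(run)
    sus <- suspects[suspects$polarity == pol, , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(sus))) {
        eic <- extractEic(run, sus$precursorMz[i], tolDa)
        pk <- detectPeaks(eic, minHeightSnr)
        if (!nrow(pk)) next
        pk <- pk[which.max(pk$area), , drop = FALSE]
        rows[[length(rows) + 1L]] <- cbind(
            data.frame(suspect = sus$name[i], sample = sampleId(run),
                       stringsAsFactors = FALSE), pk)
    }
    if (!length(rows))
        return(data.frame(suspect = character(), sample = character(),
                          rtApex = numeric(), height = numeric(),
                          area = numeric(), rtStart = numeric(),
                          rtEnd = numeric(), mz = numeric()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
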