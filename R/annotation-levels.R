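.LEVELS <- c("1", "2a", "2b", "3", "4", "5")

#' Assemble identification evidence for one suspect in one sample
#'
#' @param massMatch logical: experimental m/z within the accurate-mass
#'   window (+/-0.005 Da) of the theoretical adduct m/z.
#' @param formulaConfirmed logical: molecular formula confirmed (here by
#'   mass fit; no isotope-pattern scoring).
#' @param spectrumRoute `NA`, `"DDA"` or `"DIA"`: the route that yielded a
#'   fragmentation-derived spectrum.
#' @param libraryScore cosine similarity against an experimental spectral
#'   library entry (`NA` when none); only valid with a spectrum.
#' @param referenceAvailable logical: reference standard in the lab.
#' @param referenceRt standard's retention time (minutes; `NA` unless
#'   available).
#' @param referenceScore cosine similarity against the standard's spectrum.
#' @param rtObserved observed apex RT (minutes).
#' @param predictedRt predicted RT (minutes, optional; prioritization only,
#'   never a gate).
#' @param diagnosticIonsOk logical or `NA`: all required diagnostic ions
#'   found.
#' @param inSilicoSupport logical or `NA`: in-silico fragment list matched.
#' @return A list of class `"Evidence"`.
#' @export
evidence <- function(massMatch, formulaConfirmed = FALSE,
                     spectrumRoute = NA_character_,
                     libraryScore = NA_real_,
                     referenceAvailable = FALSE, referenceRt = NA_real_,
                     referenceScore = NA_real_, rtObserved = NA_real_,
                     predictedRt = NA_real_, diagnosticIonsOk = NA,
                     inSilicoSupport = NA) {
    if (!is.na(libraryScore) && is.na(spectrumRoute))
        stop("inconsistent evidence: a library score requires a spectrum")
    if (!is.na(referenceRt) && !referenceAvailable)
        stop("inconsistent evidence: reference RT without a standard")
    structure(list(massMatch = isTRUE(massMatch),
                   formulaConfirmed = isTRUE(formulaConfirmed),
                   spectrumRoute = spectrumRoute,
                   libraryScore = libraryScore,
                   referenceAvailable = isTRUE(referenceAvailable),
                   referenceRt = referenceRt,
                   referenceScore = referenceScore,
                   rtObserved = rtObserved, predictedRt = predictedRt,
                   diagnosticIonsOk = diagnosticIonsOk,
                   inSilicoSupport = inSilicoSupport),
              class = "Evidence")
}

#' Assign an identification confidence level
#'
#' Applies the five-level confidence scheme (with the 2a/2b split) as an
#' ordered rule cascade; the first rule that fires decides the level:
#' \describe{
#'   \item{1}{reference standard available, observed RT within `rtTol` of the
#'     standard's RT, and the acquired spectrum matches the standard's
#'     spectrum with score >= `level1ScoreMin`;}
#'   \item{2a}{an experimental library spectrum matches with score
#'     strictly greater than `score2a` (0.7);}
#'   \item{2b}{all required diagnostic ions are present;}
#'   \item{3}{in-silico fragmentation support;}
#'   \item{4}{molecular formula confirmed;}
#'   \item{5}{exact mass only.}
#' }
#' Adding evidence can only improve (never worsen) the level. The returned
#' rationale names the fired rule and the evaluated values.
#'
#' @param ev an [evidence()] object with `massMatch = TRUE` (without a mass
#'   match there is nothing to annotate and an error is raised).
#' @param rtTol level-1 RT agreement tolerance (minutes).
#' @param level1ScoreMin minimum score against the standard's spectrum for
#'   level 1.
#' @param score2a the (strict) library-match gate for level 2a.
#' @return list with `level` (one of "1","2a","2b","3","4","5"), `score`
#'   (the score supporting the level, or `NA`) and `rationale`.
#' @export
assignLevel <- function(ev, rtTol = 0.5, level1ScoreMin = 0.6,
                        score2a = 0.7) {
    stopifnot(inherits(ev, "Evidence"))
    if (!ev$massMatch)
        stop("no accurate-mass match: suspect cannot be annotated")
    if (ev$referenceAvailable && !is.na(ev$referenceRt) &&
        !is.na(ev$rtObserved) &&
        abs(ev$rtObserved - ev$referenceRt) <= rtTol &&
        !is.na(ev$referenceScore) && ev$referenceScore >= level1ScoreMin)
        return(list(level = "1", score = ev$referenceScore,
                    rationale = sprintf(
                        "L1: standard RT %.2f vs observed %.2f (<= %.2f min), standard-spectrum score %.3f >= %.2f",
                        ev$referenceRt, ev$rtObserved, rtTol,
                        ev$referenceScore, level1ScoreMin)))
    if (!is.na(ev$libraryScore) && ev$libraryScore > score2a)
        return(list(level = "2a", score = ev$libraryScore,
                    rationale = sprintf(
                        "L2a: library score %.3f > %.2f", ev$libraryScore,
                        score2a)))
    if (isTRUE(ev$diagnosticIonsOk))
        return(list(level = "2b", score = NA_real_,
                    rationale = "L2b: all required diagnostic ions present"))
    if (isTRUE(ev$inSilicoSupport))
        return(list(level = "3", score = NA_real_,
                    rationale = "L3: in-silico fragmentation support"))
    if (ev$formulaConfirmed)
        return(list(level = "4", score = NA_real_,
                    rationale = "L4: molecular formula confirmed"))
    list(level = "5", score = NA_real_,
         rationale = "L5: exact mass only")
}

#' Annotate a screened dataset
#'
#' Joins kept features with per-compound match reports and the standards
#' registry, assigns a confidence level to every (suspect, sample) pair,
#' resolves co-candidates (isobaric suspects claiming the same
#' chromatographic peak keep only their best-evidenced candidate as
#' primary), and summarizes per compound (the best, i.e. lowest, level
#' across samples) and as a level histogram over compounds.
#'
#' @param features kept feature table (columns `suspect`, `sample`,
#'   `rtApex`, `mz`).
#' @param matchReports data.frame keyed by (`suspect`, `sample`) with
#'   columns `route`, `libraryScore`, `referenceScore`, `diagnosticOk`,
#'   `inSilicoOk` (NAs where not applicable).
#' @param suspects suspect table (theoretical m/z and predicted RT).
#' @param standards data.frame registry with columns `name` and `rt`
#'   (reference standards available in the lab).
#' @param mzTol accurate-mass window (Da).
#' @param ... thresholds passed to [assignLevel()].
#' @return list with `annotations` (one row per suspect per sample),
#'   `byCompound` (best level per compound) and `summary` (named level
#'   histogram over compounds).
#' @export
annotateDataset <- function(features, matchReports, suspects, standards,
                            mzTol = 0.005, ...) {
    emptyAnn <- data.frame(suspect = character(), sample = character(),
                           level = character(), score = numeric(),
                           route = character(), rationale = character(),
                           rtApex = numeric(), mz = numeric(),
                           coCandidate = logical(),
                           stringsAsFactors = FALSE)
    if (!nrow(features))
        return(list(annotations = emptyAnn,
                    byCompound = emptyAnn[, c("suspect", "level")],
                    summary = integer()))
    rows <- list()
    for (i in seq_len(nrow(features))) {
        f <- features[i, ]
        si <- match(f$suspect, suspects$name)
        theor <- suspects$precursorMz[si]
        expMz <- if ("expMz" %in% names(f) && !is.na(f$expMz)) f$expMz
                 else f$mz
        if (is.na(theor) || abs(expMz - theor) > mzTol) next
        mi <- which(matchReports$suspect == f$suspect &
                    matchReports$sample == f$sample)
        rep1 <- if (length(mi)) matchReports[mi[1L], ] else NULL
        stdIdx <- match(f$suspect, standards$name)
        route <- if (!is.null(rep1)) rep1$route else NA_character_
        ev <- evidence(
            massMatch = TRUE,
            formulaConfirmed = TRUE,  # mass-fit-only formula confirmation
            spectrumRoute = route,
            libraryScore = if (!is.null(rep1)) rep1$libraryScore
                           else NA_real_,
            referenceAvailable = !is.na(stdIdx),
            referenceRt = if (!is.na(stdIdx)) standards$rt[stdIdx]
                          else NA_real_,
            referenceScore = if (!is.null(rep1)) rep1$referenceScore
                             else NA_real_,
            rtObserved = f$rtApex,
            predictedRt = suspects$predictedRt[si],
            diagnosticIonsOk = if (!is.null(rep1)) rep1$diagnosticOk else NA,
            inSilicoSupport = if (!is.null(rep1)) rep1$inSilicoOk else NA)
        ann <- assignLevel(ev, ...)
        rows[[length(rows) + 1L]] <- data.frame(
            suspect = f$suspect, sample = f$sample, level = ann$level,
            score = ann$score, route = route, rationale = ann$rationale,
            rtApex = f$rtApex, mz = expMz, stringsAsFactors = FALSE)
    }
    annotations <- if (length(rows)) do.call(rbind, rows) else emptyAnn
    rownames(annotations) <- NULL
    annotations <- .resolveCoCandidates(annotations, mzTol)
    primary <- annotations[!annotations$coCandidate, , drop = FALSE]
    byCompound <- do.call(rbind, lapply(
        split(primary, primary$suspect), function(g) {
            best <- g[which.min(match(g$level, .LEVELS)), , drop = FALSE]
            best[, c("suspect", "level", "score")]
        }))
    if (is.null(byCompound))
        byCompound <- emptyAnn[, c("suspect", "level", "score")]
    rownames(byCompound) <- NULL
    summary <- table(factor(byCompound$level, levels = .LEVELS))
    list(annotations = annotations, byCompound = byCompound,
         summary = summary[summary > 0])
}

# One chromatographic peak identifies one compound: suspects that are
# isobaric within the accurate-mass window and share the apex RT (e.g. an
# enumerated diglucoside sharing the formula of a planted glycoside) claim
# the same feature. The candidate with the strongest evidence (lowest level,
# then highest score, then name) stays primary; the rest are flagged as
# co-candidates and excluded from compound-level reporting.
.resolveCoCandidates <- function(annotations, mzTol, rtTol = 0.1) {
    annotations$coCandidate <- rep(FALSE, nrow(annotations))
    if (!nrow(annotations)) return(annotations)
    for (s in unique(annotations$sample)) {
        idx <- which(annotations$sample == s)
        a <- annotations[idx, ]
        ord <- idx[order(match(a$level, .LEVELS), -ifelse(is.na(a$score),
                                                          -Inf, a$score),
                         a$suspect)]
        taken <- annotations[integer(), c("rtApex", "mz")]
        for (i in ord) {
            clash <- nrow(taken) &&
                any(abs(taken$mz - annotations$mz[i]) <= 2 * mzTol &
                    abs(taken$rtApex - annotations$rtApex[i]) <= rtTol)
            if (clash) annotations$coCandidate[i] <- TRUE
            else taken <- rbind(taken,
                                annotations[i, c("rtApex", "mz")])
        }
    }
    annotations
}
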