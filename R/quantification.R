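#' Fit an external calibration curve
#'
#' Unweighted ordinary least squares of response on concentration, with the
#' classical parameter standard errors and the determination coefficient.
#'
#' @param levels data.frame with columns `conc` (mg/L) and `response`
#'   (instrument response); at least three distinct concentrations.
#' @param analyte optional analyte name carried in the result.
#' @return list of class `"CalibrationCurve"` with elements `analyte`, `a`
#'   (slope), `sa`, `b` (intercept), `sb`, `r2` and `levels`.
#' @examples
#' lv <- data.frame(conc = c(0.5, 1, 2.5, 5, 10),
#'                  response = 114212 * c(0.5, 1, 2.5, 5, 10) - 27802)
#' fitCalibration(lv)$a  # 114212
#' @export
fitCalibration <- function(levels, analyte = NA_character_) {
    stopifnot(is.data.frame(levels),
              all(c("conc", "response") %in% names(levels)))
    if (length(unique(levels$conc)) < 3L)
        stop("insufficient levels: need >= 3 distinct concentrations")
    fit <- stats::lm(response ~ conc, data = levels)
    # exactly collinear points are a legitimate input (round-trip contract);
    # muffle only summary.lm's perfect-fit caveat
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
    co <- sm$coefficients
    structure(list(analyte = analyte,
                   a = unname(co["conc", "Estimate"]),
                   sa = unname(co["conc", "Std. Error"]),
                   b = unname(co["(Intercept)", "Estimate"]),
                   sb = unname(co["(Intercept)", "Std. Error"]),
                   r2 = sm$r.squared,
                   levels = levels),
              class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
    cat(sprintf(
        "Calibration %s: y = (%.4g ± %.3g)x %s (%.4g ± %.3g), R² = %.4g, %d levels\n",
        if (is.na(x$analyte)) "" else x$analyte, x$a, x$sa,
        if (x$b < 0) "−" else "+", abs(x$b), x$sb, x$r2,
        nrow(x$levels)))
    invisible(x)
}

#' Invert a calibration curve
#'
#' `(response - b) / a`; monotone in the response for positive slopes.
#'
#' @param curve a `"CalibrationCurve"`.
#' @param response instrument response(s).
#' @return concentration(s) in mg/L.
#' @export
invertConcentration <- function(curve, response) {
    if (curve$a == 0) stop("zero calibration slope")
    (response - curve$b) / curve$a
}

#' Quantify replicate sample responses
#'
#' Inverts each replicate response through the analyte's calibration curve,
#' converts mg/L to mg/kg via `massFactor` (default 1: the extraction is
#' treated as self-consistent), and reports the replicate mean, standard
#' deviation and a below-LOQ flag applied to the mean concentration.
#'
#' @param curves named list of `"CalibrationCurve"` objects (names =
#'   analytes), or a single curve.
#' @param responses data.frame with columns `analyte`, `sample`,
#'   `replicate`, `response`.
#' @param massFactor mg/L -> mg/kg conversion factor.
#' @param loq limit of quantification (mg/kg), default 0.5.
#' @return data.frame with columns `analyte`, `sample`, `concentration`
#'   (mg/kg, replicate mean), `sd`, `n`, `belowLoq`.
#' @export
quantifySamples <- function(curves, responses, massFactor = 1, loq = 0.5) {
    if (inherits(curves, "CalibrationCurve"))
        curves <- stats::setNames(list(curves), curves$analyte)
    groups <- split(responses,
                    list(responses$analyte, responses$sample), drop = TRUE)
    rows <- lapply(groups, function(g) {
        curve <- curves[[g$analyte[1L]]]
        if (is.null(curve))
            stop("no calibration curve for analyte '", g$analyte[1L], "'")
        conc <- invertConcentration(curve, g$response) * massFactor
        m <- mean(conc)
        data.frame(analyte = g$analyte[1L], sample = g$sample[1L],
                   concentration = m,
                   sd = if (length(conc) > 1L) stats::sd(conc) else 0,
                   n = length(conc), belowLoq = m < loq,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$analyte, out$sample), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read calibration and sample-response CSV files
#'
#' `readCalibrationCsv` expects columns `analyte`, `conc`, `response` and
#' returns a named list of fitted curves; `readResponsesCsv` expects
#' `analyte`, `sample`, `replicate`, `response`.
#'
#' @param path CSV file path.
#' @return See description.
#' @export
readCalibrationCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("analyte", "conc", "response") %in% names(df)))
    lapply(split(df, df$analyte), function(g)
        fitCalibration(g[, c("conc", "response")], analyte = g$analyte[1L]))
}

#' @rdname readCalibrationCsv
#' @export
readResponsesCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("analyte", "sample", "replicate", "response") %in%
                  names(df)))
    df
}
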