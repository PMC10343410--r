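#' Construct a suspect table
#'
#' The canonical in-memory form of a suspect list (BDSL, LBL, VMSL or a merge
#' thereof): one row per candidate compound per adduct. `exactMass` and
#' `precursorMz` are recomputed from the formula/adduct whenever missing, and
#' a supplied `precursorMz` must agree with the theoretical adduct m/z within
#' 0.002 Da.
#'
#' @param name,formula character vectors (required; any formula dialect).
#' @param adduct adduct labels (default `"[M-H]-"`), recycled.
#' @param exactMass,precursorMz optional numeric; filled in when `NA`.
#' @param predictedRt optional predicted retention time (minutes).
#' @param source list tag(s), e.g. `"BDSL"`; multiple tags are
#'   semicolon-joined in one string.
#' @param referenceStandard logical: is a reference standard available?
#' @param smiles optional structure strings (carried through).
#' @param diagnosticIons optional list of data.frames as returned by
#'   [diagnosticIons()] (one per row).
#' @return data.frame with columns name, formula, adduct, polarity,
#'   exactMass, precursorMz, predictedRt, source, referenceStandard, smiles,
#'   and the list-column diagnosticIons.
#' @export
suspectTable <- function(name = character(), formula = character(),
                         adduct = "[M-H]-", exactMass = NA_real_,
                         precursorMz = NA_real_, predictedRt = NA_real_,
                         source = "BDSL", referenceStandard = FALSE,
                         smiles = NA_character_, diagnosticIons = NULL) {
    n <- length(name)
    if (n == 0L) {
        out <- data.frame(name = character(), formula = character(),
                          adduct = character(), polarity = character(),
                          exactMass = numeric(), precursorMz = numeric(),
                          predictedRt = numeric(), source = character(),
                          referenceStandard = logical(),
                          smiles = character(), stringsAsFactors = FALSE)
        out$diagnosticIons <- list()
        return(out)
    }
    stopifnot(length(formula) == n)
    rec <- function(x) rep_len(x, n)
    adduct <- rec(adduct); exactMass <- rec(exactMass)
    precursorMz <- rec(precursorMz); predictedRt <- rec(predictedRt)
    source <- rec(source); referenceStandard <- rec(referenceStandard)
    smiles <- rec(smiles)
    hill <- character(n); pol <- character(n)
    for (i in seq_len(n)) {
        f <- parseFormula(formula[i])
        hill[i] <- hillFormula(f)
        sp <- adductSpec(adduct[i])
        adduct[i] <- sp$name
        pol[i] <- sp$polarity
        theor <- adductMz(f, sp)
        if (is.na(exactMass[i])) exactMass[i] <- monoisotopicMass(f)
        if (is.na(precursorMz[i])) {
            precursorMz[i] <- theor
        } else if (abs(precursorMz[i] - theor) > 0.002) {
            stop(sprintf(
                "precursorMz %.4f inconsistent with %s of %s (%.4f)",
                precursorMz[i], adduct[i], hill[i], theor))
        }
    }
    out <- data.frame(name = name, formula = hill, adduct = adduct,
                      polarity = pol, exactMass = exactMass,
                      precursorMz = precursorMz, predictedRt = predictedRt,
                      source = source, referenceStandard = referenceStandard,
                      smiles = smiles, stringsAsFactors = FALSE)
    out$diagnosticIons <- if (is.null(diagnosticIons))
        replicate(n, .emptyIons(), simplify = FALSE) else diagnosticIons
    out
}

.emptyIons <- function()
    data.frame(label = character(), mz = numeric(), required = logical())

.suspectKey <- function(suspects)
    paste(suspects$formula, tolower(suspects$name), sep = "|")

# pack/unpack the diagnostic-ion list column for CSV round-trips
.packIons <- function(ions) {
    if (is.null(ions) || !nrow(ions)) return("")
    paste(sprintf("%s:%.6f:%d", ions$label, ions$mz,
                  as.integer(ions$required)), collapse = ";")
}

.unpackIons <- function(txt) {
    if (is.na(txt) || !nzchar(txt)) return(.emptyIons())
    parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(label = vapply(parts, `[`, "", 1L),
               mz = as.numeric(vapply(parts, `[`, "", 2L)),
               required = as.logical(as.integer(vapply(parts, `[`, "", 3L))))
}

#' Read / write suspect-list CSV files
#'
#' The CSV schema requires `name` and `formula` columns; `adduct`,
#' `exact_mass`, `precursor_mz`, `predicted_rt`, `source`,
#' `reference_standard`, `smiles` and `diagnostic_ions` are optional and
#' recomputed or defaulted when absent. Write-then-read is the identity on
#' the canonical suspect table.
#'
#' @param path file path.
#' @param suspects a suspect table (see [suspectTable()]).
#' @return `readSuspectCsv` returns a suspect table; `writeSuspectCsv`
#'   invisibly returns `path`.
#' @export
readSuspectCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    missing <- setdiff(c("name", "formula"), names(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    if (!nrow(df)) return(suspectTable())
    get <- function(col, default) if (col %in% names(df)) df[[col]] else
        rep(default, nrow(df))
    formulas <- df$formula
    for (i in seq_len(nrow(df))) {
        ok <- tryCatch({ parseFormula(formulas[i]); TRUE },
                       error = function(e) e)
        if (!isTRUE(ok))
            stop(sprintf("row %d: %s", i, conditionMessage(ok)))
    }
    ionsTxt <- get("diagnostic_ions", "")
    suspectTable(
        name = df$name, formula = formulas,
        adduct = get("adduct", "[M-H]-"),
        exactMass = as.numeric(get("exact_mass", NA_real_)),
        precursorMz = as.numeric(get("precursor_mz", NA_real_)),
        predictedRt = as.numeric(get("predicted_rt", NA_real_)),
        source = get("source", "BDSL"),
        referenceStandard = as.logical(get("reference_standard", FALSE)),
        smiles = as.character(get("smiles", NA_character_)),
        diagnosticIons = lapply(as.character(ionsTxt), .unpackIons)
    )
}

#' @rdname readSuspectCsv
#' @export
writeSuspectCsv <- function(suspects, path) {
    df <- data.frame(
        name = suspects$name, formula = suspects$formula,
        adduct = suspects$adduct,
        exact_mass = suspects$exactMass,
        precursor_mz = suspects$precursorMz,
        predicted_rt = suspects$predictedRt,
        source = suspects$source,
        reference_standard = suspects$referenceStandard,
        smiles = suspects$smiles,
        diagnostic_ions = vapply(suspects$diagnosticIons, .packIons, ""),
        stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Merge suspect lists
#'
#' Entries are deduplicated on (canonical Hill formula, case-folded name);
#' for duplicates the source tags are unioned (semicolon-joined), a
#' reference-standard flag is OR-ed, and the first non-missing value of the
#' remaining fields wins. Entries sharing a name but not a formula are kept
#' separately (a name collision is messaged). Output order is first
#' appearance.
#'
#' @param ... suspect tables, or a single list of them.
#' @return A merged suspect table.
#' @export
mergeSuspectLists <- function(...) {
    lists <- list(...)
    if (length(lists) == 1L && is.list(lists[[1]]) &&
        !is.data.frame(lists[[1]])) lists <- lists[[1]]
    all <- do.call(rbind, lists)
    if (is.null(all) || !nrow(all)) return(suspectTable())
    key <- .suspectKey(all)
    nm <- tolower(all$name)
    for (x in unique(nm)) {
        forms <- unique(all$formula[nm == x])
        if (length(forms) > 1L)
            message("name collision: '", all$name[match(x, nm)],
                    "' maps to formulas ", paste(forms, collapse = ", "),
                    "; kept as separate entries")
    }
    firsts <- !duplicated(key)
    out <- all[firsts, , drop = FALSE]
    outKey <- key[firsts]
    for (i in seq_len(nrow(out))) {
        grp <- all[key == outKey[i], , drop = FALSE]
        tags <- unique(unlist(strsplit(grp$source, ";", fixed = TRUE)))
        out$source[i] <- paste(tags, collapse = ";")
        out$referenceStandard[i] <- any(grp$referenceStandard)
        if (is.na(out$predictedRt[i]))
            out$predictedRt[i] <- grp$predictedRt[
                which(!is.na(grp$predictedRt))[1]]
        best <- which(vapply(grp$diagnosticIons, nrow, 0L) > 0)[1]
        if (!is.na(best)) out$diagnosticIons[[i]] <- grp$diagnosticIons[[best]]
    }
    rownames(out) <- NULL
    out
}

#' Intersect two suspect lists
#'
#' Returns the entries of `a` whose dedupe key (canonical formula +
#' case-folded name) also occurs in `b`; the confirmatory cross-list check
#' between independently compiled suspect lists.
#'
#' @param a,b suspect tables.
#' @return A suspect table (subset of `a`).
#' @export
intersectSuspectLists <- function(a, b) {
    keep <- .suspectKey(a) %in% .suspectKey(b)
    out <- a[keep, , drop = FALSE]
    out <- out[!duplicated(.suspectKey(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# ---- MSP ----------------------------------------------------------------

#' Construct an MSP record
#'
#' @param name,formula,precursorType,ionMode character scalars.
#' @param precursorMz numeric precursor m/z (Da).
#' @param retentionTime optional minutes.
#' @param peaks two-column matrix or data.frame (mz, intensity); sorted by
#'   m/z on construction.
#' @param extra named character vector of additional MSP keys (preserved on
#'   serialization).
#' @return An [MspRecord-class].
#' @export
mspRecord <- function(name, formula, precursorMz, precursorType,
                      ionMode = c("negative", "positive"),
                      retentionTime = NA_real_, peaks,
                      extra = character()) {
    ionMode <- match.arg(ionMode)
    pk <- as.matrix(peaks)
    colnames(pk) <- c("mz", "intensity")
    pk <- pk[order(pk[, 1L]), , drop = FALSE]
    new("MspRecord", name = name, formula = formula,
        precursorMz = precursorMz,
        precursorType = .normalizeAdductName(precursorType),
        ionMode = ionMode, retentionTime = retentionTime,
        peaks = pk, extra = extra)
}

setMethod("show", "MspRecord", function(object) {
    cat(sprintf("MspRecord: %s (%s) %s %.4f, %d peaks\n", object@name,
                object@formula, object@precursorType, object@precursorMz,
                nrow(object@peaks)))
})

#' Read / write MSP spectral databases
#'
#' Parses the GNPS/MS-DIAL-compatible MSP dialect: records separated by blank
#' lines, case-insensitive `NAME` / `FORMULA` / `PRECURSORMZ` /
#' `PRECURSORTYPE` / `IONMODE` / `RETENTIONTIME` / `Num Peaks` keys, peak
#' lines `mz<TAB or space>intensity`. Unknown keys are preserved verbatim and
#' round-trip untouched; a peak count differing from `Num Peaks` is an error.
#'
#' @param path file path.
#' @param records list of [MspRecord-class] objects.
#' @return `readMsp` returns a list of [MspRecord-class]; `writeMsp`
#'   invisibly returns `path`.
#' @export
readMsp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    blank <- !nzchar(trimws(lines))
    blocks <- split(lines[!blank], cumsum(blank)[!blank])
    out <- lapply(blocks, .parseMspBlock)
    names(out) <- NULL
    out
}

.parseMspBlock <- function(lines) {
    keyed <- grepl("^[^ \t].*:", lines) & !grepl("^[0-9]", lines)
    kv <- lines[keyed]
    origKeys <- trimws(sub(":.*$", "", kv))
    keys <- toupper(origKeys)
    vals <- trimws(sub("^[^:]*:", "", kv))
    names(vals) <- keys
    npIdx <- which(keys == "NUM PEAKS")
    if (!length(npIdx)) stop("MSP block without 'Num Peaks'")
    np <- as.integer(vals[["NUM PEAKS"]])
    peakLines <- lines[!keyed]
    peakLines <- peakLines[nzchar(trimws(peakLines))]
    if (length(peakLines) != np)
        stop(sprintf("peak count mismatch: 'Num Peaks: %d' but %d peak lines",
                     np, length(peakLines)))
    pk <- matrix(numeric(), 0, 2)
    if (np > 0) {
        parts <- strsplit(trimws(peakLines), "[ \t]+")
        if (any(vapply(parts, length, 0L) < 2L))
            stop("unparseable peak line in MSP block")
        pk <- cbind(as.numeric(vapply(parts, `[`, "", 1L)),
                    as.numeric(vapply(parts, `[`, "", 2L)))
        if (any(is.na(pk))) stop("unparseable peak line in MSP block")
    }
    known <- c("NAME", "FORMULA", "PRECURSORMZ", "PRECURSORTYPE", "IONMODE",
               "RETENTIONTIME", "NUM PEAKS")
    extraIdx <- which(!keys %in% known)
    extra <- stats::setNames(unname(vals[extraIdx]), origKeys[extraIdx])
    mode <- tolower(vals["IONMODE"] %||NA% "negative")
    mspRecord(
        name = unname(vals["NAME"] %||NA% ""),
        formula = unname(vals["FORMULA"] %||NA% ""),
        precursorMz = as.numeric(vals["PRECURSORMZ"] %||NA% NA),
        precursorType = unname(vals["PRECURSORTYPE"] %||NA% "[M-H]-"),
        ionMode = if (startsWith(mode, "p")) "positive" else "negative",
        retentionTime = as.numeric(vals["RETENTIONTIME"] %||NA% NA),
        peaks = pk,
        extra = extra
    )
}

`%||NA%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' @rdname readMsp
#' @export
writeMsp <- function(records, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in records) {
        writeLines(c(
            paste0("NAME: ", r@name),
            paste0("FORMULA: ", r@formula),
            sprintf("PRECURSORMZ: %.4f", r@precursorMz),
            paste0("PRECURSORTYPE: ", r@precursorType),
            paste0("IONMODE: ", r@ionMode),
            if (!is.na(r@retentionTime))
                sprintf("RETENTIONTIME: %.2f", r@retentionTime),
            if (length(r@extra))
                paste0(.titleKey(names(r@extra)), ": ", unname(r@extra)),
            sprintf("Num Peaks: %d", nrow(r@peaks)),
            if (nrow(r@peaks))
                sprintf("%.4f\t%.1f", r@peaks[, 1L], r@peaks[, 2L]),
            ""
        ), con)
    }
    invisible(path)
}

.titleKey <- function(keys) keys  # extras round-trip with their stored case
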