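#' Combinatorial enumeration of virtual metabolites
#'
#' Expands a set of scaffold compounds into a Virtual Metabolite Suspect List
#' (VMSL) by combinatorially attaching glucose units and/or a methyl group.
#' Glycosylation is modeled as condensation chemistry (+C6H10O5 per glucose,
#' i.e. glucose minus water) and methylation as +CH2; the (0, 0) combination
#' is the hydrogen building block, which retains the unmodified parent.
#'
#' @param scaffolds data.frame with columns `name` and `formula` (strings;
#'   any accepted formula dialect) and optionally `smiles` (carried through,
#'   never interpreted).
#' @param maxGlucose,maxMethyl maximum number of glucose units / methyl
#'   groups (defaults 2 and 1: one or two glucose units and/or a methyl).
#' @return data.frame with one row per product, in deterministic order
#'   (scaffold order, then `nGlucose`, then `nMethyl`): columns `name`,
#'   `formula` (Hill string), `parent`, `nGlucose`, `nMethyl`, `smiles`.
#'   Exactly `nrow(scaffolds) * (maxGlucose+1) * (maxMethyl+1)` rows.
#' @examples
#' sc <- data.frame(name = "ellagic acid", formula = "C14H6O8")
#' subset(enumerateProducts(sc), nGlucose == 1 & nMethyl == 0)$formula
#' @export
enumerateProducts <- function(scaffolds, maxGlucose = 2, maxMethyl = 1) {
    stopifnot(is.data.frame(scaffolds), nrow(scaffolds) > 0,
              all(c("name", "formula") %in% names(scaffolds)),
              maxGlucose >= 0, maxMethyl >= 0)
    if (anyDuplicated(scaffolds$name))
        stop("duplicate scaffold names")
    glc <- parseFormula("C6H10O5")
    me  <- parseFormula("CH2")
    smiles <- if ("smiles" %in% names(scaffolds)) scaffolds$smiles
              else rep(NA_character_, nrow(scaffolds))
    rows <- list()
    for (i in seq_len(nrow(scaffolds))) {
        parent <- parseFormula(scaffolds$formula[i])
        for (g in 0:maxGlucose) for (m in 0:maxMethyl) {
            f <- formulaAdd(formulaAdd(parent, formulaMultiply(glc, g)),
                            formulaMultiply(me, m))
            rows[[length(rows) + 1L]] <- data.frame(
                name = .productName(scaffolds$name[i], g, m),
                formula = hillFormula(f),
                parent = scaffolds$name[i],
                nGlucose = g, nMethyl = m,
                smiles = smiles[i],
                stringsAsFactors = FALSE
            )
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.productName <- function(parent, g, m) {
    if (g == 0 && m == 0) return(parent)
    if (m == 0 && g == 1) return(paste(parent, "glucoside"))
    if (m == 0 && g == 2) return(paste(parent, "diglucoside"))
    suffix <- c(if (g > 0) sprintf("+%dGlc", g), if (m > 0) "+Me")
    paste(parent, paste(suffix, collapse = " "))
}

#' Diagnostic ions of an enumerated metabolite
#'
#' For glycosylated products the MS/MS behaviour is predicted from the
#' characteristic diagnostic ions alone: the aglycone ion (the parent
#' scaffold, retaining any methylations, ionized in the requested polarity)
#' equals the neutral-loss series precursor - k x 162.0528 Da (k = 1..n
#' glucose units). The deprotonated/protonated sugar-moiety fragment is also
#' reported but labelled optional. Parent-only products (hydrogen block)
#' yield no supplement.
#'
#' @param product one row of [enumerateProducts()] output (data.frame or
#'   list with `formula`, `nGlucose`, `nMethyl`).
#' @param polarity "negative" (default) or "positive".
#' @return data.frame with columns `label`, `mz`, `required` (logical);
#'   zero rows for the (0, 0) combination.
#' @export
diagnosticIons <- function(product, polarity = c("negative", "positive")) {
    polarity <- match.arg(polarity)
    adduct <- if (polarity == "negative") "[M-H]-" else "[M+H]+"
    g <- product$nGlucose
    m <- product$nMethyl
    empty <- data.frame(label = character(), mz = numeric(),
                        required = logical())
    if (g == 0 && m == 0) return(empty)
    if (g == 0) return(empty)  # pure methylation: no glycoside diagnostics
    f <- parseFormula(product$formula)
    aglyconeF <- formulaSubtract(
        f, formulaMultiply(parseFormula("C6H10O5"), g))
    aglycone <- adductMz(aglyconeF, adduct)
    precursor <- adductMz(f, adduct)
    losses <- precursor - seq_len(g) * .GLUCOSE_CONDENSATION
    sugar <- .GLUCOSE_CONDENSATION +
        if (polarity == "negative") -.PROTON_MASS else .PROTON_MASS
    out <- rbind(
        data.frame(label = "aglycone", mz = aglycone, required = TRUE),
        data.frame(label = sprintf("loss_%dxGlc", seq_len(g)), mz = losses,
                   required = TRUE),
        data.frame(label = "sugar", mz = sugar, required = FALSE)
    )
    rownames(out) <- NULL
    out
}

#' Convert enumerated products into suspect entries
#'
#' One suspect entry per product per polarity-compatible adduct, tagged with
#' source "VMSL" and carrying the product's diagnostic ions.
#'
#' @param products output of [enumerateProducts()].
#' @param adducts character vector of adduct labels (or list of
#'   [adductSpec()] results); default `"[M-H]-"`.
#' @return A suspect table (see [suspectTable()]).
#' @export
productsToSuspects <- function(products, adducts = "[M-H]-") {
    specs <- lapply(adducts, function(a)
        if (is.character(a)) adductSpec(a) else a)
    rows <- list()
    for (i in seq_len(nrow(products))) for (sp in specs) {
        p <- products[i, ]
        rows[[length(rows) + 1L]] <- suspectTable(
            name = p$name,
            formula = p$formula,
            adduct = sp$name,
            predictedRt = NA_real_,
            source = "VMSL",
            referenceStandard = FALSE,
            diagnosticIons = list(diagnosticIons(p, sp$polarity))
        )
    }
    if (!length(rows))
        return(suspectTable())
    do.call(rbind, rows)
}
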