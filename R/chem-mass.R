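# Monoisotopic masses of the most abundant isotope (Da). Embedded as constants
# so all mass arithmetic is dependency-free and deterministic.
.ELEMENT_MASSES <- c(
    C  = 12.0000000,
    H  = 1.0078250319,
    N  = 14.0030740052,
    O  = 15.9949146221,
    S  = 31.97207069,
    P  = 30.97376151,
    Na = 22.98976928,
    K  = 38.9637069,
    Cl = 34.96885271,
    F  = 18.99840322,
    Br = 78.9183376,
    I  = 126.904473,
    Si = 27.9769265
)

# Charge-carrier convention: the (de)protonation delta is the proton mass
# (nuclide mass minus the electron carried away by the charge), 1.007276 Da,
# not the H-atom mass. The ammonium cation likewise carries the charge.
.PROTON_MASS   <- 1.00727646
.ELECTRON_MASS <- 0.00054858
.WATER_MASS    <- 18.0105646   # H2O
.AMMONIUM_MASS <- 18.0338254   # NH4+ cation (N + 4H - e)

#' Masses of common building blocks (Da)
#'
#' Condensation-chemistry increments used by the virtual-metabolite
#' enumeration: a glucose unit adds C6H10O5 (glucose minus water) and a methyl
#' group adds CH2 (replacing an H).
#' @keywords internal
.GLUCOSE_CONDENSATION <- 162.05282343  # C6H10O5
.METHYLENE            <- 14.01565006   # CH2

.SUBSCRIPT_DIGITS <- c("₀", "₁", "₂", "₃", "₄",
                       "₅", "₆", "₇", "₈", "₉")

#' Construct a molecular formula from element counts
#'
#' @param counts named numeric/integer vector of element counts; zero counts
#'   are dropped, so `molecularFormula(c(C = 0))` is the empty formula.
#' @return A [MolecularFormula-class].
#' @examples
#' molecularFormula(c(C = 6, H = 8, O = 7))
#' @export
molecularFormula <- function(counts = integer()) {
    if (length(counts)) {
        if (any(is.na(counts)) || any(counts < 0))
            stop("element counts must be non-negative")
        counts <- counts[counts > 0]
        cnt <- as.integer(round(counts))
        names(cnt) <- names(counts)
        # canonical storage order: Hill (C, H, then alphabetical)
        cnt <- cnt[.hillOrder(names(cnt))]
    } else {
        cnt <- integer()
    }
    new("MolecularFormula", counts = cnt)
}

.hillOrder <- function(symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    match(c(intersect(c("C", "H"), symbols), rest), symbols)
}

#' Element counts of a formula
#' @param formula A [MolecularFormula-class].
#' @return Named integer vector.
#' @export
formulaCounts <- function(formula) {
    stopifnot(is(formula, "MolecularFormula"))
    formula@counts
}

#' Parse a molecular-formula string
#'
#' Accepts three dialects, all normalized to the same canonical composition:
#' plain Hill notation (`"C6H8O7"`), Unicode subscript digits
#' (`"C₆H₈O₇"`), and underscore-delimited counts
#' (`"C_6_H_8_O_7_"`) as found in typeset tables.
#'
#' @param text a single non-empty formula string.
#' @return A [MolecularFormula-class].
#' @examples
#' formulaCounts(parseFormula("C6H8O7"))
#' formulaCounts(parseFormula("C_27_H_30_O_16_"))
#' @export
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("'text' must be a single string")
    txt <- gsub("_", "", text, fixed = TRUE)
    for (i in seq_along(.SUBSCRIPT_DIGITS))
        txt <- gsub(.SUBSCRIPT_DIGITS[i], as.character(i - 1L), txt,
                    fixed = TRUE)
    txt <- gsub("[[:space:]]", "", txt)
    if (!nzchar(txt)) stop("empty formula string")
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", txt)[[1]]
    tokens <- regmatches(txt, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(txt) || !length(tokens))
        stop("malformed formula string: '", text, "'")
    syms <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Z][a-z]?", "", tokens)
    cnt <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
    if (any(is.na(cnt))) stop("malformed count in formula '", text, "'")
    unknown <- setdiff(syms, names(.ELEMENT_MASSES))
    if (length(unknown))
        stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    counts <- tapply(cnt, syms, sum)
    molecularFormula(stats::setNames(as.integer(counts), names(counts)))
}

#' Serialize a formula in Hill notation
#' @param formula A [MolecularFormula-class].
#' @return A string such as `"C6H8O7"` (empty formula -> `""`).
#' @export
hillFormula <- function(formula) {
    cnt <- formulaCounts(formula)
    if (!length(cnt)) return("")
    paste0(names(cnt), ifelse(cnt > 1L, cnt, ""), collapse = "")
}

setMethod("show", "MolecularFormula", function(object) {
    cat("MolecularFormula:", hillFormula(object),
        sprintf("(%.6f Da)\n", monoisotopicMass(object)))
})

#' Formula arithmetic
#'
#' Element-wise addition, subtraction and integer scaling of compositions.
#' Subtraction errors rather than yielding a negative count.
#'
#' @param f1,f2,formula [MolecularFormula-class] objects.
#' @param n non-negative integer multiplier.
#' @return A [MolecularFormula-class].
#' @export
formulaAdd <- function(f1, f2) {
    c1 <- formulaCounts(f1); c2 <- formulaCounts(f2)
    syms <- union(names(c1), names(c2))
    out <- stats::setNames(integer(length(syms)), syms)
    out[names(c1)] <- out[names(c1)] + c1
    out[names(c2)] <- out[names(c2)] + c2
    molecularFormula(out)
}

#' @rdname formulaAdd
#' @export
formulaSubtract <- function(f1, f2) {
    c1 <- formulaCounts(f1); c2 <- formulaCounts(f2)
    syms <- union(names(c1), names(c2))
    out <- stats::setNames(integer(length(syms)), syms)
    out[names(c1)] <- out[names(c1)] + c1
    out[names(c2)] <- out[names(c2)] - c2
    if (any(out < 0L))
        stop("formula subtraction would yield a negative element count")
    molecularFormula(out)
}

#' @rdname formulaAdd
#' @export
formulaMultiply <- function(formula, n) {
    stopifnot(length(n) == 1L, n >= 0, n == round(n))
    molecularFormula(formulaCounts(formula) * as.integer(n))
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass.
#'
#' @param formula A [MolecularFormula-class] (or a formula string, parsed
#'   on the fly).
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("H2O"))  # 18.010565
#' @export
monoisotopicMass <- function(formula) {
    if (is.character(formula)) formula <- parseFormula(formula)
    cnt <- formulaCounts(formula)
    if (!length(cnt)) return(0)
    sum(cnt * .ELEMENT_MASSES[names(cnt)])
}

# ---- Adducts -----------------------------------------------------------

.ADDUCT_REGISTRY <- list(
    "[M-H]-"     = list(delta = -.PROTON_MASS,                 polarity = "negative"),
    "[M+H]+"     = list(delta = +.PROTON_MASS,                 polarity = "positive"),
    "[M-H2O+H]+" = list(delta = -.WATER_MASS + .PROTON_MASS,   polarity = "positive"),
    "[M+NH4]+"   = list(delta = +.AMMONIUM_MASS,               polarity = "positive")
)

.normalizeAdductName <- function(name) {
    x <- gsub("[[:space:]]", "", name)
    # tolerate the unicode minus and subscripted water occasionally seen in
    # typeset adduct labels
    x <- gsub("−", "-", x)
    x <- gsub("H₂O", "H2O", x)
    x
}

#' Adduct specification
#'
#' Looks up (or constructs) the mass delta and polarity of an ionization
#' adduct. Built-in adducts: `[M-H]-`, `[M+H]+`, `[M-H2O+H]+`, `[M+NH4]+`
#' (proton-mass charge-carrier convention, the electron mass travelling with
#' the charge agent). Additional adducts can be declared by passing `delta`
#' and `polarity` explicitly.
#'
#' @param name adduct label.
#' @param delta,polarity optional explicit mass delta (Da, signed) and
#'   polarity ("positive"/"negative") for adducts outside the registry.
#' @return A list with elements `name`, `delta`, `polarity`.
#' @export
adductSpec <- function(name, delta = NULL, polarity = NULL) {
    key <- .normalizeAdductName(name)
    if (is.null(delta)) {
        spec <- .ADDUCT_REGISTRY[[key]]
        if (is.null(spec)) stop("unsupported adduct: '", name, "'")
        return(list(name = key, delta = spec$delta, polarity = spec$polarity))
    }
    stopifnot(is.numeric(delta), length(delta) == 1L,
              polarity %in% c("positive", "negative"))
    list(name = key, delta = delta, polarity = polarity)
}

#' Theoretical adduct m/z
#'
#' Monoisotopic mass of the neutral formula plus the adduct's charge-carrier
#' delta (singly charged ions only).
#'
#' @param formula A [MolecularFormula-class] or formula string.
#' @param adduct adduct label or the list returned by [adductSpec()].
#' @return m/z in Da.
#' @examples
#' adductMz("C6H8O7", "[M-H]-")   # 191.0197, citric acid
#' adductMz("C6H13NO2", "[M+H]+") # 132.1019, leucine
#' @export
adductMz <- function(formula, adduct) {
    if (is.character(adduct)) adduct <- adductSpec(adduct)
    monoisotopicMass(formula) + adduct$delta
}

#' Mass error between an experimental and a theoretical m/z
#'
#' @param experimentalMz,theoreticalMz positive m/z values (Da).
#' @return A list with `deltaDa` (signed, experimental - theoretical) and
#'   `deltaPpm` (`deltaDa / theoreticalMz * 1e6`).
#' @examples
#' massError(191.0213, 191.0197)$deltaDa  # +0.0016
#' @export
massError <- function(experimentalMz, theoreticalMz) {
    if (any(experimentalMz <= 0) || any(theoreticalMz <= 0))
        stop("m/z values must be positive")
    dDa <- experimentalMz - theoreticalMz
    list(deltaDa = dDa, deltaPpm = dDa / theoreticalMz * 1e6)
}
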