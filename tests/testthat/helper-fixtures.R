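# Independent monoisotopic mass table used as an oracle in tests (kept
# separate from the package's embedded constants on purpose).
ORACLE_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)
ORACLE_PROTON <- 1.00727646

oracleMass <- function(counts) sum(counts * ORACLE_MASS[names(counts)])

# a minimal single-compound recipe
tinyRecipe <- function(area = 1e6, rt = 2, sigma = 0.05, mz = 301.0354,
                       scanInterval = 0.01, noiseLevel = 0, seed = 11L,
                       acquisition = "DDA",
                       frags = cbind(c(151.0037, 179.0), c(100, 50))) {
    cmp <- data.frame(name = "test compound", mz = mz, rt = rt,
                      sigma = sigma, area = area, stringsAsFactors = FALSE)
    cmp$frags <- list(frags)
    runRecipe("S1", cmp, gradientLength = 4, scanInterval = scanInterval,
              noiseLevel = noiseLevel, seed = seed,
              acquisition = acquisition)
}

randomMspRecord <- function(i) {
    n <- 2L + i %% 5L
    mzs <- sort(round(stats::runif(n, 60, 600), 4))
    mspRecord(name = sprintf("compound %d", i),
              formula = sprintf("C%dH%dO%d", 5 + i %% 10, 6 + i %% 12,
                                2 + i %% 6),
              precursorMz = round(stats::runif(1, 100, 700), 4),
              precursorType = sample(c("[M-H]-", "[M+H]+"), 1),
              ionMode = sample(c("negative", "positive"), 1),
              retentionTime = round(stats::runif(1, 0.5, 14), 2),
              peaks = cbind(mzs, round(stats::runif(n, 1, 100), 1)),
              extra = c(Comment = sprintf("synthetic record %d", i)))
}
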