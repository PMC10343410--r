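# brute-force assignment oracle: enumerate all injective query->library
# mappings within tolerance, keep those with the maximum number of pairs and
# the minimum total |delta|
bruteMatch <- function(q, l, tol) {
    best <- list(n = -1, cost = Inf, pairs = NULL)
    recurse <- function(qi, usedL, pairs, cost) {
        if (qi > length(q)) {
            n <- nrow(pairs)
            if (n > best$n || (n == best$n && cost < best$cost))
                best <<- list(n = n, cost = cost, pairs = pairs)
            return(invisible())
        }
        recurse(qi + 1L, usedL, pairs, cost)  # leave query peak unmatched
        for (li in seq_along(l)) {
            if (usedL[li] || abs(q[qi] - l[li]) > tol) next
            u <- usedL; u[li] <- TRUE
            recurse(qi + 1L, u,
                    rbind(pairs, data.frame(queryIdx = qi, libraryIdx = li)),
                    cost + abs(q[qi] - l[li]))
        }
    }
    recurse(1L, logical(length(l)),
            data.frame(queryIdx = integer(), libraryIdx = integer()), 0)
    best
}

test_that("greedy peak pairing matches printed fragment pairs", {
    m <- matchPeaks(cbind(c(151.0042, 169.0170, 179.0004), c(100, 80, 60)),
                    cbind(c(151.0037, 169.0135, 178.9996), c(100, 80, 60)))
    expect_equal(nrow(m$pairs), 3)
    expect_length(m$unmatchedQuery, 0)
    q <- cbind(c(100, 200, 300), c(1, 1, 1))
    ident <- matchPeaks(q, q)
    expect_equal(ident$pairs$deltaMz, c(0, 0, 0))
    disjoint <- matchPeaks(q, q + 1)
    expect_equal(nrow(disjoint$pairs), 0)
    expect_equal(disjoint$unmatchedLibrary, 1:3)
})

test_that("greedy pairing equals the optimal assignment on small instances", {
    set.seed(7)
    for (i in 1:25) {
        nq <- sample(1:5, 1); nl <- sample(1:5, 1)
        # well-separated m/z (gaps >> tol) with small jitter
        q <- sort(sample(seq(100, 500, by = 1), nq)) +
            stats::runif(nq, -0.004, 0.004)
        l <- sort(sample(seq(100, 500, by = 1), nl)) +
            stats::runif(nl, -0.004, 0.004)
        g <- matchPeaks(cbind(q, 1), cbind(l, 1), tol = 0.01)
        b <- bruteMatch(q, l, tol = 0.01)
        expect_equal(nrow(g$pairs), b$n)
        if (b$n > 0)
            expect_equal(g$pairs[, c("queryIdx", "libraryIdx")],
                         b$pairs[order(b$pairs$queryIdx), ],
                         ignore_attr = TRUE)
    }
})

test_that("cosine similarity has its defining properties", {
    s <- cbind(c(100, 200, 300), c(10, 40, 20))
    expect_equal(cosineScore(s, s)$score, 1)
    # scale invariance in either argument
    expect_equal(cosineScore(s, cbind(s[, 1], s[, 2] * 37))$score, 1)
    # symmetry
    t <- cbind(c(100, 200, 410), c(5, 80, 30))
    expect_equal(cosineScore(s, t)$score, cosineScore(t, s)$score)
    # hand-computed two-peak value
    expect_equal(cosineScore(cbind(c(100, 200), c(1.0, 0.5)),
                             cbind(c(100, 200), c(0.5, 1.0)))$score, 0.8,
                 tolerance = 1e-12)
    # no shared peaks
    expect_equal(cosineScore(s, s + 5)$score, 0)
    expect_warning(res <- cosineScore(matrix(numeric(), 0, 2), s), "empty")
    expect_equal(res$score, 0)
})

test_that("DDA spectrum selection picks the nearest in-window precursor scan", {
    run <- generateRun(tinyRecipe(mz = 191.0213, rt = 1.2,
                                  frags = cbind(c(57.0353, 87.0092,
                                                  111.0094, 191.0198),
                                                c(100, 80, 60, 40)),
                                  scanInterval = 0.02))
    s <- selectDdaSpectrum(run, 191.0197, c(1.0, 1.4))
    expect_false(is.null(s))
    expect_equal(sort(peaksOf(s)[, 1]),
                 c(57.0353, 87.0092, 111.0094, 191.0198))
    expect_null(selectDdaSpectrum(run, 500.0, c(1.0, 1.4)))
    expect_null(selectDdaSpectrum(run, 191.0197, c(3.0, 3.5)))
    # two candidate scans: nearer to the window centre wins
    mk <- function(id, rt) msSpectrum(id, 2, "DDA_MS2", rt, "negative",
                                      cbind(100 + id, 10),
                                      precursorMz = 250.1)
    run2 <- lcmsRun("S", list(mk(1, 1.0), mk(2, 1.18)))
    sel <- selectDdaSpectrum(run2, 250.1, c(1.0, 1.3))
    expect_equal(sel@scanId, 2L)
})

test_that("DIA pseudo-spectra keep co-eluting and drop shifted fragments", {
    rec <- tinyRecipe(acquisition = "DIA", scanInterval = 0.02,
                      noiseLevel = 0)
    # second compound elutes 1 minute later with its own fragment
    cmp <- rbind(rec$compounds, rec$compounds)
    cmp$mz <- c(301.0354, 415.1)
    cmp$rt <- c(2, 3)
    cmp$frags <- list(cbind(c(151.0037, 179.0), c(100, 50)),
                      cbind(255.5, 100))
    rec$compounds <- cmp
    run <- generateRun(rec)
    eic <- extractEic(run, 301.0354)
    ft <- detectPeaks(eic)[1, ]
    ps <- diaPseudoSpectrum(run, eic, ft)
    expect_setequal(round(ps[, 1], 4), c(151.0037, 179.0))
    expect_false(any(abs(ps[, 1] - 255.5) < 0.01))
    # correlation with the precursor trace is ~1 by construction
    expect_equal(nrow(ps), 2)
    expect_error(diaPseudoSpectrum(generateRun(tinyRecipe()), eic, ft),
                 "no DIA_HIGH")
})

test_that("diagnostic-ion checks require every listed ion", {
    spec <- cbind(c(300.9976, 463.0514), c(100, 40))
    expect_true(diagnosticIonCheck(spec, 300.9990, tolDa = 0.01)$ok)
    expect_false(diagnosticIonCheck(spec, c(300.9990, 999.0))$ok)
    expect_equal(diagnosticIonCheck(spec, c(300.9990, 999.0))$matched,
                 300.9990)
    expect_true(diagnosticIonCheck(spec, 300.9976, tolDa = 0)$ok)
    expect_error(diagnosticIonCheck(spec, numeric()), "no diagnostic ions")
})
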