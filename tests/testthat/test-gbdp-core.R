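# The distance machinery: e-value filtering, greedy-with-trimming,
# coverage, the three formulas, symmetrization and the all-pairs matrix.

simple_ms <- function(rows, qlen = 1000L, slen = 1000L) {
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    make_matchset(df, qlen, slen)
}

hsp_row <- function(qs, qe, ss, se, score, ident = NULL, strand = "+",
                    log10e = -30) {
    len <- qe - qs + 1L
    list(qStart = qs, qEnd = qe, sStart = ss, sEnd = se, strand = strand,
         alnLength = len, identities = if (is.null(ident)) len else ident,
         score = score, log10Evalue = log10e)
}

test_that("e-value filtering drops strictly above the cutoff only", {
    ms <- simple_ms(list(hsp_row(1L, 50L, 1L, 50L, 90, log10e = -5),
                         hsp_row(101L, 150L, 101L, 150L, 80, log10e = -1),
                         hsp_row(201L, 250L, 201L, 250L, 70, log10e = -3)))
    expect_identical(matchCount(filterByEvalue(ms, 1e-2)), 2L)
    # equality at the cutoff is retained
    ms2 <- simple_ms(list(hsp_row(1L, 50L, 1L, 50L, 90, log10e = -2)))
    expect_identical(matchCount(filterByEvalue(ms2, 1e-2)), 1L)
    # MUMs (no e-value) pass unchanged
    mum <- simple_ms(list(hsp_row(1L, 50L, 1L, 50L, NA_real_,
                                  log10e = NA_real_)))
    expect_identical(matchCount(filterByEvalue(mum, 1e-300)), 1L)
})

test_that("trimming keeps disjoint matches unchanged and halves an overlap", {
    ms <- simple_ms(list(hsp_row(1L, 100L, 1L, 100L, 100),
                         hsp_row(301L, 400L, 301L, 400L, 50)))
    out <- greedyTrim(ms)
    expect_identical(matchCount(out), 2L)
    expect_identical(metadata(out)$trim[["trimmed"]], 0L)
    expect_identical(as.data.frame(matchTable(out)),
                     as.data.frame(matchTable(ms)))

    # B's query half overlaps accepted A; subject side disjoint
    ms2 <- simple_ms(list(hsp_row(1L, 200L, 301L, 500L, 100, ident = 180L),
                          hsp_row(101L, 300L, 601L, 800L, 50, ident = 180L)))
    out2 <- greedyTrim(ms2)
    df <- as.data.frame(matchTable(out2))
    b <- df[df$score < 100, ]
    expect_identical(b$qStart, 201L)
    expect_identical(b$qEnd, 300L)
    expect_identical(b$alnLength, 100L)   # halved
    expect_identical(b$identities, 90L)   # halved, rounded half-up
    expect_identical(metadata(out2)$trim[["trimmed"]], 1L)

    # full containment on the query side: dropped
    ms3 <- simple_ms(list(hsp_row(1L, 200L, 1L, 200L, 100),
                          hsp_row(51L, 150L, 501L, 600L, 40)))
    out3 <- greedyTrim(ms3)
    expect_identical(matchCount(out3), 1L)
    expect_identical(metadata(out3)$trim[["dropped"]], 1L)
})

test_that("trimming equals the independent reference on random match sets", {
    withr::local_seed(2024)
    for (trial in 1:200) {
        ms <- random_matchset(sample(1:8, 1L))
        out <- greedyTrim(ms)
        expect_two_sided_disjoint(out)
        got <- as.data.frame(matchTable(out))
        ref <- ref_greedy_trim(ms)
        rownames(got) <- rownames(ref) <- NULL
        expect_equal(got[, c("qStart", "qEnd", "sStart", "sEnd", "strand",
                             "alnLength", "identities")],
                     ref[, c("qStart", "qEnd", "sStart", "sEnd", "strand",
                             "alnLength", "identities")],
                     info = paste("trial", trial))
        expect_equal(got$score, ref$score, tolerance = 1e-12)
    }
})

test_that("coverage is the union length of match intervals", {
    ms <- simple_ms(list(hsp_row(101L, 300L, 1L, 200L, 50),
                         hsp_row(201L, 400L, 501L, 700L, 40)))
    expect_identical(coverageBases(ms, "query"), 300L)
    expect_identical(coverageBases(ms, "subject"), 400L)
    empty <- make_matchset(data.frame(), 1000L, 1000L)
    expect_identical(coverageBases(empty, "query"), 0L)
})

test_that("coverage equals a position-by-position bitmap count", {
    withr::local_seed(11)
    ms <- random_matchset(1000L, qlen = 10000L, slen = 10000L)
    expect_identical(coverageBases(ms, "query"),
                     ref_coverage(ms, "query"))
    expect_identical(coverageBases(ms, "subject"),
                     ref_coverage(ms, "subject"))
})

test_that("the three formulas give the worked-example distances", {
    ms <- simple_ms(list(hsp_row(1L, 200L, 1L, 200L, 100, ident = 180L)))
    p <- function(f) GbdpParams(algorithm = "trimming", formula = f)
    r1 <- distanceFromMatches(ms, p(1L))
    r2 <- distanceFromMatches(ms, p(2L))
    r3 <- distanceFromMatches(ms, p(3L))
    expect_equal(r1$ratio, 0.2, tolerance = 1e-15)
    expect_equal(r1$d, 0.8, tolerance = 1e-15)
    expect_equal(r2$ratio, 0.9, tolerance = 1e-15)
    expect_equal(r2$d, 0.1, tolerance = 1e-15)
    expect_equal(r3$ratio, 0.18, tolerance = 1e-15)
    expect_equal(r3$d, 0.82, tolerance = 1e-15)
})

test_that("no surviving matches saturates the distance at 1", {
    empty <- make_matchset(data.frame(), 1000L, 1000L)
    for (f in 1:3)
        expect_identical(
            distanceFromMatches(empty, GbdpParams(formula = f))$d, 1)
    # and the log option saturates at the cap
    expect_identical(
        distanceFromMatches(empty, GbdpParams(formula = 1L, useLog = TRUE))$d,
        99)
})

test_that("formula 2 is invariant under appended unmatched sequence", {
    df <- data.frame(qStart = 1L, qEnd = 200L, sStart = 1L, sEnd = 200L,
                     strand = "+", alnLength = 200L, identities = 180L,
                     score = 100, log10Evalue = -30)
    short <- make_matchset(df, 1000L, 1000L)
    long <- make_matchset(df, 3000L, 1500L)  # unmatched sequence appended
    for (mode in c("min", "average")) {
        p2 <- GbdpParams(formula = 2L, lengthMode = mode)
        expect_identical(distanceFromMatches(short, p2)$d,
                         distanceFromMatches(long, p2)$d)
        for (f in c(1L, 3L)) {
            pf <- GbdpParams(formula = f, lengthMode = mode)
            expect_gt(distanceFromMatches(long, pf)$d,
                      distanceFromMatches(short, pf)$d)
        }
    }
})

test_that("distances and ratios stay in [0,1]; evidence is monotone", {
    withr::local_seed(17)
    for (trial in 1:25) {
        ms <- greedyTrim(random_matchset(sample(1:8, 1L)))
        for (f in 1:3) {
            r <- distanceFromMatches(ms, GbdpParams(formula = f))
            expect_gte(r$ratio, 0); expect_lte(r$ratio, 1)
            expect_gte(r$d, 0);     expect_lte(r$d, 1)
        }
    }
    # adding a disjoint identity-bearing match never increases d (1) and (3)
    base <- simple_ms(list(hsp_row(1L, 100L, 1L, 100L, 100, ident = 90L)))
    more <- simple_ms(list(hsp_row(1L, 100L, 1L, 100L, 100, ident = 90L),
                           hsp_row(501L, 600L, 501L, 600L, 80, ident = 85L)))
    for (f in c(1L, 3L)) {
        p <- GbdpParams(formula = f)
        expect_lte(distanceFromMatches(more, p)$d,
                   distanceFromMatches(base, p)$d)
    }
})

test_that("symmetrization is the arithmetic mean and idempotent", {
    expect_equal(symmetrizeDistance(0.2, 0.4), 0.3, tolerance = 1e-15)
    for (x in c(0, 0.123, 1)) expect_identical(symmetrizeDistance(x, x), x)
})

test_that("the full pipeline is direction-symmetric", {
    pr <- evolvePair(5000, substitutionRate = 0.05, seed = 5)
    for (setup in list(list(p = GbdpParams(formula = 2L), e = "hsp"),
                       list(p = GbdpParams(algorithm = "coverage",
                                           formula = 1L), e = "mum"))) {
        ab <- gbdpDistance(pr$ancestor, pr$derived, setup$p, setup$e)
        ba <- gbdpDistance(pr$derived, pr$ancestor, setup$p, setup$e)
        expect_equal(distanceValue(ab), distanceValue(ba), tolerance = 1e-12)
    }
})

test_that("distance matrices are symmetric, composable and label-checked", {
    g1 <- randomGenome(2000, seed = 71, label = "A")
    g2 <- Genome(setNames(as.character(g1)[[1L]], "chr1"), label = "B")
    g3 <- randomGenome(2000, seed = 73, label = "C")
    m <- distanceMatrix(list(g1, g2, g3))
    expect_identical(dim(m), c(3L, 3L))
    expect_identical(unname(diag(m)), rep(0, 3L))
    expect_identical(m["A", "B"], 0)  # identical genomes
    d13 <- distanceValue(gbdpDistance(g1, g3))
    expect_identical(m["A", "C"], d13)
    expect_error(distanceMatrix(list(g1, g1)), "duplicate")
})

test_that("divergence ordering is recovered on an evolved family", {
    # same seed -> same ancestor at every rate
    anc <- evolvePair(5000, substitutionRate = 0.01, seed = 9)$ancestor
    copies <- lapply(c(0.01, 0.05, 0.10), function(rate) {
        pr <- evolvePair(5000, substitutionRate = rate, seed = 9)
        Genome(setNames(as.character(pr$derived)[[1L]], "chr1"),
               label = sprintf("r%.2f", rate))
    })
    d2 <- vapply(copies, function(g)
        distanceValue(gbdpDistance(anc, g, GbdpParams(formula = 2L))),
        numeric(1))
    expect_true(all(diff(d2) > 0))
})

test_that("MUM sources warn for identity-based formulas", {
    g <- randomGenome(1000, seed = 81, label = "g")
    expect_warning(gbdpDistance(g, g, GbdpParams(formula = 2L),
                                engine = "mum"),
                   "degenerate")
})
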