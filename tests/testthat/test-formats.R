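# Genome and match-file I/O: FASTA normalization, the CGVIZ dialect,
# BLAST tabular and MUMmer ingestion, Phylip/Nexus matrix output.

test_that("FASTA reading normalizes case and alphabet and sums lengths", {
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">chr1 extra description", "ACG", ">plasmid", "acgtn"), fa)
    g <- readGenome(fa, label = "toy")
    expect_s4_class(g, "Genome")
    expect_identical(totalLength(g), 8L)
    expect_identical(names(g), c("chr1", "plasmid"))
    expect_identical(as.character(g)[["plasmid"]], "ACGTN")

    writeLines(c(">r", "ACRGT"), fa)
    expect_warning(g2 <- readGenome(fa), "replaced by N")
    expect_identical(as.character(g2)[["r"]], "ACNGT")
})

test_that("FASTA format errors are raised for empty and zero-length input", {
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(character(), fa)
    expect_error(readGenome(fa), "FASTA")
    writeLines(c(">a", ">b", "ACGT"), fa)
    expect_error(readGenome(fa), "zero-length")
})

test_that("CGVIZ stores log10 e-values and 1-based coordinates", {
    df <- data.frame(qStart = 1L, qEnd = 10L, sStart = 21L, sEnd = 30L,
                     strand = "+", alnLength = 10L, identities = 9L,
                     score = 12, log10Evalue = log10(1e-5))
    ms <- make_matchset(df, qlen = 100L, slen = 100L)
    f <- withr::local_tempfile(fileext = ".cgviz")
    writeCgviz(ms, f)
    lines <- readLines(f)
    expect_identical(lines[[1L]], "#cgviz 1")
    body <- lines[!startsWith(lines, "#")]
    fields <- strsplit(body, "\t")[[1L]]
    expect_identical(fields[3:6], c("1", "10", "21", "30"))
    expect_equal(as.numeric(fields[[11L]]), -5)
})

test_that("CGVIZ round-trip is the identity on MatchSets", {
    withr::local_seed(42)
    ms <- random_matchset(50L)
    f <- withr::local_tempfile(fileext = ".cgviz")
    writeCgviz(ms, f)
    back <- readCgviz(f)
    expect_identical(matchCount(back), 50L)
    expect_identical(queryLabel(back), queryLabel(ms))
    expect_identical(queryLength(back), queryLength(ms))
    a <- as.data.frame(matchTable(ms))
    b <- as.data.frame(matchTable(back))
    for (col in c("qRecord", "sRecord", "qStart", "qEnd", "sStart", "sEnd",
                  "strand", "alnLength", "identities"))
        expect_identical(b[[col]], a[[col]], info = col)
    expect_equal(b$score, a$score, tolerance = 1e-9)
    expect_equal(b$log10Evalue, a$log10Evalue, tolerance = 1e-9)
})

test_that("CGVIZ MUM lines omit identities/score/e-value and read back", {
    df <- data.frame(qStart = 5L, qEnd = 64L, sStart = 11L, sEnd = 70L,
                     strand = "-", alnLength = 60L, identities = 60L,
                     score = NA_real_, log10Evalue = NA_real_)
    ms <- make_matchset(df, 100L, 100L, source = "builtin-mum")
    f <- withr::local_tempfile()
    writeCgviz(ms, f)
    body <- readLines(f)
    body <- body[!startsWith(body, "#")]
    expect_identical(strsplit(body, "\t")[[1L]][9:11], c(".", ".", "."))
    back <- readCgviz(f)
    df2 <- as.data.frame(matchTable(back))
    expect_identical(df2$identities, 60L)  # restored from alnLength
    expect_true(is.na(df2$score) && is.na(df2$log10Evalue))
})

test_that("CGVIZ validation rejects missing header and bad coordinates", {
    f <- withr::local_tempfile()
    writeLines(c("#query a 100", "#subject b 100"), f)
    expect_error(readCgviz(f), "#cgviz")
    writeLines(c("#cgviz 1", "#query a 1000", "#subject b 1000",
                 paste(c("r1", "r2", "100", "1200", "1", "50", "+", "50",
                         "50", ".", "."), collapse = "\t")), f)
    expect_error(readCgviz(f), "beyond declared record length")
})

test_that("BLAST tabular parsing follows the coordinate/e-value contracts", {
    g_q <- Genome(c(q1 = strrep("A", 1000)), label = "Q")
    g_s <- Genome(c(s1 = strrep("A", 1000)), label = "S")
    f <- withr::local_tempfile()
    rows <- c(
        paste(c("q1", "s1", "90.0", "200", "20", "0", "1", "200", "301",
                "500", "1e-50", "370"), collapse = "\t"),
        paste(c("q1", "s1", "100.0", "100", "0", "0", "10", "109", "500",
                "401", "0.0", "185"), collapse = "\t"))
    writeLines(rows, f)
    ms <- parseBlastTabular(f, g_q, g_s)
    df <- as.data.frame(matchTable(ms))
    expect_identical(df$identities[[1L]], 180L)   # round(pident * len / 100)
    expect_identical(df$strand, c("+", "-"))
    expect_identical(df$sStart[[2L]], 401L)       # normalized ascending
    expect_identical(df$sEnd[[2L]], 500L)
    expect_identical(df$log10Evalue[[2L]], -400)  # e-value 0 sentinel

    writeLines("q1\ts1\tbad", f)
    expect_error(parseBlastTabular(f, g_q, g_s), "12")
    writeLines(sub("^q1", "nope", rows[[1L]]), f)
    expect_error(parseBlastTabular(f, g_q, g_s), "unknown")
})

test_that("BLAST tabular ingestion inverts a synthetic row writer", {
    withr::local_seed(101)
    g_q <- Genome(c(q1 = strrep("A", 2000)), label = "Q")
    g_s <- Genome(c(s1 = strrep("A", 2000)), label = "S")
    f <- withr::local_tempfile()
    for (case in seq_len(500L)) {
        len <- sample(30:300, 1L)
        qs <- sample(2000L - len, 1L); ss <- sample(2000L - len, 1L)
        pid <- round(runif(1, 50, 100), 2)
        minus <- runif(1) < 0.5
        ev <- 10^runif(1, -180, 1)
        bits <- round(runif(1, 30, 500), 1)
        row <- paste(c("q1", "s1", sprintf("%.2f", pid), len,
                       len - round(pid * len / 100), 0, qs, qs + len - 1L,
                       if (minus) c(ss + len - 1L, ss) else c(ss, ss + len - 1L),
                       sprintf("%.3g", ev), bits), collapse = "\t")
        writeLines(row, f)
        df <- as.data.frame(matchTable(parseBlastTabular(f, g_q, g_s)))
        expect_identical(df$qStart, qs)
        expect_identical(df$qEnd, qs + len - 1L)
        expect_identical(df$sStart, ss)
        expect_identical(df$sEnd, ss + len - 1L)
        expect_identical(df$strand, if (minus) "-" else "+")
        expect_identical(df$identities, as.integer(round(pid * len / 100)))
        expect_equal(df$log10Evalue, log10(as.numeric(sprintf("%.3g", ev))))
    }
})

test_that("MUMmer match files parse with 1-based starts and strand blocks", {
    g_q <- Genome(c(q1 = strrep("A", 2000)), label = "Q")
    g_s <- Genome(c(s1 = strrep("A", 2000)), label = "S")
    f <- withr::local_tempfile()
    writeLines(c("> q1", "  1201    88    44",
                 "> q1 Reverse", "  501    120    50"), f)
    ms <- parseMummer(f, g_q, g_s)
    df <- as.data.frame(matchTable(ms))
    expect_identical(df$sStart[[1L]], 1201L)
    expect_identical(df$qStart[[1L]], 88L)
    expect_identical(df$qEnd[[1L]], 88L + 44L - 1L)
    expect_identical(df$identities[[1L]], 44L)
    expect_true(all(is.na(df$score)))
    expect_identical(df$strand, c("+", "-"))
    expect_true(all(df$sEnd >= df$sStart))

    writeLines("> q1\nabc def ghi", f)
    expect_error(parseMummer(f, g_q, g_s), "malformed")
    writeLines(character(), f)
    expect_identical(matchCount(parseMummer(f, g_q, g_s)), 0L)
})

test_that("Phylip and Nexus writers round-trip the matrix values", {
    m <- matrix(c(0, 0.25, 0.25, 0), 2L, 2L)
    labs <- c("Escherichia coli", "E albertii")
    fp <- withr::local_tempfile(); fn <- withr::local_tempfile()
    writePhylip(labs, m, fp)
    lines <- readLines(fp)
    expect_identical(trimws(lines[[1L]]), "2")
    vals <- as.numeric(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]][-1L])
    expect_equal(vals, c(0, 0.25), tolerance = 1e-6)

    writeNexus(labs, m, fn)
    back <- ref_read_nexus_dist(fn)
    expect_equal(unname(back), unname(m), tolerance = 1e-6)
    expect_identical(rownames(back), sanitizeLabels(labs))

    # degenerate 1x1 matrix is valid output
    writePhylip("solo", matrix(0, 1L, 1L), fp)
    expect_identical(trimws(readLines(fp)[[1L]]), "1")

    bad <- matrix(c(0, 0.2, 0.3, 0), 2L, 2L)
    expect_error(writePhylip(labs, bad, fp), "asymmetric")
})

test_that("matrix writers agree with inputs on random matrices", {
    withr::local_seed(7)
    for (rep in 1:5) {
        n <- sample(2:6, 1L)
        m <- matrix(0, n, n)
        m[upper.tri(m)] <- round(runif(n * (n - 1) / 2), 4)
        m <- m + t(m)
        labs <- paste0("tax ", seq_len(n))
        fn <- withr::local_tempfile()
        writeNexus(labs, m, fn)
        expect_equal(unname(ref_read_nexus_dist(fn)), unname(m),
                     tolerance = 1e-6)
    }
})
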