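# Independent reference implementations and fixture builders used across
# the suite.  These deliberately share no code with the package internals:
# trimming is re-derived with per-position bitmaps, coverage with a boolean
# array, MUMs by diagonal run enumeration plus Biostrings pattern counting.

# -- fixture builders --------------------------------------------------------

# a MatchSet over two single-record genomes from a plain data.frame of
# equal-span matches (columns qStart, qEnd, sStart, sEnd, strand, alnLength,
# identities, score, log10Evalue)
make_matchset <- function(df, qlen = 1000L, slen = 1200L,
                          source = "synthetic") {
    if (nrow(df)) {
        df$qRecord <- "q1"
        df$sRecord <- "s1"
    }
    MatchSet(c(q1 = as.integer(qlen)), c(s1 = as.integer(slen)), df,
             source = source, queryLabel = "Q", subjectLabel = "S")
}

# random equal-span match sets for trimming/coverage property tests
random_matchset <- function(n, qlen = 1000L, slen = 1200L) {
    len <- sample(20:150, n, replace = TRUE)
    qs <- vapply(len, function(l) sample(qlen - l, 1L), integer(1))
    ss <- vapply(len, function(l) sample(slen - l, 1L), integer(1))
    ident <- pmax(1L, len - sample(0:10, n, replace = TRUE))
    df <- data.frame(
        qStart = qs, qEnd = qs + len - 1L,
        sStart = ss, sEnd = ss + len - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        alnLength = len, identities = ident,
        # small score range on purpose: ties exercise the tie-breaks
        score = as.numeric(sample(10:40, n, replace = TRUE)),
        log10Evalue = runif(n, -50, -3))
    make_matchset(df, qlen, slen)
}

# -- greedy-with-trimming reference -----------------------------------------

# independently coded reference for the trimming rules: process matches in
# descending score order (ties: longer, then qStart, then sStart), keep for
# each match the longest contiguous part free on both genomes, rescale
# statistics by the retained query fraction (round half-up), drop below
# min_residual.  Equal-span matches only (all generated fixtures are).
ref_greedy_trim <- function(ms, min_residual = 1L) {
    df <- as.data.frame(matchTable(ms))
    if (!nrow(df)) return(df)
    sc <- ifelse(is.na(df$score), as.numeric(df$alnLength), df$score)
    df <- df[order(-sc, -df$alnLength, df$qStart, df$sStart), , drop = FALSE]
    qcov <- rep(FALSE, queryLength(ms))
    scov <- rep(FALSE, subjectLength(ms))
    kept <- list()
    for (i in seq_len(nrow(df))) {
        r <- df[i, ]
        qpos <- r$qStart:r$qEnd
        spos <- if (r$strand == "+") r$sStart:r$sEnd else r$sEnd:r$sStart
        ok <- !qcov[qpos] & !scov[spos]
        # longest run of TRUE (first one on ties)
        best_len <- 0L; best_at <- NA_integer_; run <- 0L
        for (t in seq_along(ok)) {
            run <- if (ok[t]) run + 1L else 0L
            if (run > best_len) { best_len <- run; best_at <- t - run + 1L }
        }
        if (best_len < max(1L, min_residual)) next
        idx <- best_at:(best_at + best_len - 1L)
        qcov[qpos[idx]] <- TRUE
        scov[spos[idx]] <- TRUE
        frac <- best_len / length(qpos)
        r$qStart <- qpos[idx][1L]; r$qEnd <- qpos[idx][best_len]
        r$sStart <- min(spos[idx]); r$sEnd <- max(spos[idx])
        if (best_len < length(qpos)) {
            r$alnLength <- max(1L, as.integer(floor(r$alnLength * frac + 0.5)))
            r$identities <- as.integer(min(floor(r$identities * frac + 0.5),
                                           r$alnLength))
            r$score <- r$score * frac
        }
        kept[[length(kept) + 1L]] <- r
    }
    out <- if (length(kept)) do.call(rbind, kept) else df[0L, ]
    out <- out[order(out$qStart, out$sStart, out$alnLength), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# pairwise disjointness of retained intervals on both genomes
expect_two_sided_disjoint <- function(ms) {
    df <- as.data.frame(matchTable(ms))
    if (nrow(df) < 2L) return(invisible(TRUE))
    olap <- function(st, en) {
        o <- order(st)
        all(st[o][-1L] > en[o][-length(en)])
    }
    expect_true(olap(df$qStart, df$qEnd))
    expect_true(olap(df$sStart, df$sEnd))
}

# -- coverage reference ------------------------------------------------------

ref_coverage <- function(ms, side = "query") {
    df <- as.data.frame(matchTable(ms))
    n <- if (side == "query") queryLength(ms) else subjectLength(ms)
    hit <- rep(FALSE, n)
    st <- if (side == "query") df$qStart else df$sStart
    en <- if (side == "query") df$qEnd else df$sEnd
    for (i in seq_len(nrow(df))) hit[st[i]:en[i]] <- TRUE
    sum(hit)
}

# -- MUM reference -----------------------------------------------------------

# all maximal exact matches of length >= min_len between character strings
# a and b (plus strand of b), by diagonal run enumeration
ref_mems_plus <- function(a, b, min_len) {
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    eq <- outer(av, bv, "==") & outer(av != "N", bv != "N", "&")
    d <- row(eq) - col(eq)
    runs <- list()
    for (g in split(seq_along(eq), as.vector(d))) {
        r <- rle(eq[g])
        if (!any(r$values & r$lengths >= min_len)) next
        ends <- cumsum(r$lengths)
        for (k in which(r$values & r$lengths >= min_len)) {
            first <- g[ends[k] - r$lengths[k] + 1L]
            i0 <- (first - 1L) %% length(av) + 1L
            j0 <- (first - 1L) %/% length(av) + 1L
            runs[[length(runs) + 1L]] <-
                c(qStart = i0, sStart = j0, len = r$lengths[k])
        }
    }
    if (!length(runs)) return(data.frame(qStart = integer(),
                                         sStart = integer(),
                                         len = integer()))
    as.data.frame(do.call(rbind, runs))
}

rc_chr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# occurrences of pat in text counting both strands (overlapping)
ref_occ_both <- function(text, pat) {
    n <- Biostrings::countPattern(pat, Biostrings::DNAString(text))
    rc <- rc_chr(pat)
    if (rc != pat)
        n <- n + Biostrings::countPattern(rc, Biostrings::DNAString(text))
    n
}

# full MUM oracle: maximal exact matches on both strands, then uniqueness
# in both genomes (counting both strands); returns a canonical key set
ref_mums <- function(q, s, min_len) {
    plus <- ref_mems_plus(q, s, min_len)
    plus$strand <- rep("+", nrow(plus))
    minus <- ref_mems_plus(q, rc_chr(s), min_len)
    if (nrow(minus)) {
        ns <- nchar(s)
        send_orig <- ns - minus$sStart + 1L
        minus$sStart <- send_orig - minus$len + 1L
        minus$strand <- "-"
    } else minus$strand <- character()
    all <- rbind(plus, minus)
    if (!nrow(all)) return(character())
    keep <- vapply(seq_len(nrow(all)), function(i) {
        pat <- substr(q, all$qStart[i], all$qStart[i] + all$len[i] - 1L)
        ref_occ_both(q, pat) == 1L && ref_occ_both(s, pat) == 1L
    }, logical(1))
    all <- all[keep, , drop = FALSE]
    sort(sprintf("%d:%d:%d:%s", all$qStart, all$sStart, all$len, all$strand))
}

mum_keys <- function(ms) {
    df <- as.data.frame(matchTable(ms))
    sort(sprintf("%d:%d:%d:%s", df$qStart, df$sStart, df$alnLength,
                 df$strand))
}

# -- generic Nexus DISTANCES reader -----------------------------------------

ref_read_nexus_dist <- function(file) {
    lines <- readLines(file)
    i0 <- grep("MATRIX", lines, fixed = TRUE)[1L]
    rows <- list()
    for (ln in lines[-seq_len(i0)]) {
        ln <- trimws(ln)
        if (ln == ";" || startsWith(ln, "END")) break
        f <- strsplit(ln, "\\s+")[[1L]]
        rows[[f[1L]]] <- as.numeric(f[-1L])
    }
    m <- do.call(rbind, rows)
    dimnames(m) <- list(names(rows), names(rows))
    m
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
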