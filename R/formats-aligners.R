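# Parsers for external similarity-search output (ingestion path).

.meta_side <- function(g, what) {
    if (is(g, "Genome"))
        list(label = genomeLabel(g), lens = setNames(width(g), names(g)))
    else if (is.list(g) && all(c("label", "lens") %in% names(g)))
        g
    else stop("'", what, "' must be a Genome or list(label=, lens=)")
}

#' Parse NCBI-BLAST 12-column tabular output into a MatchSet
#'
#' Expects the standard tabular dialect (\code{-outfmt 6} /
#' \code{-m 8}): \code{qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore}.  Identities are reconstructed as
#' \code{round(pident * length / 100)}; a subject start greater than the
#' subject end encodes a minus-strand hit and is normalised to ascending
#' coordinates with \code{strand == "-"}; e-values are stored as log10,
#' with a reported e-value of 0 mapped to the finite sentinel \code{-400}.
#'
#' @param file path to a BLAST tabular file.
#' @param query,subject the two \linkS4class{Genome}s (or
#'   \code{list(label=, lens=)} metadata) the search was run on.
#' @return A \linkS4class{MatchSet} with source \code{"blast-tab"}.
#' @export
parseBlastTabular <- function(file, query, subject) {
    q <- .meta_side(query, "query"); s <- .meta_side(subject, "subject")
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 12L))
        stop("BLAST tabular rows must have 12 tab-separated columns")
    if (!length(fields)) {
        return(MatchSet(q$lens, s$lens, data.frame(), source = "blast-tab",
                        queryLabel = q$label, subjectLabel = s$label))
    }
    col <- function(i, how = identity) how(vapply(fields, `[[`, character(1), i))
    pident <- col(3, as.numeric); len <- col(4, as.integer)
    ss_raw <- col(9, as.integer); se_raw <- col(10, as.integer)
    minus <- ss_raw > se_raw
    ev <- col(11, as.numeric)
    if (anyNA(ev) || any(ev < 0)) stop("non-numeric or negative e-value")
    df <- data.frame(
        qRecord = col(1), sRecord = col(2),
        qStart = col(7, as.integer), qEnd = col(8, as.integer),
        sStart = ifelse(minus, se_raw, ss_raw),
        sEnd = ifelse(minus, ss_raw, se_raw),
        strand = ifelse(minus, "-", "+"),
        alnLength = len,
        identities = as.integer(round(pident * len / 100)),
        score = col(12, as.numeric),
        log10Evalue = ifelse(ev == 0, -400, log10(ev)),
        stringsAsFactors = FALSE)
    MatchSet(q$lens, s$lens, df, source = "blast-tab",
             queryLabel = q$label, subjectLabel = s$label)
}

#' Parse MUMmer match output into a MatchSet
#'
#' Reads the three-column match dialect produced by
#' \code{mummer -b -c -F -l 44 -mum SUBJECT QUERY}: blocks headed by
#' \code{> <query record>} (a \code{Reverse} suffix marks the
#' reverse-complement section), each match line giving the 1-based start in
#' the subject, the 1-based start on the forward strand of the query, and
#' the match length.  Every line becomes an exact match with
#' \code{identities == alnLength}; MUMs carry no e-value or score.
#' Subject coordinates are taken as genome-global and split back onto the
#' subject's records.
#'
#' @inheritParams parseBlastTabular
#' @param file path to a MUMmer match file.
#' @return A \linkS4class{MatchSet} with source \code{"mummer"}.
#' @export
parseMummer <- function(file, query, subject) {
    q <- .meta_side(query, "query"); s <- .meta_side(subject, "subject")
    lines <- trimws(readLines(file, warn = FALSE))
    lines <- lines[nzchar(lines)]
    cur_rec <- if (length(q$lens) == 1L) names(q$lens)[1L] else NA_character_
    cur_strand <- "+"
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        if (startsWith(ln, ">")) {
            hdr <- trimws(sub("^>", "", ln))
            cur_strand <- if (grepl("Reverse$", hdr)) "-" else "+"
            cur_rec <- trimws(sub("\\s*Reverse$", "", hdr))
            if (!nzchar(cur_rec)) cur_rec <- names(q$lens)[1L]
            next
        }
        f <- strsplit(ln, "\\s+")[[1L]]
        if (length(f) != 3L || anyNA(suppressWarnings(as.numeric(f))))
            stop("malformed MUMmer match line: ", ln)
        v <- as.integer(f)
        rows[[i]] <- data.frame(qRecord = cur_rec, sGlobal = v[[1L]],
                                qStart = v[[2L]], len = v[[3L]],
                                strand = cur_strand, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) {
        return(MatchSet(q$lens, s$lens, data.frame(), source = "mummer",
                        queryLabel = q$label, subjectLabel = s$label))
    }
    m <- do.call(rbind, rows)
    off <- .record_offsets(s$lens)
    # locate the subject record containing each global start
    idx <- findInterval(m$sGlobal, off + 1L)
    df <- data.frame(
        qRecord = m$qRecord, sRecord = names(s$lens)[idx],
        qStart = m$qStart, qEnd = m$qStart + m$len - 1L,
        sStart = m$sGlobal - unname(off[idx]),
        sEnd = m$sGlobal - unname(off[idx]) + m$len - 1L,
        strand = m$strand, alnLength = m$len, identities = m$len,
        score = NA_real_, log10Evalue = NA_real_, stringsAsFactors = FALSE)
    MatchSet(q$lens, s$lens, df, source = "mummer",
             queryLabel = q$label, subjectLabel = s$label)
}
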