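# Condensed CGVIZ match format
#
# Layout:
#   #cgviz 1
#   #query <label> <total_length>
#   #subject <label> <total_length>
#   #qrecord <id> <length>        (optional, one per query record)
#   #srecord <id> <length>        (optional, one per subject record)
#   qRec sRec qStart qEnd sStart sEnd strand alnLength identities score log10E
# Coordinates 1-based inclusive; e-values stored as log10; '.' marks absent
# fields (MUM lines carry no identities/score/e-value).

.fmt_num <- function(x) {
    ifelse(is.na(x), ".", formatC(x, digits = 10, format = "g"))
}

#' Write a MatchSet in the condensed CGVIZ format
#'
#' Stores match coordinates together with the statistical data needed for
#' distance calculation (score, alignment length, identities and the
#' \emph{base-10 logarithm} of the e-value), which is sufficient for all
#' downstream steps while preserving storage space.  MUM lines write
#' \code{.} in the identities/score/e-value fields.
#'
#' @param ms a \linkS4class{MatchSet}.
#' @param file output path or connection.
#' @return \code{file}, invisibly.
#' @seealso [readCgviz()]
#' @export
writeCgviz <- function(ms, file) {
    stopifnot(is(ms, "MatchSet"))
    df <- as.data.frame(matchTable(ms))
    is_mum <- ms@source %in% c("builtin-mum", "mummer") |
        (is.na(df$score) & is.na(df$log10Evalue) & df$identities == df$alnLength)
    idout <- ifelse(nrow(df) > 0 & is_mum, ".", as.character(df$identities))
    lines <- c(
        "#cgviz 1",
        sprintf("#query %s %d", queryLabel(ms), queryLength(ms)),
        sprintf("#subject %s %d", subjectLabel(ms), subjectLength(ms)),
        sprintf("#qrecord %s %d", names(ms@queryLengths), ms@queryLengths),
        sprintf("#srecord %s %d", names(ms@subjectLengths), ms@subjectLengths))
    if (nrow(df))
        lines <- c(lines, paste(df$qRecord, df$sRecord, df$qStart, df$qEnd,
                                df$sStart, df$sEnd, df$strand, df$alnLength,
                                idout, .fmt_num(df$score),
                                .fmt_num(df$log10Evalue), sep = "\t"))
    writeLines(lines, file)
    invisible(file)
}

.num_or_na <- function(x) ifelse(x == ".", NA_real_, suppressWarnings(as.numeric(x)))

#' Read a MatchSet from a CGVIZ file
#'
#' Inverse of [writeCgviz()].  Files lacking the optional per-record header
#' lines are accepted; coordinates are then validated against the declared
#' total genome lengths.
#'
#' @param file path to a CGVIZ file.
#' @return A \linkS4class{MatchSet} with source \code{"cgviz"}.
#' @export
readCgviz <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines) || !grepl("^#cgviz\\s+1\\b", lines[[1L]]))
        stop("missing '#cgviz 1' header")
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    take <- function(tag) {
        m <- hdr[startsWith(hdr, paste0("#", tag, " "))]
        lapply(strsplit(m, "\\s+"), function(f) list(id = f[[2L]],
                                                     len = as.integer(f[[3L]])))
    }
    q <- take("query"); s <- take("subject")
    if (length(q) != 1L || length(s) != 1L)
        stop("CGVIZ header must declare exactly one #query and one #subject line")
    qrec <- take("qrecord"); srec <- take("srecord")
    recs <- function(rec, total, body_ids) {
        if (length(rec))
            setNames(vapply(rec, `[[`, integer(1), "len"),
                     vapply(rec, `[[`, character(1), "id"))
        else setNames(rep(total, length(body_ids)), body_ids)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (length(fields) && any(lengths(fields) != 11L))
        stop("CGVIZ match lines must have 11 tab-separated fields")
    f <- function(i, how = identity) how(vapply(fields, `[[`, character(1), i))
    if (length(fields)) {
        id_raw <- f(9)
        aln <- f(8, as.integer)
        df <- data.frame(
            qRecord = f(1), sRecord = f(2),
            qStart = f(3, as.integer), qEnd = f(4, as.integer),
            sStart = f(5, as.integer), sEnd = f(6, as.integer),
            strand = f(7), alnLength = aln,
            identities = ifelse(id_raw == ".", aln, suppressWarnings(as.integer(id_raw))),
            score = .num_or_na(f(10)), log10Evalue = .num_or_na(f(11)),
            stringsAsFactors = FALSE)
    } else df <- data.frame()
    qlens <- recs(qrec, q[[1L]]$len, unique(df$qRecord))
    slens <- recs(srec, s[[1L]]$len, unique(df$sRecord))
    if (!length(qlens)) qlens <- setNames(q[[1L]]$len, q[[1L]]$id)
    if (!length(slens)) slens <- setNames(s[[1L]]$len, s[[1L]]$id)
    storage.mode(qlens) <- "integer"
    storage.mode(slens) <- "integer"
    MatchSet(qlens, slens, df, source = "cgviz",
             queryLabel = q[[1L]]$id, subjectLabel = s[[1L]]$id)
}
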