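#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors Annotated DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet reverseComplement
#' @importFrom IRanges IRanges reduce width
NULL

#' Genome: a labelled set of replicon sequences
#'
#' A \code{Genome} is a \linkS4class{DNAStringSet} (one entry per chromosome
#' or plasmid) carrying a genome-level label.  Sequences are restricted to
#' the alphabet \code{A,C,G,T,N}; anything else is collapsed to \code{N} at
#' construction time.
#'
#' @slot label single character, the genome identifier used in reports and
#'   distance matrices.
#' @aliases Genome-class
#' @exportClass Genome
setClass("Genome", contains = "DNAStringSet",
         representation(label = "character"))

setValidity("Genome", function(object) {
    msg <- NULL
    if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    if (length(object) < 1L)
        msg <- c(msg, "a Genome needs at least one sequence record")
    if (length(object) && any(width(object) < 1L))
        msg <- c(msg, "zero-length sequence records are not allowed")
    ids <- names(object)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        msg <- c(msg, "every record needs a non-empty id")
    else if (anyDuplicated(ids))
        msg <- c(msg, "record ids must be unique within a genome")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Genome from sequences
#'
#' Input sequences are uppercased and any character outside
#' \code{A,C,G,T} (ambiguity codes, gaps, ...) is replaced by \code{N},
#' with a warning.  \code{N} never counts as an identity anywhere in the
#' package.
#'
#' @param seqs a character vector, \code{DNAStringSet} or anything coercible
#'   to character; names become record ids (defaults \code{seq1}, ...).
#' @param label genome label (single string).
#' @return A \linkS4class{Genome}.
#' @examples
#' g <- Genome(c(chr = "acgtACGT"), label = "toy")
#' totalLength(g)
#' @export
Genome <- function(seqs, label = "genome") {
    nm <- names(seqs)
    chr <- toupper(as.character(seqs))
    names(chr) <- nm
    if (length(chr) < 1L)
        stop("a Genome needs at least one sequence record")
    if (is.null(names(chr)) || any(!nzchar(names(chr))))
        names(chr) <- if (is.null(names(chr))) paste0("seq", seq_along(chr)) else
            ifelse(nzchar(names(chr)), names(chr), paste0("seq", seq_along(chr)))
    bad <- grepl("[^ACGTN]", chr)
    if (any(bad)) {
        n_bad <- sum(vapply(gregexpr("[^ACGTN]", chr[bad]),
                            function(m) sum(m > 0L), integer(1)))
        warning(sprintf("%d non-ACGT character(s) replaced by N", n_bad))
        chr <- gsub("[^ACGTN]", "N", chr)
    }
    new("Genome", DNAStringSet(chr), label = as.character(label))
}

#' @describeIn Genome genome label accessor
#' @param x a Genome
#' @export
genomeLabel <- function(x) x@label

#' @describeIn Genome total genome length in bp (sum of record lengths)
#' @export
totalLength <- function(x) sum(width(x))

setMethod("show", "Genome", function(object) {
    cat(sprintf("Genome '%s': %d record(s), %d bp total\n",
                object@label, length(object), totalLength(object)))
    callNextMethod()
})

#' MatchSet: all matches for one ordered genome pair
#'
#' Holds the HSPs or MUMs found between an ordered (query, subject) genome
#' pair, together with both genomes' labels and record lengths.  The match
#' table is a \code{DataFrame} with columns \code{qRecord}, \code{sRecord},
#' \code{qStart}, \code{qEnd}, \code{sStart}, \code{sEnd} (1-based inclusive,
#' ascending on both genomes), \code{strand} (\code{+}/\code{-}, subject
#' orientation), \code{alnLength}, \code{identities}, \code{score} and
#' \code{log10Evalue} (both \code{NA} for MUMs).
#'
#' @slot queryLabel,subjectLabel genome labels.
#' @slot queryLengths,subjectLengths named integer vectors of record lengths.
#' @slot matches \code{DataFrame} of matches (see above).
#' @slot source one of \code{builtin-hsp}, \code{builtin-mum},
#'   \code{blast-tab}, \code{mummer}, \code{cgviz}.
#' @aliases MatchSet-class
#' @exportClass MatchSet
setClass("MatchSet", contains = "Annotated",
         representation(queryLabel = "character", subjectLabel = "character",
                        queryLengths = "integer", subjectLengths = "integer",
                        matches = "DataFrame", source = "character"))

.match_cols <- c("qRecord", "sRecord", "qStart", "qEnd", "sStart", "sEnd",
                 "strand", "alnLength", "identities", "score", "log10Evalue")

.validate_side <- function(df, lens, pre) {
    rec <- df[[paste0(pre, "Record")]]
    st  <- df[[paste0(pre, "Start")]]
    en  <- df[[paste0(pre, "End")]]
    msg <- NULL
    unknown <- setdiff(unique(rec), names(lens))
    if (length(unknown))
        msg <- c(msg, sprintf("unknown %s record id(s): %s", pre,
                              paste(unknown, collapse = ", ")))
    else {
        if (any(st < 1L) || any(en < st))
            msg <- c(msg, sprintf("%s coordinates must satisfy 1 <= start <= end", pre))
        if (any(en > unname(lens[rec])))
            msg <- c(msg, sprintf("%s coordinate beyond declared record length", pre))
    }
    msg
}

setValidity("MatchSet", function(object) {
    msg <- NULL
    df <- object@matches
    if (!all(.match_cols %in% colnames(df)))
        msg <- c(msg, paste("match table must have columns:",
                            paste(.match_cols, collapse = ", ")))
    else if (nrow(df)) {
        msg <- c(msg, .validate_side(df, object@queryLengths, "q"))
        msg <- c(msg, .validate_side(df, object@subjectLengths, "s"))
        if (!all(df$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        if (any(df$alnLength < 1L))
            msg <- c(msg, "alnLength must be >= 1")
        if (any(df$identities > df$alnLength))
            msg <- c(msg, "identities cannot exceed alnLength")
    }
    if (!object@source %in% c("builtin-hsp", "builtin-mum", "blast-tab",
                              "mummer", "cgviz", "synthetic"))
        msg <- c(msg, "unknown match source")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MatchSet
#'
#' @param query,subject \linkS4class{Genome} objects, or named integer
#'   vectors of record lengths with a \code{label} attribute-free shortcut
#'   (use \code{queryLabel=}/\code{subjectLabel=} then).
#' @param matches a data.frame/DataFrame with the match columns
#'   (see \linkS4class{MatchSet}); missing \code{score}/\code{log10Evalue}
#'   columns are filled with \code{NA}.
#' @param source provenance tag of the matches.
#' @param queryLabel,subjectLabel labels, required when lengths are given
#'   as bare vectors.
#' @return A \linkS4class{MatchSet}.
#' @export
MatchSet <- function(query, subject, matches, source = "synthetic",
                     queryLabel = NULL, subjectLabel = NULL) {
    side <- function(g, lab) {
        if (is(g, "Genome")) {
            lens <- setNames(width(g), names(g))
            list(label = genomeLabel(g), lengths = lens)
        } else {
            stopifnot(!is.null(names(g)), !is.null(lab))
            list(label = lab, lengths = setNames(as.integer(g), names(g)))
        }
    }
    q <- side(query, queryLabel); s <- side(subject, subjectLabel)
    df <- as(as.data.frame(matches, stringsAsFactors = FALSE), "DataFrame")
    if (nrow(df) == 0L)
        df <- DataFrame(qRecord = character(), sRecord = character(),
                        qStart = integer(), qEnd = integer(),
                        sStart = integer(), sEnd = integer(),
                        strand = character(), alnLength = integer(),
                        identities = integer(), score = numeric(),
                        log10Evalue = numeric())
    for (col in c("score", "log10Evalue"))
        if (!col %in% colnames(df)) df[[col]] <- rep(NA_real_, nrow(df))
    int_cols <- c("qStart", "qEnd", "sStart", "sEnd", "alnLength", "identities")
    for (col in int_cols) df[[col]] <- as.integer(df[[col]])
    df$strand <- as.character(df$strand)
    df <- df[, .match_cols, drop = FALSE]
    new("MatchSet", queryLabel = q$label, subjectLabel = s$label,
        queryLengths = q$lengths, subjectLengths = s$lengths,
        matches = df, source = source)
}

#' @describeIn MatchSet the match table (a \code{DataFrame})
#' @param x a MatchSet
#' @export
matchTable <- function(x) x@matches

#' @describeIn MatchSet number of matches
#' @export
matchCount <- function(x) nrow(x@matches)

#' @describeIn MatchSet provenance of the matches
#' @export
matchSource <- function(x) x@source

#' @describeIn MatchSet query genome label
#' @export
queryLabel <- function(x) x@queryLabel

#' @describeIn MatchSet subject genome label
#' @export
subjectLabel <- function(x) x@subjectLabel

#' @describeIn MatchSet total query genome length (bp)
#' @export
queryLength <- function(x) sum(x@queryLengths)

#' @describeIn MatchSet total subject genome length (bp)
#' @export
subjectLength <- function(x) sum(x@subjectLengths)

setMethod("show", "MatchSet", function(object) {
    cat(sprintf("MatchSet [%s]: %s (%d bp) vs %s (%d bp), %d match(es)\n",
                object@source, object@queryLabel, queryLength(object),
                object@subjectLabel, subjectLength(object),
                matchCount(object)))
    if (matchCount(object))
        show(utils::head(as.data.frame(object@matches), 5L))
})

# replace the match table, keeping metadata/labels
.set_matches <- function(ms, df) {
    ms@matches <- as(df, "DataFrame")
    validObject(ms)
    ms
}

# genome-global 1-based coordinates (records laid end to end, no gaps)
.record_offsets <- function(lens) {
    off <- c(0L, cumsum(as.numeric(lens)))[seq_along(lens)]
    names(off) <- names(lens)
    off
}

.global_ranges <- function(ms, side = c("query", "subject")) {
    side <- match.arg(side)
    df <- ms@matches
    lens <- if (side == "query") ms@queryLengths else ms@subjectLengths
    off <- .record_offsets(lens)
    pre <- if (side == "query") "q" else "s"
    st <- df[[paste0(pre, "Start")]] + off[df[[paste0(pre, "Record")]]]
    en <- df[[paste0(pre, "End")]] + off[df[[paste0(pre, "Record")]]]
    IRanges(start = as.integer(st), end = as.integer(en))
}
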