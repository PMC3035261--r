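# Built-in, dependency-free HSP and MUM detection.
#
# The finders are deliberately simple stand-ins for external similarity
# search tools (similarity search is a pluggable step; the science lives
# downstream in the distance machinery): exact-word seeding, ungapped
# x-drop extension, no low-complexity masking.  They are deterministic and
# every reported statistic is exact for the reported coordinates.

#' Parameters for the built-in HSP finder
#'
#' Seed-and-extend with ungapped x-drop extension.  E-values follow the
#' Karlin-Altschul form \eqn{E = K m n e^{-\lambda S}} with the total
#' genome lengths as \eqn{m, n}; the shipped \eqn{\lambda} and \eqn{K} are
#' fixed approximate defaults for the +1/-2 scoring scheme.
#'
#' @slot wordSize seed word length (4-31).
#' @slot matchScore,mismatchScore per-column scores (+1 / -2 by default).
#' @slot xdrop score drop that terminates an extension (default 20).
#' @slot minScore minimum raw score for a reported HSP (default 30).
#' @slot lambda,K e-value scaling constants (defaults 1.28, 0.46).
#' @slot bothStrands also scan the reverse complement of the subject.
#' @aliases HspParams-class
#' @exportClass HspParams
setClass("HspParams",
         representation(wordSize = "integer", matchScore = "integer",
                        mismatchScore = "integer", xdrop = "integer",
                        minScore = "integer", lambda = "numeric",
                        K = "numeric", bothStrands = "logical"))

setValidity("HspParams", function(object) {
    msg <- NULL
    if (object@wordSize < 4L || object@wordSize > 31L)
        msg <- c(msg, "wordSize must be in [4, 31]")
    if (!(object@matchScore > 0L && object@mismatchScore < 0L))
        msg <- c(msg, "need matchScore > 0 > mismatchScore")
    if (object@lambda <= 0 || object@K <= 0)
        msg <- c(msg, "lambda and K must be positive")
    if (object@xdrop < 1L) msg <- c(msg, "xdrop must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn HspParams constructor with the package defaults
#' @param wordSize,matchScore,mismatchScore,xdrop,minScore,lambda,K,bothStrands
#'   see slots.
#' @export
HspParams <- function(wordSize = 11L, matchScore = 1L, mismatchScore = -2L,
                      xdrop = 20L, minScore = 30L, lambda = 1.28, K = 0.46,
                      bothStrands = TRUE) {
    new("HspParams", wordSize = as.integer(wordSize),
        matchScore = as.integer(matchScore),
        mismatchScore = as.integer(mismatchScore), xdrop = as.integer(xdrop),
        minScore = as.integer(minScore), lambda = lambda, K = K,
        bothStrands = bothStrands)
}

#' Parameters for the built-in MUM finder
#'
#' @slot minLength minimum match length (default 44, the MUMmer preset).
#' @slot bothStrands also scan the reverse complement of the subject.
#' @slot uniqueInBoth require the matched substring to occur exactly once
#'   in each genome (counting both strands); when \code{FALSE} all maximal
#'   exact matches are returned.
#' @aliases MumParams-class
#' @exportClass MumParams
setClass("MumParams",
         representation(minLength = "integer", bothStrands = "logical",
                        uniqueInBoth = "logical"))

setValidity("MumParams", function(object) {
    if (object@minLength < 8L) "minLength must be >= 8" else TRUE
})

#' @describeIn MumParams constructor with the package defaults
#' @param minLength,bothStrands,uniqueInBoth see slots.
#' @export
MumParams <- function(minLength = 44L, bothStrands = TRUE,
                      uniqueInBoth = TRUE) {
    new("MumParams", minLength = as.integer(minLength),
        bothStrands = bothStrands, uniqueInBoth = uniqueInBoth)
}

# concatenate genome records with an N spacer long enough that no HSP or
# exact match can cross a record boundary (the spacer alone forces a score
# drop beyond xdrop; N never matches anything).
.concat_genome <- function(g, spacer_len) {
    seqs <- as.character(g)
    spacer <- strrep("N", spacer_len)
    cat_seq <- paste(seqs, collapse = spacer)
    off <- cumsum(c(0L, (nchar(seqs) + spacer_len)[-length(seqs)]))
    list(seq = cat_seq, offsets = setNames(off, names(seqs)),
         lens = setNames(nchar(seqs), names(seqs)))
}

# map global (spacered) 1-based intervals back onto records; every interval
# must fall within a single record by construction.
.to_records <- function(start, end, cat) {
    idx <- findInterval(start, cat$offsets + 1L)
    rec <- names(cat$offsets)[idx]
    st <- start - unname(cat$offsets[idx])
    en <- end - unname(cat$offsets[idx])
    stopifnot(all(st >= 1L), all(en <= unname(cat$lens[idx])))
    list(record = rec, start = st, end = en)
}

.revcomp_chr <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))[[1L]]
}

# drop matches whose query AND subject intervals are contained in a
# higher-ranked match on the same strand
.collapse_contained <- function(df) {
    if (nrow(df) < 2L) return(df)
    o <- order(-df$score, -df$alnLength, df$qStart, df$sStart)
    df <- df[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))[-1L]) {
        for (j in seq_len(i - 1L)) {
            if (!keep[j] || df$strand[j] != df$strand[i]) next
            if (df$qStart[j] <= df$qStart[i] && df$qEnd[j] >= df$qEnd[i] &&
                df$sStart[j] <= df$sStart[i] && df$sEnd[j] >= df$sEnd[i]) {
                keep[i] <- FALSE
                break
            }
        }
    }
    df[keep, , drop = FALSE]
}

#' Find high-scoring segment pairs between two genomes
#'
#' Exact \code{wordSize}-mers shared by the two genomes seed ungapped
#' extensions in both directions, terminated once the running score falls
#' \code{xdrop} below the best score seen; the minus strand is handled by
#' scanning the reverse complement of the subject.  Duplicate and fully
#' contained HSPs are collapsed, HSPs scoring below \code{minScore} are
#' dropped, and output ordering is deterministic (query start, subject
#' start, length).
#'
#' @param query,subject \linkS4class{Genome} objects.
#' @param params an \linkS4class{HspParams} object.
#' @return A \linkS4class{MatchSet} with source \code{"builtin-hsp"}.
#' @examples
#' g <- randomGenome(2000, seed = 1, label = "g")
#' ms <- findHSPs(g, g)
#' matchCount(ms) >= 1
#' @export
findHSPs <- function(query, subject, params = HspParams()) {
    stopifnot(is(query, "Genome"), is(subject, "Genome"))
    validObject(params)
    spacer <- max(11L, params@xdrop %/% abs(params@mismatchScore) + 2L)
    qc <- .concat_genome(query, spacer)
    sc <- .concat_genome(subject, spacer)
    run <- function(subj_seq, strand) {
        h <- .cpp_find_hsps(qc$seq, subj_seq, params@wordSize,
                            params@matchScore, params@mismatchScore,
                            params@xdrop, params@minScore)
        h <- as.data.frame(h)
        if (!nrow(h)) return(NULL)
        if (strand == "-") {
            L <- nchar(subj_seq)
            ss <- L - h$sEnd + 1L; se <- L - h$sStart + 1L
            h$sStart <- ss; h$sEnd <- se
        }
        h$strand <- strand
        h
    }
    hits <- run(sc$seq, "+")
    if (params@bothStrands)
        hits <- rbind(hits, run(.revcomp_chr(sc$seq), "-"))
    if (is.null(hits) || !nrow(hits)) {
        return(MatchSet(query, subject, data.frame(), source = "builtin-hsp"))
    }
    hits$alnLength <- hits$qEnd - hits$qStart + 1L
    hits <- .collapse_contained(hits)
    qr <- .to_records(hits$qStart, hits$qEnd, qc)
    sr <- .to_records(hits$sStart, hits$sEnd, sc)
    log10e <- log10(params@K) + log10(totalLength(query)) +
        log10(totalLength(subject)) - params@lambda * hits$score / log(10)
    df <- data.frame(qRecord = qr$record, sRecord = sr$record,
                     qStart = qr$start, qEnd = qr$end,
                     sStart = sr$start, sEnd = sr$end,
                     strand = hits$strand, alnLength = hits$alnLength,
                     identities = hits$identities,
                     score = as.numeric(hits$score), log10Evalue = log10e,
                     stringsAsFactors = FALSE)
    df <- df[order(df$qStart, df$sStart, df$alnLength), , drop = FALSE]
    rownames(df) <- NULL
    MatchSet(query, subject, df, source = "builtin-hsp")
}

#' Find maximal unique matches between two genomes
#'
#' Returns maximal exact matches of length at least \code{minLength}; with
#' \code{uniqueInBoth} (the default, mirroring \code{mummer -mum}) only
#' matches whose substring occurs exactly once in each genome - counting
#' both strands - are kept.  Maximality means extension by one base on
#' either side breaks the exact match.  MUMs carry
#' \code{identities == alnLength} and no score or e-value.
#'
#' @param query,subject \linkS4class{Genome} objects.
#' @param params a \linkS4class{MumParams} object.
#' @return A \linkS4class{MatchSet} with source \code{"builtin-mum"}.
#' @examples
#' g <- randomGenome(500, seed = 2, label = "g")
#' matchCount(findMUMs(g, g)) == 1
#' @export
findMUMs <- function(query, subject, params = MumParams()) {
    stopifnot(is(query, "Genome"), is(subject, "Genome"))
    validObject(params)
    qc <- .concat_genome(query, 10L)
    sc <- .concat_genome(subject, 10L)
    run <- function(subj_seq, strand) {
        h <- as.data.frame(.cpp_find_mems(qc$seq, subj_seq, params@minLength))
        if (!nrow(h)) return(NULL)
        h$qEnd <- h$qStart + h$length - 1L
        if (strand == "-") {
            L <- nchar(subj_seq)
            h$sEnd <- L - h$sStart + 1L
            h$sStart <- h$sEnd - h$length + 1L
        } else h$sEnd <- h$sStart + h$length - 1L
        h$strand <- strand
        h
    }
    hits <- run(sc$seq, "+")
    if (params@bothStrands)
        hits <- rbind(hits, run(.revcomp_chr(sc$seq), "-"))
    if (is.null(hits) || !nrow(hits)) {
        return(MatchSet(query, subject, data.frame(), source = "builtin-mum"))
    }
    hits <- hits[!duplicated(hits[, c("qStart", "sStart", "length", "strand")]), ,
                 drop = FALSE]
    if (params@uniqueInBoth && nrow(hits)) {
        occ_both <- function(text, pat) {
            rc <- .revcomp_chr(pat)
            .cpp_count_sub(text, pat) +
                if (pat == rc) 0L else .cpp_count_sub(text, rc)
        }
        pats <- substring(qc$seq, hits$qStart, hits$qEnd)
        uq <- vapply(pats, function(p)
            occ_both(qc$seq, p) == 1L && occ_both(sc$seq, p) == 1L,
            logical(1), USE.NAMES = FALSE)
        hits <- hits[uq, , drop = FALSE]
    }
    if (!nrow(hits)) {
        return(MatchSet(query, subject, data.frame(), source = "builtin-mum"))
    }
    qr <- .to_records(hits$qStart, hits$qEnd, qc)
    sr <- .to_records(hits$sStart, hits$sEnd, sc)
    df <- data.frame(qRecord = qr$record, sRecord = sr$record,
                     qStart = qr$start, qEnd = qr$end,
                     sStart = sr$start, sEnd = sr$end,
                     strand = hits$strand, alnLength = hits$length,
                     identities = hits$length,
                     score = NA_real_, log10Evalue = NA_real_,
                     stringsAsFactors = FALSE)
    df <- df[order(df$qStart, df$sStart, df$alnLength), , drop = FALSE]
    rownames(df) <- NULL
    MatchSet(query, subject, df, source = "builtin-mum")
}

#' Documented command-line presets for external similarity search tools
#'
#' The calibrated conversion constants shipped with the package were
#' derived from searches run with these exact invocations; they are
#' provided as documentation for users running the external tools
#' themselves (their tabular/match output can be ingested with
#' [parseBlastTabular()] and [parseMummer()]).  The package never invokes
#' these binaries.
#'
#' @return Named character vector of command templates
#'   (\code{QUERY}/\code{SUBJECT}/\code{OUTFILE} placeholders).
#' @export
alignerPresets <- function() {
    c(`ncbi-blast` = "blastall -p blastn -i QUERY -d SUBJECT -m 7 -a 1 -S 3 -e 10 -F 'm D' -b 100000",
      `wu-blast` = "blastn SUBJECT QUERY mformat=7 cpus=1 E=10 wordmask=dust B=100000 hspmax=100000 hspsepSmax=50 hspsepQmax=50",
      blat = "blat SUBJECT QUERY OUTFILE -t=dna -q=dna -out=blast -minScore=30 -minIdentity=50",
      blastz = "blastz QUERY SUBJECT B=2 C=2 K=3500 Y=700",
      mummer = "mummer -b -c -F -l 44 -mum SUBJECT QUERY")
}
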