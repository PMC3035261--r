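# The GBDP distance machinery: e-value filtering, greedy-with-trimming
# overlap resolution, coverage computation, the three distance formulas,
# and bidirectional symmetrization.

#' Parameters for GBDP distance calculation
#'
#' @slot algorithm overlap handling: \code{"trimming"} (greedy-with-trimming)
#'   or \code{"coverage"} (union of matched positions, the MUMmer pathway).
#' @slot formula distance ratio: 1 = matched length per total genome length,
#'   2 = identities per total HSP length, 3 = identities per total genome
#'   length.
#' @slot lengthMode how the total genome length enters the ratio:
#'   \code{"min"} or \code{"average"} of the two genome lengths (default
#'   average; the choice has little effect in practice).
#' @slot useLog report \eqn{d = -\ln(ratio)} instead of \eqn{d = 1 - ratio}
#'   (default off).
#' @slot evalueCutoff e-value filter applied before overlap resolution
#'   (default \code{1e-2}; \code{NA} disables).  Matches without an e-value
#'   (MUMs) always pass.
#' @slot minResidualLength trimmed matches retaining fewer query bases than
#'   this are dropped (default 1).
#' @aliases GbdpParams-class
#' @exportClass GbdpParams
setClass("GbdpParams",
         representation(algorithm = "character", formula = "integer",
                        lengthMode = "character", useLog = "logical",
                        evalueCutoff = "numeric", minResidualLength = "integer"))

setValidity("GbdpParams", function(object) {
    msg <- NULL
    if (!object@algorithm %in% c("trimming", "coverage"))
        msg <- c(msg, "algorithm must be 'trimming' or 'coverage'")
    if (!object@formula %in% 1:3)
        msg <- c(msg, "formula must be 1, 2 or 3")
    if (!object@lengthMode %in% c("min", "average"))
        msg <- c(msg, "lengthMode must be 'min' or 'average'")
    if (!is.na(object@evalueCutoff) && object@evalueCutoff <= 0)
        msg <- c(msg, "evalueCutoff must be positive (or NA to disable)")
    if (object@minResidualLength < 1L)
        msg <- c(msg, "minResidualLength must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GbdpParams constructor with the package defaults
#' @param algorithm,formula,lengthMode,useLog,evalueCutoff,minResidualLength
#'   see slots.
#' @export
GbdpParams <- function(algorithm = c("trimming", "coverage"), formula = 2L,
                       lengthMode = c("average", "min"), useLog = FALSE,
                       evalueCutoff = 1e-2, minResidualLength = 1L) {
    new("GbdpParams", algorithm = match.arg(algorithm),
        formula = as.integer(formula), lengthMode = match.arg(lengthMode),
        useLog = useLog, evalueCutoff = as.numeric(evalueCutoff),
        minResidualLength = as.integer(minResidualLength))
}

setMethod("show", "GbdpParams", function(object) {
    cat(sprintf(
        "GbdpParams: %s, formula %d, length mode %s, log %s, e-value cutoff %s\n",
        object@algorithm, object@formula, object@lengthMode,
        if (object@useLog) "on" else "off",
        if (is.na(object@evalueCutoff)) "off" else
            format(object@evalueCutoff)))
})

#' Result of a bidirectional GBDP distance calculation
#'
#' @slot d symmetrized distance.
#' @slot ratio symmetrized similarity ratio the distance derives from.
#' @slot dForward,dReverse per-direction distances.
#' @slot nUsed,nTrimmed,nDropped match bookkeeping over both directions:
#'   matches contributing to the distance, matches shortened by trimming,
#'   matches removed by the e-value filter or by trimming.
#' @slot params the \linkS4class{GbdpParams} used.
#' @aliases DistanceResult-class
#' @exportClass DistanceResult
setClass("DistanceResult",
         representation(d = "numeric", ratio = "numeric",
                        dForward = "numeric", dReverse = "numeric",
                        nUsed = "integer", nTrimmed = "integer",
                        nDropped = "integer", params = "GbdpParams"))

#' @describeIn DistanceResult the symmetrized distance
#' @param x a DistanceResult
#' @export
distanceValue <- function(x) x@d

#' @describeIn DistanceResult the symmetrized ratio
#' @export
distanceRatio <- function(x) x@ratio

#' @describeIn DistanceResult named vector of match counts
#' @export
matchCounts <- function(x) c(used = x@nUsed, trimmed = x@nTrimmed,
                             dropped = x@nDropped)

setMethod("show", "DistanceResult", function(object) {
    cat(sprintf("GBDP distance: d = %.6f (ratio %.6f; forward %.6f, reverse %.6f)\n",
                object@d, object@ratio, object@dForward, object@dReverse))
    cat(sprintf("  matches: %d used, %d trimmed, %d dropped\n",
                object@nUsed, object@nTrimmed, object@nDropped))
    show(object@params)
})

#' Filter matches by e-value
#'
#' Matches with an e-value above \code{cutoff} are removed before distance
#' calculation; equality at the cutoff is kept.  Matches without an
#' e-value (MUMs) are retained unchanged.
#'
#' @param ms a \linkS4class{MatchSet}.
#' @param cutoff e-value cutoff on the linear scale (default \code{1e-2}).
#' @return The filtered \linkS4class{MatchSet}.
#' @export
filterByEvalue <- function(ms, cutoff = 1e-2) {
    stopifnot(is(ms, "MatchSet"), is.na(cutoff) || cutoff > 0)
    if (is.na(cutoff)) return(ms)
    df <- matchTable(ms)
    keep <- is.na(df$log10Evalue) | df$log10Evalue <= log10(cutoff)
    .set_matches(ms, df[keep, , drop = FALSE])
}

.round_half_up <- function(x) floor(x + 0.5)

# the per-query-position subject segment boundaries of a match under the
# proportional (strand-aware) coordinate map; segments tile [sStart, sEnd]
.seg_bounds <- function(t0, t1, qlen, slen, sStart, sEnd, strand) {
    lo <- sStart + floor(t0 * slen / qlen)
    hi <- sStart + floor(t1 * slen / qlen) - 1
    if (strand == "-") {
        tmp <- lo
        lo <- sStart + sEnd - hi
        hi <- sStart + sEnd - tmp
    }
    c(lo, hi)
}

#' Greedy-with-trimming overlap resolution
#'
#' Matches are processed in descending score order (ties broken by longer
#' alignment, then query start, then subject start).  The first match is
#' accepted whole; every later match is trimmed to the single longest
#' contiguous part whose query positions are free of all previously
#' accepted query intervals \emph{and} whose subject image is free of all
#' previously accepted subject intervals.  Alignment length and identities
#' of a trimmed match are rescaled by the retained fraction of the query
#' span (rounded half-up, identities capped at the new alignment length);
#' the score is rescaled proportionally.  Matches retaining fewer than
#' \code{minResidualLength} query bases are dropped.  The output has zero
#' pairwise overlap on the query genome and zero pairwise overlap on the
#' subject genome.
#'
#' @param ms a \linkS4class{MatchSet}.
#' @param minResidualLength drop threshold for trimmed matches (bp).
#' @return A \linkS4class{MatchSet}; counts of trimmed/dropped matches are
#'   available via \code{metadata(result)$trim}.
#' @export
greedyTrim <- function(ms, minResidualLength = 1L) {
    stopifnot(is(ms, "MatchSet"))
    df <- as.data.frame(matchTable(ms))
    if (nrow(df) == 0L) {
        metadata(ms)$trim <- c(used = 0L, trimmed = 0L, dropped = 0L)
        return(ms)
    }
    eff_score <- ifelse(is.na(df$score), as.numeric(df$alnLength), df$score)
    o <- order(-eff_score, -df$alnLength, df$qStart, df$sStart,
               xtfrm(df$qRecord), xtfrm(df$sRecord))
    df <- df[o, , drop = FALSE]

    qoff <- .record_offsets(ms@queryLengths)
    soff <- .record_offsets(ms@subjectLengths)
    qcov <- logical(queryLength(ms))
    scov <- logical(subjectLength(ms))

    out <- vector("list", nrow(df))
    n_trim <- 0L; n_drop <- 0L
    for (i in seq_len(nrow(df))) {
        r <- df[i, ]
        gq0 <- r$qStart + qoff[[r$qRecord]]; gq1 <- r$qEnd + qoff[[r$qRecord]]
        gs0 <- r$sStart + soff[[r$sRecord]]; gs1 <- r$sEnd + soff[[r$sRecord]]
        qlen <- gq1 - gq0 + 1L; slen <- gs1 - gs0 + 1L
        qfree <- !qcov[gq0:gq1]
        if (qlen == slen) {
            smap <- if (r$strand == "+") gs0:gs1 else gs1:gs0
            free <- qfree & !scov[smap]
        } else {
            free <- logical(qlen)
            for (t in which(qfree)) {
                b <- .seg_bounds(t - 1L, t, qlen, slen, gs0, gs1, r$strand)
                free[t] <- b[[2L]] < b[[1L]] || !any(scov[b[[1L]]:b[[2L]]])
            }
        }
        runs <- rle(free)
        if (!any(runs$values)) { n_drop <- n_drop + 1L; next }
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        cand <- which(runs$values)
        best <- cand[which.max(runs$lengths[cand])]
        t0 <- starts[[best]]; t1 <- ends[[best]]
        keep_len <- t1 - t0 + 1L
        if (keep_len < minResidualLength) { n_drop <- n_drop + 1L; next }

        sb <- .seg_bounds(t0 - 1L, t1, qlen, slen, gs0, gs1, r$strand)
        if (sb[[2L]] < sb[[1L]]) { n_drop <- n_drop + 1L; next }
        nq0 <- gq0 + t0 - 1L; nq1 <- gq0 + t1 - 1L
        qcov[nq0:nq1] <- TRUE
        scov[sb[[1L]]:sb[[2L]]] <- TRUE

        frac <- keep_len / qlen
        if (keep_len < qlen) {
            n_trim <- n_trim + 1L
            r$alnLength <- max(1L, as.integer(.round_half_up(r$alnLength * frac)))
            r$identities <- min(as.integer(.round_half_up(r$identities * frac)),
                                r$alnLength)
            r$score <- r$score * frac
        }
        r$qStart <- as.integer(nq0 - qoff[[r$qRecord]])
        r$qEnd <- as.integer(nq1 - qoff[[r$qRecord]])
        r$sStart <- as.integer(sb[[1L]] - soff[[r$sRecord]])
        r$sEnd <- as.integer(sb[[2L]] - soff[[r$sRecord]])
        out[[i]] <- r
    }
    out <- out[!vapply(out, is.null, logical(1))]
    res <- if (length(out)) do.call(rbind, out) else df[0L, , drop = FALSE]
    res <- res[order(res$qStart, res$sStart, res$alnLength,
                     xtfrm(res$qRecord)), , drop = FALSE]
    rownames(res) <- NULL
    ms <- .set_matches(ms, res)
    metadata(ms)$trim <- c(used = nrow(res), trimmed = n_trim,
                           dropped = n_drop)
    ms
}

#' Number of genome positions covered by at least one match
#'
#' Union length of the match intervals on the chosen genome, without any
#' trimming (the coverage overlap-handling pathway).
#'
#' @param ms a \linkS4class{MatchSet}.
#' @param side \code{"query"} or \code{"subject"}.
#' @return Integer number of covered base positions.
#' @export
coverageBases <- function(ms, side = c("query", "subject")) {
    stopifnot(is(ms, "MatchSet"))
    side <- match.arg(side)
    if (matchCount(ms) == 0L) return(0L)
    sum(width(reduce(.global_ranges(ms, side))))
}

#' Distance from a prepared match set
#'
#' Computes the similarity ratio and the distance for one direction.  The
#' match set must already be prepared for the chosen overlap algorithm:
#' e-value-filtered and trimmed for \code{"trimming"}, raw for
#' \code{"coverage"} (where formula 1 uses the union of matched positions
#' on the query genome).  With \eqn{G} the minimum or average of the two
#' total genome lengths:
#' \itemize{
#'   \item formula 1: matched length / \eqn{G}
#'   \item formula 2: identities / total HSP length (0 when no matches)
#'   \item formula 3: identities / \eqn{G}
#' }
#' The ratio is clamped to \eqn{[0,1]}; \eqn{d = 1 - ratio}, or
#' \eqn{-\ln(ratio)} (capped at 99 for ratio 0) when \code{useLog}.
#'
#' @param ms a prepared \linkS4class{MatchSet}.
#' @param params a \linkS4class{GbdpParams}.
#' @return \code{list(ratio =, d =)}.
#' @export
distanceFromMatches <- function(ms, params = GbdpParams()) {
    stopifnot(is(ms, "MatchSet"), is(params, "GbdpParams"))
    validObject(params)
    G <- switch(params@lengthMode,
                min = min(queryLength(ms), subjectLength(ms)),
                average = (queryLength(ms) + subjectLength(ms)) / 2)
    if (G <= 0) stop("total genome length must be positive")
    df <- matchTable(ms)
    ratio <- if (params@formula == 1L) {
        matched <- if (params@algorithm == "coverage")
            coverageBases(ms, "query") else sum(df$alnLength)
        matched / G
    } else if (params@formula == 2L) {
        if (nrow(df) == 0L) 0 else sum(df$identities) / sum(df$alnLength)
    } else {
        sum(df$identities) / G
    }
    ratio <- min(max(ratio, 0), 1)
    d <- if (params@useLog) {
        if (ratio == 0) 99 else min(-log(ratio), 99)
    } else 1 - ratio
    list(ratio = ratio, d = d)
}

#' Combine the two per-direction distances
#'
#' Similarity search is asymmetric, so the search runs twice with the
#' roles of the genomes exchanged; the two distances are combined by
#' their arithmetic mean.
#'
#' @param dForward,dReverse per-direction distances computed with
#'   identical parameters.
#' @return The symmetrized distance.
#' @export
symmetrizeDistance <- function(dForward, dReverse) {
    (dForward + dReverse) / 2
}

# prepare one direction: find matches (or take a supplied MatchSet),
# filter, trim if requested; returns list(ms, counts)
.prepare_direction <- function(query, subject, params, engine,
                               hspParams, mumParams, ms = NULL) {
    if (is.null(ms)) {
        ms <- switch(engine,
                     hsp = findHSPs(query, subject, hspParams),
                     mum = findMUMs(query, subject, mumParams),
                     stop("unknown engine: ", engine))
    }
    n0 <- matchCount(ms)
    ms <- filterByEvalue(ms, params@evalueCutoff)
    n_eval_drop <- n0 - matchCount(ms)
    if (params@algorithm == "trimming") {
        ms <- greedyTrim(ms, params@minResidualLength)
        tr <- metadata(ms)$trim
        counts <- c(used = unname(tr[["used"]]),
                    trimmed = unname(tr[["trimmed"]]),
                    dropped = unname(tr[["dropped"]]) + n_eval_drop)
    } else {
        counts <- c(used = matchCount(ms), trimmed = 0L,
                    dropped = n_eval_drop)
    }
    list(ms = ms, counts = counts)
}

#' Bidirectional GBDP distance between two genomes
#'
#' Runs the full per-pair pipeline: match detection in both directions
#' (query vs subject and subject vs query), e-value filtering,
#' greedy-with-trimming or coverage overlap handling, the chosen distance
#' formula, and symmetrization by the arithmetic mean.
#'
#' A warning is issued for formulas 2 and 3 on MUM matches: exact matches
#' have \code{identities == alnLength}, which forces the formula-2 ratio
#' to 1; the MUM pathway pairs with the coverage algorithm and formula 1.
#'
#' @param query,subject \linkS4class{Genome} objects.
#' @param params a \linkS4class{GbdpParams}.
#' @param engine \code{"hsp"} or \code{"mum"} (built-in finders), or supply
#'   \code{forwardMatches}/\code{reverseMatches}.
#' @param hspParams,mumParams finder parameters.
#' @param forwardMatches,reverseMatches optional pre-computed
#'   \linkS4class{MatchSet}s (e.g. from [parseBlastTabular()],
#'   [parseMummer()] or [readCgviz()]) for the two search directions;
#'   when given, \code{engine} is ignored.
#' @return A \linkS4class{DistanceResult}.
#' @examples
#' g <- randomGenome(3000, seed = 1, label = "A")
#' distanceValue(gbdpDistance(g, g))  # 0 for self-comparison
#' @export
gbdpDistance <- function(query, subject, params = GbdpParams(),
                         engine = c("hsp", "mum"),
                         hspParams = HspParams(), mumParams = MumParams(),
                         forwardMatches = NULL, reverseMatches = NULL) {
    engine <- match.arg(engine)
    validObject(params)
    mum_like <- engine == "mum" ||
        (!is.null(forwardMatches) &&
         matchSource(forwardMatches) %in% c("builtin-mum", "mummer"))
    if (mum_like && params@formula %in% c(2L, 3L))
        warning("formulas 2/3 are degenerate for exact matches ",
                "(identities == length); the MUM pathway pairs with the ",
                "coverage algorithm and formula 1")
    fwd <- .prepare_direction(query, subject, params, engine,
                              hspParams, mumParams, forwardMatches)
    rev <- .prepare_direction(subject, query, params, engine,
                              hspParams, mumParams, reverseMatches)
    rf <- distanceFromMatches(fwd$ms, params)
    rr <- distanceFromMatches(rev$ms, params)
    counts <- fwd$counts + rev$counts
    new("DistanceResult",
        d = symmetrizeDistance(rf$d, rr$d),
        ratio = (rf$ratio + rr$ratio) / 2,
        dForward = rf$d, dReverse = rr$d,
        nUsed = as.integer(counts[["used"]]),
        nTrimmed = as.integer(counts[["trimmed"]]),
        nDropped = as.integer(counts[["dropped"]]),
        params = params)
}

#' All-pairs GBDP distance matrix
#'
#' @param genomes list of \linkS4class{Genome} objects with unique labels.
#' @param params a \linkS4class{GbdpParams}.
#' @param engine,hspParams,mumParams as in [gbdpDistance()].
#' @return A symmetric numeric matrix with zero diagonal; genome labels as
#'   dimnames.
#' @export
distanceMatrix <- function(genomes, params = GbdpParams(),
                           engine = c("hsp", "mum"),
                           hspParams = HspParams(), mumParams = MumParams()) {
    engine <- match.arg(engine)
    stopifnot(length(genomes) >= 2L,
              all(vapply(genomes, is, logical(1), "Genome")))
    labels <- vapply(genomes, genomeLabel, character(1))
    if (anyDuplicated(labels))
        stop("duplicate genome labels: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))
    n <- length(genomes)
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            d <- distanceValue(gbdpDistance(genomes[[i]], genomes[[j]],
                                            params, engine,
                                            hspParams, mumParams))
            m[i, j] <- d
            m[j, i] <- d
        }
    }
    m
}
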