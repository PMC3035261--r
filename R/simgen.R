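# Seeded synthetic genome-pair generator.  Provides ground-truth-bearing
# inputs (ancestor/derived pairs with a known event log) so the full
# pipeline can be exercised without downloading real genomes; emulates
# substitution divergence, rearrangement, and incomplete sequencing
# (contiguous deletions).

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

# derive independent per-stage seeds from one global seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
    (as.numeric(seed) * 48271 + stage * 16807) %% 2147483647
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with \eqn{P(G) + P(C) = } \code{gc}; the result
#' is deterministic for a given seed and leaves the caller's RNG state
#' untouched.
#'
#' @param length genome length in bp (\eqn{\ge 1}).
#' @param gc GC content in (0, 1), default 0.5.
#' @param seed integer seed.
#' @param label genome label.
#' @return A single-record \linkS4class{Genome}.
#' @examples
#' identical(as.character(randomGenome(50, seed = 1)),
#'           as.character(randomGenome(50, seed = 1)))
#' @export
randomGenome <- function(length, gc = 0.5, seed = 1L, label = "random") {
    stopifnot(length >= 1L, gc > 0, gc < 1)
    .with_seed(seed, {
        p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
        seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                     collapse = "")
        Genome(setNames(seq, "chr1"), label = label)
    })
}

.other_base <- function(base) {
    alt <- c("A", "C", "G", "T")
    vapply(base, function(b) sample(setdiff(alt, b), 1L), character(1))
}

#' Evolve a derived genome from a random ancestor
#'
#' Builds an ancestor of the requested length, then applies, in order:
#' per-site substitutions at \code{substitutionRate}, \code{nInversions}
#' reverse-complemented random blocks, \code{nTranslocations} random block
#' moves, and finally removal of \code{deletionFraction} of the genome as
#' contiguous blocks.  Deletions come last so the fraction is directly
#' interpretable as the missing-genome fraction of an incomplete
#' sequencing.  Every event is recorded with coordinates in the truth log.
#'
#' @param length ancestor length in bp.
#' @param substitutionRate per-site substitution probability, in [0, 0.5].
#' @param deletionFraction fraction of the derived genome removed as
#'   contiguous blocks, in [0, 0.9].
#' @param nInversions,nTranslocations number of rearranged blocks.
#' @param gc GC content of the ancestor.
#' @param seed single integer; all per-stage seeds derive from it.
#' @return \code{list(ancestor =, derived =, events =)} with two
#'   \linkS4class{Genome}s and a data.frame truth log (columns type,
#'   start, end, detail).
#' @export
evolvePair <- function(length, substitutionRate = 0.05,
                       deletionFraction = 0, nInversions = 0L,
                       nTranslocations = 0L, gc = 0.5, seed = 1L) {
    stopifnot(substitutionRate >= 0, substitutionRate <= 0.5,
              deletionFraction >= 0, deletionFraction <= 0.9,
              nInversions >= 0L, nTranslocations >= 0L)
    anc <- randomGenome(length, gc = gc, seed = .stage_seed(seed, 1L),
                        label = "ancestor")
    seqv <- strsplit(as.character(anc)[[1L]], "")[[1L]]
    events <- list()
    ev <- function(type, start, end, detail = "") {
        events[[length(events) + 1L]] <<- data.frame(
            type = type, start = start, end = end, detail = detail,
            stringsAsFactors = FALSE)
    }

    # save/restore the caller's RNG state; per-stage seeds in between
    has_rng <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_rng) old_rng <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_rng) assign(".Random.seed", old_rng, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })

    if (substitutionRate > 0) {
        set.seed(.stage_seed(seed, 2L))
        hit <- which(stats::runif(length) < substitutionRate)
        if (length(hit)) {
            newb <- .other_base(seqv[hit])
            ev("substitution", hit, hit, paste0(seqv[hit], ">", newb))
            seqv[hit] <- newb
        }
    }
    if (nInversions > 0L) {
        set.seed(.stage_seed(seed, 3L))
        for (k in seq_len(nInversions)) {
            len <- sample(50:max(51, min(2000, floor(length / 10))), 1L)
            st <- sample(seq_len(max(1L, length(seqv) - len)), 1L)
            en <- min(st + len - 1L, length(seqv))
            block <- paste(seqv[st:en], collapse = "")
            seqv[st:en] <- strsplit(.revcomp_chr(block), "")[[1L]]
            ev("inversion", st, en)
        }
    }
    if (nTranslocations > 0L) {
        set.seed(.stage_seed(seed, 4L))
        for (k in seq_len(nTranslocations)) {
            len <- sample(50:max(51, min(2000, floor(length / 10))), 1L)
            st <- sample(seq_len(max(1L, length(seqv) - len)), 1L)
            en <- min(st + len - 1L, length(seqv))
            block <- seqv[st:en]
            rest <- seqv[-(st:en)]
            at <- sample(0:length(rest), 1L)
            seqv <- append(rest, block, after = at)
            ev("translocation", st, en, paste0("to:", at + 1L))
        }
    }
    if (deletionFraction > 0) {
        set.seed(.stage_seed(seed, 5L))
        total <- round(deletionFraction * length(seqv))
        n_blocks <- sample(1:3, 1L)
        sizes <- diff(round(seq(0, total, length.out = n_blocks + 1L)))
        sizes <- sizes[sizes > 0]
        for (sz in sizes) {
            st <- sample(seq_len(max(1L, length(seqv) - sz)), 1L)
            en <- min(st + sz - 1L, length(seqv))
            ev("deletion", st, en)
            seqv <- seqv[-(st:en)]
        }
    }
    derived <- Genome(setNames(paste(seqv, collapse = ""), "chr1"),
                      label = "derived")
    events <- if (length(events)) do.call(rbind, events) else
        data.frame(type = character(), start = integer(), end = integer(),
                   detail = character(), stringsAsFactors = FALSE)
    list(ancestor = anc, derived = derived, events = events)
}
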