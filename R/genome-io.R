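#' Read a genome from a multi-FASTA file
#'
#' One file per genome is expected, with each chromosome or plasmid as a
#' single FASTA entry.  Sequences are uppercased and characters outside
#' \code{A,C,G,T} are replaced by \code{N} (warning).  Record ids are taken
#' from the first whitespace-delimited token of each header.
#'
#' @param file path to a FASTA file.
#' @param label genome label; defaults to the file name without extension.
#' @return A \linkS4class{Genome}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "ACGTACGT", ">p1", "acgtn"), fa)
#' readGenome(fa, label = "toy")
#' @export
readGenome <- function(file, label = NULL) {
    if (!file.exists(file)) stop("no such file: ", file)
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(file))
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines) || !startsWith(lines[[1L]], ">"))
        stop("not a FASTA stream: ", file)
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(gsub("\\s", "", x), collapse = ""),
                   character(1))
    # headers with no sequence lines at all
    if (length(seqs) < sum(hdr) || any(!nzchar(seqs)))
        stop("FASTA record with zero-length sequence in ", file)
    names(seqs) <- ids
    Genome(seqs, label = label)
}

#' Write a Genome to a FASTA file
#'
#' @param g a \linkS4class{Genome}.
#' @param file output path.
#' @param width line width for sequence wrapping.
#' @return \code{file}, invisibly.
#' @export
writeGenome <- function(g, file, width = 70L) {
    stopifnot(is(g, "Genome"))
    Biostrings::writeXStringSet(as(g, "DNAStringSet"), filepath = file,
                                width = width)
    invisible(file)
}
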