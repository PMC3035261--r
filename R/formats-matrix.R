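# Distance-matrix writers for downstream phylogeny applications.

.check_dist_matrix <- function(labels, m) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
        stop("distance matrix must be square")
    if (length(labels) != nrow(m))
        stop("need one label per matrix row")
    if (any(abs(m - t(m)) > 1e-9))
        stop("distance matrix is asymmetric beyond 1e-9")
    if (any(abs(diag(m)) > 1e-9))
        stop("distance matrix must have a zero diagonal")
    invisible(TRUE)
}

#' Sanitize genome labels for matrix output
#'
#' Whitespace and Phylip/Nexus-hostile punctuation are replaced by
#' underscores, deterministically, so the same label maps to the same
#' token in TSV, Phylip and Nexus output.
#'
#' @param labels character vector.
#' @return character vector of sanitized labels.
#' @export
sanitizeLabels <- function(labels) {
    out <- gsub("[\\s(),:;\\[\\]'\"]+", "_", labels, perl = TRUE)
    out[!nzchar(out)] <- "unnamed"
    make.unique(out, sep = "_")
}

#' Write a distance matrix in relaxed Phylip square format
#'
#' @param labels genome labels (one per row).
#' @param m square symmetric numeric matrix with zero diagonal.
#' @param file output path or connection.
#' @param digits decimal places for distances.
#' @return \code{file}, invisibly.
#' @export
writePhylip <- function(labels, m, file, digits = 6L) {
    .check_dist_matrix(labels, m)
    labs <- sanitizeLabels(labels)
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste(formatC(labs[i], width = max(10L, nchar(labs)) + 2L, flag = "-"),
              paste(formatC(m[i, ], digits = digits, format = "f"),
                    collapse = "  ")),
        character(1))
    writeLines(c(sprintf("%5d", nrow(m)), rows), file)
    invisible(file)
}

#' Write a distance matrix as a Nexus DISTANCES block
#'
#' Emits a TAXA block plus a DISTANCES block with
#' \code{FORMAT TRIANGLE=BOTH DIAGONAL}.
#'
#' @inheritParams writePhylip
#' @return \code{file}, invisibly.
#' @export
writeNexus <- function(labels, m, file, digits = 6L) {
    .check_dist_matrix(labels, m)
    labs <- sanitizeLabels(labels)
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste0("    ", formatC(labs[i], width = max(nchar(labs)) + 2L,
                               flag = "-"),
               paste(formatC(m[i, ], digits = digits, format = "f"),
                     collapse = " ")),
        character(1))
    writeLines(c(
        "#NEXUS",
        "BEGIN TAXA;",
        sprintf("  DIMENSIONS NTAX=%d;", nrow(m)),
        paste0("  TAXLABELS ", paste(labs, collapse = " "), ";"),
        "END;",
        "BEGIN DISTANCES;",
        sprintf("  DIMENSIONS NTAX=%d;", nrow(m)),
        "  FORMAT TRIANGLE=BOTH DIAGONAL;",
        "  MATRIX",
        rows,
        "  ;",
        "END;"), file)
    invisible(file)
}
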