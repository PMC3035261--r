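# End-to-end orchestration: genomes in -> matches -> filter -> trim or
# coverage -> distances (all three formulas) -> DDH similarities and
# species calls -> TSV report and distance matrices.

.as_genome <- function(x, label = NULL) {
    if (is(x, "Genome")) x else readGenome(x, label = label)
}

.default_model_method <- function(engine) {
    if (engine == "mum") "mummer" else "ncbi-blast"
}

#' Run the full per-pair pipeline and report all three formulas
#'
#' For one genome pair, computes the bidirectional GBDP distance under
#' formulas 1, 2 and 3 (formula 2 is the recommended headline for HSPs,
#' in particular whenever incomplete genome sequences are involved; the
#' MUM engine pairs with the coverage algorithm and formula 1 only),
#' converts each distance to a percent DDH-analogous similarity with the
#' matching conversion model, and adds a species call.
#'
#' The built-in HSP finder defaults to the \code{ncbi-blast} conversion
#' row; note (logged as a message) that those constants were calibrated
#' on real BLAST output, not on the built-in stand-in finder.
#'
#' @param query,subject \linkS4class{Genome} objects or FASTA paths.
#' @param params a \linkS4class{GbdpParams}; its \code{formula} slot is
#'   ignored here (all applicable formulas are computed).
#' @param engine \code{"hsp"} or \code{"mum"}.
#' @param model conversion-model method key (registry \code{method}
#'   column); defaults to \code{ncbi-blast} for HSPs and \code{mummer}
#'   for MUMs.
#' @param hspParams,mumParams finder parameters.
#' @param quiet suppress the calibration caveat message.
#' @return A data.frame with one row per formula: query, subject,
#'   engine, algorithm, formula, distance, ratio, ddh (clamped percent),
#'   ddh_unclamped, threshold, distinct, n_used, n_trimmed, n_dropped.
#' @export
runPair <- function(query, subject, params = GbdpParams(),
                    engine = c("hsp", "mum"), model = NULL,
                    hspParams = HspParams(), mumParams = MumParams(),
                    quiet = FALSE) {
    engine <- match.arg(engine)
    query <- .as_genome(query); subject <- .as_genome(subject)
    if (is.null(model)) model <- .default_model_method(engine)
    if (engine == "hsp" && model == "ncbi-blast" && !quiet)
        message("note: conversion constants were calibrated on real ",
                "NCBI-BLAST output; the built-in HSP finder is a stand-in")
    algorithm <- if (engine == "mum") "coverage" else params@algorithm
    formulas <- if (engine == "mum") 1L else 1:3
    registry <- conversionModels()
    rows <- lapply(formulas, function(f) {
        p <- GbdpParams(algorithm = algorithm, formula = f,
                        lengthMode = params@lengthMode,
                        useLog = params@useLog,
                        evalueCutoff = params@evalueCutoff,
                        minResidualLength = params@minResidualLength)
        res <- gbdpDistance(query, subject, p, engine,
                            hspParams = hspParams, mumParams = mumParams)
        cm <- lookupModel(model, algorithm, f, registry)
        s <- toSimilarity(cm, distanceValue(res))
        call <- classifySpecies(cm, distanceValue(res))
        cnt <- matchCounts(res)
        data.frame(query = genomeLabel(query), subject = genomeLabel(subject),
                   engine = engine, algorithm = algorithm, formula = f,
                   distance = distanceValue(res), ratio = distanceRatio(res),
                   ddh = s$similarity, ddh_unclamped = s$unclamped,
                   threshold = cm@threshold, distinct = isDistinct(call),
                   n_used = cnt[["used"]], n_trimmed = cnt[["trimmed"]],
                   n_dropped = cnt[["dropped"]], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write a pipeline report as TSV
#'
#' Deterministic (byte-identical for identical input): numbers are
#' formatted with a fixed precision.
#'
#' @param report data.frame from [runPair()] (or several rbind-ed).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeReport <- function(report, file) {
    fmt <- report
    for (col in c("distance", "ratio", "ddh", "ddh_unclamped"))
        fmt[[col]] <- formatC(report[[col]], digits = 6L, format = "f")
    fmt$threshold <- formatC(report$threshold, digits = 4L, format = "f")
    utils::write.table(fmt, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Run the all-pairs pipeline and write distance matrices
#'
#' Computes the symmetric distance matrix for the chosen formula, writes
#' it in Phylip and Nexus format plus a per-pair TSV report, and returns
#' the matrix.
#'
#' @param genomes list of \linkS4class{Genome}s or FASTA paths.
#' @param params a \linkS4class{GbdpParams} (its \code{formula} is used).
#' @param engine,model,hspParams,mumParams as in [runPair()].
#' @param outDir output directory (created if missing); files
#'   \code{distances.phylip}, \code{distances.nexus}, \code{report.tsv}.
#' @return The distance matrix, invisibly.
#' @export
runMatrix <- function(genomes, params = GbdpParams(),
                      engine = c("hsp", "mum"), model = NULL,
                      hspParams = HspParams(), mumParams = MumParams(),
                      outDir = ".") {
    engine <- match.arg(engine)
    genomes <- lapply(genomes, .as_genome)
    if (engine == "mum")
        params <- GbdpParams(algorithm = "coverage", formula = 1L,
                             lengthMode = params@lengthMode,
                             useLog = params@useLog,
                             evalueCutoff = params@evalueCutoff,
                             minResidualLength = params@minResidualLength)
    m <- distanceMatrix(genomes, params, engine, hspParams, mumParams)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writePhylip(rownames(m), m, file.path(outDir, "distances.phylip"))
    writeNexus(rownames(m), m, file.path(outDir, "distances.nexus"))
    reports <- list()
    for (i in seq_len(length(genomes) - 1L))
        for (j in seq(i + 1L, length(genomes)))
            reports[[length(reports) + 1L]] <-
                runPair(genomes[[i]], genomes[[j]], params, engine,
                        model = model, hspParams = hspParams,
                        mumParams = mumParams, quiet = TRUE)
    writeReport(do.call(rbind, reports), file.path(outDir, "report.tsv"))
    invisible(m)
}
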