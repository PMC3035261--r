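# Conversion of GBDP distances into percent-wise DDH-analogous
# similarities, species delimitation, and refitting of conversion lines.

#' A calibrated distance-to-DDH conversion line
#'
#' One row of the shipped conversion registry: for a given similarity
#' search method, overlap algorithm and distance formula, the linear model
#' \eqn{s(d) = c + m d} mapping a GBDP distance to a percent similarity
#' analogous to a wet-lab DDH value, together with the distance threshold
#' used for species delimitation and the error ratio of that threshold on
#' the calibration data.
#'
#' @slot method similarity search method the line was calibrated on.
#' @slot algorithm overlap algorithm (\code{trimming}/\code{coverage}).
#' @slot formula distance formula (1, 2 or 3).
#' @slot threshold distance threshold: any distance strictly above it
#'   indicates two distinct species.
#' @slot errorRatio error ratio of the threshold on the calibration data.
#' @slot intercept,slope the conversion line (percent; slope in percent
#'   per unit distance, negative for every shipped model).
#' @aliases ConversionModel-class
#' @exportClass ConversionModel
setClass("ConversionModel",
         representation(method = "character", algorithm = "character",
                        formula = "integer", threshold = "numeric",
                        errorRatio = "numeric", intercept = "numeric",
                        slope = "numeric"))

setMethod("show", "ConversionModel", function(object) {
    cat(sprintf(
        "ConversionModel (%s, %s, formula %d): s(d) = %.4f %+.4f d; threshold %.4f (error ratio %.4f)\n",
        object@method, object@algorithm, object@formula, object@intercept,
        object@slope, object@threshold, object@errorRatio))
})

#' The shipped registry of conversion models
#'
#' Reads the versioned plain-text registry (13 calibrated models: trimming
#' with formulas 1-3 for NCBI-BLAST, WU-BLAST, BLAT and BLASTZ, plus
#' coverage/formula 1 for MUMmer).  A replacement registry file with the
#' same columns can be supplied to use constants refitted on an enlarged
#' DDH collection.
#'
#' @param file path to a registry TSV; defaults to the shipped table.
#' @return A data.frame with columns method, algorithm, formula, threshold,
#'   error_ratio, intercept, slope.
#' @export
conversionModels <- function(file = system.file("extdata",
                                                "conversion_models.tsv",
                                                package = "gbdp")) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("method", "algorithm", "formula", "threshold", "error_ratio",
              "intercept", "slope")
    if (!all(need %in% names(df)))
        stop("registry must have columns: ", paste(need, collapse = ", "))
    df
}

#' Look up a conversion model
#'
#' @param method one of \code{ncbi-blast}, \code{wu-blast}, \code{blat},
#'   \code{blastz}, \code{mummer}.
#' @param algorithm \code{trimming} or \code{coverage}.
#' @param formula 1, 2 or 3.
#' @param registry registry data.frame (defaults to the shipped one).
#' @return A \linkS4class{ConversionModel}.
#' @examples
#' lookupModel("ncbi-blast", "trimming", 2)
#' @export
lookupModel <- function(method, algorithm = "trimming", formula = 2L,
                        registry = conversionModels()) {
    hit <- registry$method == method & registry$algorithm == algorithm &
        registry$formula == as.integer(formula)
    if (sum(hit) != 1L) {
        keys <- paste0("(", registry$method, ", ", registry$algorithm, ", ",
                       registry$formula, ")")
        stop(sprintf("no conversion model for (%s, %s, %s); valid keys: %s",
                     method, algorithm, formula, paste(keys, collapse = " ")))
    }
    r <- registry[hit, ]
    new("ConversionModel", method = r$method, algorithm = r$algorithm,
        formula = as.integer(r$formula), threshold = r$threshold,
        errorRatio = r$error_ratio, intercept = r$intercept, slope = r$slope)
}

#' Convert a distance to a percent DDH-analogous similarity
#'
#' Applies the conversion line \eqn{s(d) = c + m d}.  The reported
#' similarity is clamped to \eqn{[0, 100]} so it can be read as a
#' percentage (some calibrated intercepts exceed 100); the unclamped value
#' is returned alongside.
#'
#' @param model a \linkS4class{ConversionModel}.
#' @param d distance(s), \eqn{\ge 0}.
#' @return \code{list(similarity =, unclamped =)}, each the length of
#'   \code{d}.
#' @examples
#' m <- lookupModel("ncbi-blast", "trimming", 1)
#' toSimilarity(m, 0)$similarity  # the calibrated intercept, 96.8979
#' @export
toSimilarity <- function(model, d) {
    stopifnot(is(model, "ConversionModel"), all(d >= 0))
    raw <- model@intercept + model@slope * d
    list(similarity = pmin(pmax(raw, 0), 100), unclamped = raw)
}

#' A species-delimitation call
#'
#' @slot distinct \code{TRUE} when the two genomes are indicated to
#'   represent two distinct species (distance strictly above the model's
#'   threshold).
#' @slot d the distance the call is based on.
#' @slot threshold the model's distance threshold.
#' @slot modelKey "method/algorithm/formula" of the model used.
#' @aliases SpeciesCall-class
#' @exportClass SpeciesCall
setClass("SpeciesCall",
         representation(distinct = "logical", d = "numeric",
                        threshold = "numeric", modelKey = "character"))

setMethod("show", "SpeciesCall", function(object) {
    cat(sprintf("SpeciesCall [%s]: d = %.4f %s threshold %.4f -> %s\n",
                object@modelKey, object@d,
                if (object@distinct) ">" else "<=", object@threshold,
                if (object@distinct) "two distinct species"
                else "same species"))
})

#' @describeIn SpeciesCall is the pair called as two distinct species?
#' @param x a SpeciesCall
#' @export
isDistinct <- function(x) x@distinct

#' Species delimitation from a distance
#'
#' Any distance value strictly above the model's threshold is regarded as
#' indication that the two genomes represent two distinct species;
#' equality at the threshold is not.
#'
#' @param model a \linkS4class{ConversionModel}.
#' @param d distance, \eqn{\ge 0}.
#' @return A \linkS4class{SpeciesCall}.
#' @export
classifySpecies <- function(model, d) {
    stopifnot(is(model, "ConversionModel"), length(d) == 1L, d >= 0)
    new("SpeciesCall", distinct = d > model@threshold, d = d,
        threshold = model@threshold,
        modelKey = paste(model@method, model@algorithm, model@formula,
                         sep = "/"))
}

#' Refit a conversion line from (distance, DDH) pairs
#'
#' Robust line fitting by the Theil-Sen estimator: the slope is the median
#' of all pairwise slopes and the intercept the median of
#' \eqn{ddh - m d}.  Deterministic, resistant to gross outliers, and
#' suitable for recalibrating the conversion on an enlarged collection of
#' DDH values and corresponding genome distances.
#'
#' @param d distances.
#' @param ddh corresponding wet-lab DDH percent similarities.
#' @return \code{list(intercept =, slope =)}.
#' @examples
#' fitConversion(c(0, 0.1, 0.2), 90 - 400 * c(0, 0.1, 0.2))
#' @export
fitConversion <- function(d, ddh) {
    if (length(d) != length(ddh) || length(d) < 3L)
        stop("need at least 3 (distance, DDH) pairs")
    if (length(unique(d)) < 2L)
        stop("degenerate input: all distances are equal")
    n <- length(d)
    ij <- utils::combn(n, 2L)
    dx <- d[ij[2L, ]] - d[ij[1L, ]]
    dy <- ddh[ij[2L, ]] - ddh[ij[1L, ]]
    ok <- dx != 0
    m <- stats::median(dy[ok] / dx[ok])
    c0 <- stats::median(ddh - m * d)
    list(intercept = c0, slope = m)
}
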