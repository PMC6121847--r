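#' OpsinExperiment: cone opsin read counts with sample metadata
#'
#' An [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' one `counts` assay (rows: the seven cone opsins plus `cyp27c1`; columns:
#' individuals) together with per-sample metadata (`species`, `environment`,
#' `total_reads`). `total_reads` is the per-sample count of all sequenced
#' reads after QC, the denominator of the per-million `cyp27c1`
#' normalisation.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#'
#' @seealso [OpsinExperiment()] constructor, [readOpsinData()],
#'   [opsinProfiles()]
#' @export
setClass("OpsinExperiment", contains = "SummarizedExperiment")

setValidity("OpsinExperiment", function(object) {
    msg <- character()
    need <- c(OPSINS, "cyp27c1")
    if (!identical(rownames(object), need))
        msg <- c(msg, paste0("rownames must be exactly: ",
                             paste(need, collapse = ", ")))
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    for (col in c("species", "environment", "total_reads"))
        if (!col %in% names(cd))
            msg <- c(msg, paste0("colData column '", col, "' is required"))
    if (length(msg)) return(msg)

    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (!all(as.character(cd$environment) %in% ENVIRONMENTS))
        msg <- c(msg, paste0("environment must be one of: ",
                             paste(ENVIRONMENTS, collapse = ", ")))
    bad <- which(cd$total_reads < colSums(cts))
    if (length(bad))
        msg <- c(msg, paste0("gene counts exceed total_reads for sample(s): ",
                             paste(colnames(object)[bad], collapse = ", ")))
    if (any(cd$total_reads <= 0)) msg <- c(msg, "total_reads must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct an OpsinExperiment
#'
#' @param counts Integer matrix, rows named by the seven cone opsins plus
#'   `cyp27c1` (any row order; reordered internally), columns by sample id.
#' @param species Character vector, one species label per sample.
#' @param environment Character vector over
#'   `c("river", "great_lake", "crater_lake")` (case-insensitive).
#' @param totalReads Positive integer vector: all sequenced reads per
#'   sample after QC.
#'
#' @return An `OpsinExperiment`.
#' @export
#' @examples
#' cts <- matrix(10L, nrow = 8, ncol = 2,
#'               dimnames = list(c(opsinNames(), "cyp27c1"), c("s1", "s2")))
#' oe <- OpsinExperiment(cts, species = c("A", "A"),
#'                       environment = c("river", "crater_lake"),
#'                       totalReads = c(1e6, 1e6))
#' oe
OpsinExperiment <- function(counts, species, environment, totalReads) {
    counts <- as.matrix(counts)
    need <- c(OPSINS, "cyp27c1")
    missing <- setdiff(need, rownames(counts))
    if (length(missing))
        stop("missing gene rows: ", paste(missing, collapse = ", "))
    counts <- counts[need, , drop = FALSE]
    if (all(counts == round(counts))) storage.mode(counts) <- "integer"
    environment <- parseEnvironment(environment)
    cd <- DataFrame(species = as.character(species),
                    environment = environment,
                    total_reads = as.numeric(totalReads),
                    row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("OpsinExperiment", se)
}

## environment parsing shared by constructor and readers
parseEnvironment <- function(x) {
    lev <- tolower(trimws(as.character(x)))
    bad <- setdiff(unique(lev), ENVIRONMENTS)
    if (length(bad))
        stop("unknown environment label(s): ", paste(bad, collapse = ", "),
             "; allowed: ", paste(ENVIRONMENTS, collapse = ", "))
    factor(lev, levels = ENVIRONMENTS)
}

#' @describeIn OpsinExperiment Matrix of cone opsin counts (7 x samples).
#' @param x,object An `OpsinExperiment`.
#' @export
opsinCounts <- function(x) assay(x, "counts")[OPSINS, , drop = FALSE]

#' @describeIn OpsinExperiment `cyp27c1` counts per sample.
#' @export
cypCounts <- function(x) assay(x, "counts")["cyp27c1", ]

#' @describeIn OpsinExperiment Total sequenced reads per sample.
#' @export
totalReads <- function(x) setNames(colData(x)$total_reads, colnames(x))

#' @describeIn OpsinExperiment Species label per sample.
#' @export
speciesLabels <- function(x) setNames(as.character(colData(x)$species),
                                      colnames(x))

#' @describeIn OpsinExperiment Photic environment factor per sample.
#' @export
photicEnv <- function(x) setNames(colData(x)$environment, colnames(x))

setMethod("show", "OpsinExperiment", function(object) {
    cat("OpsinExperiment with", ncol(object), "samples\n")
    cat("  species:", paste(unique(speciesLabels(object)), collapse = ", "),
        "\n")
    cat("  environments:",
        paste(levels(droplevels(photicEnv(object))), collapse = ", "), "\n")
    cat("  median total reads:",
        format(stats::median(totalReads(object)), big.mark = ","), "\n")
    invisible(NULL)
})

#' ParallelismResult: permutation test of parallel phenotypic change
#'
#' Holds the observed sums of pairwise vector-angle and vector-length
#' differences, the permutation null distributions, and the resulting
#' p-values for one analysis scope.
#'
#' @slot observed Named numeric, `c(angle =, length =)`: observed sums of
#'   pairwise differences (degrees; axis-scaled length units).
#' @slot null Numeric matrix, `n_perm` rows, columns `angle`, `length`.
#' @slot p Named numeric p-values (add-one convention).
#' @slot scope One of `"colonization_1"`, `"colonization_2"`, `"combined"`.
#' @slot nPerm Number of permutations.
#' @slot seed Seed used.
#' @slot vectors data.frame of the observed species vectors.
#'
#' @export
setClass("ParallelismResult",
         representation(observed = "numeric", null = "matrix",
                        p = "numeric", scope = "character",
                        nPerm = "integer", seed = "integer",
                        vectors = "data.frame"))

setValidity("ParallelismResult", function(object) {
    msg <- character()
    if (!all(c("angle", "length") %in% names(object@observed)))
        msg <- c(msg, "observed must have 'angle' and 'length'")
    if (nrow(object@null) != object@nPerm)
        msg <- c(msg, "null must have nPerm rows")
    if (any(object@p <= 0) || any(object@p > 1))
        msg <- c(msg, "p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ParallelismResult", function(object) {
    cat("ParallelismResult [", object@scope, "], ",
        object@nPerm, " permutations\n", sep = "")
    cat(sprintf("  direction: sum of pairwise angles = %.2f deg, P = %.4f\n",
                object@observed["angle"], object@p["angle"]))
    cat(sprintf("  magnitude: sum of pairwise |dL|   = %.4f,     P = %.4f\n",
                object@observed["length"], object@p["length"]))
    invisible(NULL)
})

#' @describeIn ParallelismResult Permutation p-values.
#' @param x A `ParallelismResult`.
#' @export
pValues <- function(x) x@p

#' @describeIn ParallelismResult Observed pairwise-difference sums.
#' @export
observedSums <- function(x) x@observed

#' @describeIn ParallelismResult Null distributions (matrix, one row per
#'   permutation).
#' @export
nullSums <- function(x) x@null

#' @describeIn ParallelismResult Observed species vectors as a data.frame.
#' @export
speciesVectors <- function(x) x@vectors
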