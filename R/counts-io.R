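## Tabular I/O. All readers share one TSV dialect: UTF-8, tab-separated,
## '#' comment lines ignored, header required.

readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE)
}

#' Read a per-sample opsin count table
#'
#' Expects a TSV with columns `sample_id`, the seven cone opsins
#' (`sws1, sws2b, sws2a, rh2b, rh2ab, rh2aa, lws`), `cyp27c1`, and
#' `total_reads`. Counts must be non-negative integers; fractional values
#' are rejected rather than rounded, since counting pipelines emit integers
#' and silent rounding hides upstream errors. Unknown columns are ignored
#' with a warning.
#'
#' @param path Path to the TSV.
#' @return A data.frame with the validated columns.
#' @export
readCountTable <- function(path) {
    df <- readTsv(path)
    need <- c("sample_id", OPSINS, "cyp27c1", "total_reads")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("count table missing column(s): ",
             paste(missing, collapse = ", "))
    extra <- setdiff(names(df), need)
    if (length(extra))
        warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[, need]
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id(s): ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
    numcols <- c(OPSINS, "cyp27c1", "total_reads")
    for (col in numcols) {
        v <- df[[col]]
        if (!is.numeric(v)) stop("column '", col, "' is not numeric")
        if (any(v != round(v)))
            stop("non-integer count in column '", col, "', row(s): ",
                 paste(df$sample_id[v != round(v)], collapse = ", "))
        if (any(v < 0))
            stop("negative count in column '", col, "', row(s): ",
                 paste(df$sample_id[v < 0], collapse = ", "))
    }
    genesum <- rowSums(df[, c(OPSINS, "cyp27c1")])
    bad <- which(genesum > df$total_reads)
    if (length(bad))
        stop("gene counts exceed total_reads in row(s): ",
             paste(df$sample_id[bad], collapse = ", "))
    df
}

#' Write an opsin count table to TSV
#'
#' Inverse of [readCountTable()]: a written table reads back identically.
#'
#' @param df data.frame as returned by [readCountTable()].
#' @param path Output path.
#' @export
writeCountTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `species`, `environment`; environment is
#' parsed case-insensitively against the three levels of
#' [environmentLevels()]. A `population` label (species x environment) is
#' derived.
#'
#' @param path Path to the TSV.
#' @return A data.frame with sample_id, species, environment (factor),
#'   population.
#' @export
readSampleMetadata <- function(path) {
    df <- readTsv(path)
    need <- c("sample_id", "species", "environment")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("metadata missing column(s): ", paste(missing, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample id(s) in metadata")
    df$environment <- parseEnvironment(df$environment)
    df$population <- paste(df$species, df$environment, sep = ":")
    df[, c("sample_id", "species", "environment", "population")]
}

#' Read counts and metadata into an OpsinExperiment
#'
#' @param countsPath,metadataPath TSV paths for [readCountTable()] and
#'   [readSampleMetadata()].
#' @return An [OpsinExperiment].
#' @export
readOpsinData <- function(countsPath, metadataPath) {
    cts <- readCountTable(countsPath)
    meta <- readSampleMetadata(metadataPath)
    missing <- setdiff(cts$sample_id, meta$sample_id)
    if (length(missing))
        stop("sample(s) missing from metadata: ",
             paste(missing, collapse = ", "))
    meta <- meta[match(cts$sample_id, meta$sample_id), ]
    m <- t(as.matrix(cts[, c(OPSINS, "cyp27c1")]))
    colnames(m) <- cts$sample_id
    OpsinExperiment(m, species = meta$species,
                    environment = as.character(meta$environment),
                    totalReads = cts$total_reads)
}

#' Read a lambda-max table
#'
#' TSV with columns `opsin`, `lambda_max_nm`. Exactly the seven cone opsins
#' must be present, with peak absorbances strictly increasing in spectral
#' order (sws1 < sws2b < sws2a < rh2b < rh2ab < rh2aa < lws). The packaged
#' default (`lambdaMaxDefault()`) carries the Midas cichlid values with the
#' Nile tilapia value for sws1.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of peak absorbances (nm) in spectral order.
#' @export
readLambdaMax <- function(path) {
    df <- readTsv(path)
    if (!all(c("opsin", "lambda_max_nm") %in% names(df)))
        stop("lambda-max table needs columns 'opsin', 'lambda_max_nm'")
    lm <- setNames(as.numeric(df$lambda_max_nm), df$opsin)
    missing <- setdiff(OPSINS, names(lm))
    if (length(missing))
        stop("lambda-max table missing opsin(s): ",
             paste(missing, collapse = ", "))
    lm <- lm[OPSINS]
    if (any(lm <= 0)) stop("lambda-max values must be positive")
    if (any(diff(lm) <= 0))
        stop("lambda-max values must be strictly increasing in the order ",
             paste(OPSINS, collapse = " < "))
    lm
}

#' Default lambda-max table
#'
#' @return Named numeric vector (nm) over the seven cone opsins.
#' @export
#' @examples
#' lambdaMaxDefault()
lambdaMaxDefault <- function() {
    readLambdaMax(system.file("extdata", "lambda_max_default.tsv",
                              package = "OpsinShift", mustWork = TRUE))
}

#' Read an irradiance spectrum
#'
#' TSV with columns `wavelength_nm`, `watts` (spectral irradiance,
#' W m-2 nm-1). A `photons` column (photons s-1 m-2 nm-1) is added via
#' [wattsToPhotons()].
#'
#' @param path Path to the TSV.
#' @return data.frame with wavelength_nm, watts, photons.
#' @export
readIrradiance <- function(path) {
    df <- readTsv(path)
    if (!all(c("wavelength_nm", "watts") %in% names(df)))
        stop("irradiance table needs columns 'wavelength_nm', 'watts'")
    df$photons <- wattsToPhotons(df$watts, df$wavelength_nm)
    df
}

#' Convert spectral irradiance from watts to photon flux
#'
#' A photon of wavelength lambda carries energy `h * c / lambda`, so an
#' irradiance of `W` watts per m2 per nm corresponds to
#' `W * lambda / (h * c)` photons per second per m2 per nm (CODATA h and c;
#' lambda in metres).
#'
#' @param watts Spectral irradiance, W m-2 nm-1 (non-negative).
#' @param wavelengthNm Wavelength in nm (positive).
#' @return Photon flux, photons s-1 m-2 nm-1.
#' @export
#' @examples
#' wattsToPhotons(1, 500)  # ~2.52e18 photons
wattsToPhotons <- function(watts, wavelengthNm) {
    h <- 6.62607015e-34  # J s
    c <- 299792458       # m s-1
    if (any(wavelengthNm <= 0)) stop("wavelength must be positive")
    if (any(watts < 0)) stop("irradiance must be non-negative")
    watts * (wavelengthNm * 1e-9) / (h * c)
}
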