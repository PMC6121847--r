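#' Proportional cone opsin expression
#'
#' For each sample, the proportion of each cone opsin's read count relative
#' to the summed read count over all seven cone opsins. `cyp27c1` and
#' `total_reads` never enter the denominator.
#'
#' @param counts Named numeric vector over the seven cone opsins, or a
#'   7 x samples matrix (rows in [opsinNames()] order), or an
#'   [OpsinExperiment].
#' @return A vector (or matrix, samples in columns) of proportions summing
#'   to 1 per sample.
#' @export
#' @examples
#' proportionalExpression(c(sws1 = 0, sws2b = 0, sws2a = 30, rh2b = 0,
#'                          rh2ab = 20, rh2aa = 0, lws = 50))
proportionalExpression <- function(counts) {
    if (is(counts, "OpsinExperiment")) counts <- opsinCounts(counts)
    if (is.matrix(counts)) {
        counts <- counts[OPSINS, , drop = FALSE]
        tot <- colSums(counts)
        if (any(tot == 0))
            stop("no cone opsin expression in sample(s): ",
                 paste(colnames(counts)[tot == 0], collapse = ", "))
        return(sweep(counts, 2, tot, "/"))
    }
    counts <- counts[OPSINS]
    if (any(is.na(counts))) stop("counts must name all seven cone opsins")
    if (any(counts < 0)) stop("negative count")
    tot <- sum(counts)
    if (tot == 0) stop("no cone opsin expression")
    counts / tot
}

#' Predicted spectral sensitivity index
#'
#' The expression-weighted mean of peak absorbance over the seven cone
#' opsins: `sum_i PE_i * lambda_max_i`, in nm. Summarises a retina's
#' predicted spectral tuning in a single number; bounded by the shortest
#' and longest lambda-max in the table.
#'
#' @param pe Proportional-expression vector (sums to 1) or matrix (samples
#'   in columns).
#' @param lambdaMax Named numeric lambda-max table; defaults to
#'   [lambdaMaxDefault()].
#' @return Sensitivity index in nm (one per sample).
#' @export
#' @examples
#' pe <- proportionalExpression(c(sws1 = 0, sws2b = 0, sws2a = 0, rh2b = 0,
#'                                rh2ab = 0, rh2aa = 0, lws = 100))
#' sensitivityIndex(pe)  # 560
sensitivityIndex <- function(pe, lambdaMax = lambdaMaxDefault()) {
    lambdaMax <- lambdaMax[OPSINS]
    if (is.matrix(pe)) {
        pe <- pe[OPSINS, , drop = FALSE]
        s <- colSums(pe)
        if (any(abs(s - 1) > 1e-6))
            stop("proportional expression does not sum to 1 for sample(s): ",
                 paste(colnames(pe)[abs(s - 1) > 1e-6], collapse = ", "))
        return(colSums(pe * lambdaMax))
    }
    pe <- pe[OPSINS]
    if (abs(sum(pe) - 1) > 1e-6)
        stop("proportional expression does not sum to 1 (got ", sum(pe), ")")
    sum(pe * lambdaMax)
}

#' rh2a paralog expression ratio
#'
#' `pe[rh2ab] / (pe[rh2ab] + pe[rh2aa])`: the beta paralog's share of total
#' rh2a expression. `NA` (undefined, not an error) when neither paralog is
#' expressed; such samples are excluded from ratio tests downstream but
#' kept for every other measure.
#'
#' @param pe Proportional-expression vector or matrix (samples in columns).
#' @return Proportion in \[0, 1\] or `NA`.
#' @export
rh2aRatio <- function(pe) {
    if (is.matrix(pe)) {
        den <- pe["rh2ab", ] + pe["rh2aa", ]
        out <- ifelse(den == 0, NA_real_, pe["rh2ab", ] / den)
        return(out)
    }
    den <- pe[["rh2ab"]] + pe[["rh2aa"]]
    if (den == 0) NA_real_ else pe[["rh2ab"]] / den
}

#' cyp27c1 reads per million
#'
#' Absolute normalisation: reads mapped to the cyp27c1 coding sequence per
#' one million sequenced reads.
#'
#' @param cypCount cyp27c1 read count(s).
#' @param totalReads Total sequenced reads per sample (> 0).
#' @return Rate per million reads.
#' @export
cyp27c1PerMillion <- function(cypCount, totalReads) {
    if (any(totalReads == 0)) stop("total_reads must be positive")
    cypCount * 1e6 / totalReads
}

#' Species-relative cyp27c1 expression
#'
#' Each value divided by the highest value within its species, mapping the
#' species maximum to 1. Removes among-species variation in overall
#' expression level so that convergence of within-species change is
#' visible. A species whose values are all zero gets zeros (with a
#' warning).
#'
#' @param values Numeric vector (any cyp27c1 measure, typically per-million
#'   rates).
#' @param species Species label per value.
#' @return Values rescaled into \[0, 1\] within species.
#' @export
cyp27c1SpeciesRelative <- function(values, species) {
    species <- as.character(species)
    mx <- tapply(values, species, max)
    zero <- names(mx)[mx == 0]
    if (length(zero)) {
        warning("species with all-zero cyp27c1: ",
                paste(zero, collapse = ", "), "; values set to 0")
        mx[zero] <- 1  # avoids 0/0; output stays 0
    }
    as.numeric(values / mx[species])
}

#' Per-sample expression profile table
#'
#' One row per sample: proportional expression of the seven cone opsins,
#' the three a priori expression measures (single-cone fraction, rh2a
#' paralog ratio, lws fraction), the predicted sensitivity index, and both
#' cyp27c1 normalisations.
#'
#' @param oe An [OpsinExperiment].
#' @param lambdaMax Lambda-max table; defaults to [lambdaMaxDefault()].
#' @return A data.frame, one row per sample.
#' @export
opsinProfiles <- function(oe, lambdaMax = lambdaMaxDefault()) {
    pe <- proportionalExpression(oe)
    cypm <- cyp27c1PerMillion(cypCounts(oe), totalReads(oe))
    df <- data.frame(
        sample_id = colnames(oe),
        species = speciesLabels(oe),
        environment = photicEnv(oe),
        t(pe),
        single_cone = colSums(pe[c("sws1", "sws2b", "sws2a"), , drop = FALSE]),
        rh2a_ratio = rh2aRatio(pe),
        lws_fraction = pe["lws", ],
        sensitivity_index = sensitivityIndex(pe, lambdaMax),
        cyp_per_million = cypm,
        row.names = NULL, check.names = FALSE)
    df$cyp_rel <- cyp27c1SpeciesRelative(df$cyp_per_million, df$species)
    df
}

#' Population mean phenotypes
#'
#' Mean predicted sensitivity index and mean cyp27c1 measure per
#' species-by-environment population. Because the sensitivity index is
#' linear in proportional expression, the mean of individual indices
#' equals the index of the mean profile.
#'
#' @param profiles data.frame from [opsinProfiles()].
#' @param cyp Which cyp27c1 normalisation to carry: `"relative"`
#'   (species-relative, default) or `"per_million"`.
#' @return data.frame with species, environment, n, sensitivity_index, cyp.
#' @export
populationMeans <- function(profiles, cyp = c("relative", "per_million")) {
    cyp <- match.arg(cyp)
    ycol <- if (cyp == "relative") "cyp_rel" else "cyp_per_million"
    agg <- aggregate(cbind(sensitivity_index = profiles$sensitivity_index,
                           cyp = profiles[[ycol]]),
                     by = list(species = profiles$species,
                               environment = profiles$environment),
                     FUN = mean)
    n <- aggregate(list(n = profiles$sample_id),
                   by = list(species = profiles$species,
                             environment = profiles$environment),
                   FUN = length)
    merge(agg, n)
}
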