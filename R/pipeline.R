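#' Run the full analysis pipeline
#'
#' Orchestrates counts -> profiles -> rank statistics -> parallelism
#' (and optionally consensus calling), writing one TSV per stage plus a
#' JSON manifest (package version, seed, parameter echo, output
#' checksums) to the output directory. Every stochastic stage is seeded;
#' a missing seed is an error.
#'
#' @param config A named list or path to a YAML file with fields:
#'   `counts`, `metadata` (TSV paths), `lambda_max` (optional path;
#'   packaged default otherwise), `out_dir`, `seed` (required),
#'   `n_perm` (default 999), `scale` ("sd"/"none"), `cyp`
#'   ("relative"/"per_million"), `fdr_family` ("per-measure"/"global"),
#'   `measures` (optional character vector), and optionally `pileup`
#'   (TSV with individual/gene columns) for the consensus stage.
#' @return Invisibly, a list with profiles, srh, per_species,
#'   rank_maintenance, parallelism (one result per scope), consensus
#'   (or NULL), manifest.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    need <- c("counts", "metadata", "out_dir", "seed")
    missing <- setdiff(need, names(config))
    if (length(missing))
        stop("pipeline config missing field(s): ",
             paste(missing, collapse = ", "))
    for (f in c("counts", "metadata", "lambda_max", "pileup"))
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stop("input file not found: ", config[[f]])
    nPerm <- config$n_perm %||% 999
    scale <- config$scale %||% "sd"
    cyp <- config$cyp %||% "relative"
    family <- config$fdr_family %||% "per-measure"
    measures <- config$measures %||%
        c("single_cone", "rh2a_ratio", "lws_fraction", "cyp_per_million")
    seed <- as.integer(config$seed)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    outfile <- function(x) file.path(config$out_dir, x)
    tsv <- function(df, name) {
        write.table(df, outfile(name), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        name
    }
    written <- character()

    oe <- stage("read", readOpsinData(config$counts, config$metadata))
    lambdaMax <- stage("lambda_max", if (is.null(config$lambda_max))
        lambdaMaxDefault() else readLambdaMax(config$lambda_max))

    profiles <- stage("profiles", opsinProfiles(oe, lambdaMax))
    written <- c(written, tsv(profiles, "profiles.tsv"))

    srh <- stage("rank_stats", {
        out <- lapply(c(measures, "sensitivity_index", "cyp_rel"),
                      function(m) {
            keep <- !is.na(profiles[[m]])
            cbind(measure = m,
                  scheirerRayHare(profiles[[m]][keep],
                                  profiles$species[keep],
                                  profiles$environment[keep]))
        })
        do.call(rbind, out)
    })
    written <- c(written, tsv(srh, "scheirer_ray_hare.tsv"))

    perSpecies <- stage("per_species",
                        perSpeciesTests(profiles, measures = measures,
                                        family = family))
    written <- c(written, tsv(perSpecies, "per_species_kw.tsv"))

    rankMaint <- stage("rank_maintenance", {
        pm <- populationMeans(profiles)
        pairs <- list(colonization_1 = c("river", "great_lake"),
                      colonization_2 = c("great_lake", "crater_lake"))
        out <- lapply(names(pairs), function(ev) {
            e <- pairs[[ev]]
            m1 <- pm[pm$environment == e[1], ]
            m2 <- pm[pm$environment == e[2], ]
            common <- intersect(m1$species, m2$species)
            r <- rankMaintenance(
                setNames(m1$sensitivity_index[match(common, m1$species)],
                         common),
                setNames(m2$sensitivity_index[match(common, m2$species)],
                         common))
            cbind(event = ev, r)
        })
        do.call(rbind, out)
    })
    written <- c(written, tsv(rankMaint, "rank_maintenance.tsv"))

    parallelism <- stage("parallelism", {
        scopes <- c("colonization_1", "colonization_2", "combined")
        res <- lapply(seq_along(scopes), function(i)
            parallelismTest(profiles, scope = scopes[i], nPerm = nPerm,
                            seed = seed + i, scale = scale, cyp = cyp))
        names(res) <- scopes
        res
    })
    ptab <- do.call(rbind, lapply(parallelism, function(r)
        data.frame(scope = r@scope,
                   sum_angle = observedSums(r)["angle"],
                   sum_length = observedSums(r)["length"],
                   p_angle = pValues(r)["angle"],
                   p_length = pValues(r)["length"],
                   n_perm = r@nPerm, row.names = NULL)))
    written <- c(written, tsv(ptab, "parallelism.tsv"))

    consensus <- NULL
    if (!is.null(config$pileup)) {
        consensus <- stage("consensus", {
            pu <- readPileup(config$pileup)
            consensusFromPileup(pu)
        })
        ctab <- do.call(rbind, lapply(names(consensus), function(g)
            data.frame(gene = g,
                       individual = names(consensus[[g]]),
                       sequence = unlist(consensus[[g]]),
                       row.names = NULL)))
        written <- c(written, tsv(ctab, "consensus.tsv"))
    }

    manifest <- list(package = "OpsinShift",
                     version = as.character(packageVersion("OpsinShift")),
                     seed = seed, n_perm = nPerm, scale = scale, cyp = cyp,
                     fdr_family = family, measures = measures,
                     inputs = config[c("counts", "metadata", "lambda_max")],
                     outputs = as.list(md5sum(vapply(written, outfile, ""))))
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(profiles = profiles, srh = srh,
                   per_species = perSpecies,
                   rank_maintenance = rankMaint,
                   parallelism = parallelism,
                   consensus = consensus, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
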