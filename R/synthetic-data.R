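## Dirichlet-multinomial simulator for retinal opsin expression datasets.
## Generates count tables, metadata and pileups with the statistical
## structure the analysis assumes: compositional opsin counts with
## species-specific baselines, environment-driven shifts toward
## short-wavelength opsins on the centered log-ratio (CLR) scale (so
## shifts compose additively and stay on the simplex), overdispersed
## cyp27c1 counts, and log-normal library sizes.

softmaxClr <- function(clr) {
    e <- exp(clr - max(clr))
    e / sum(e)
}

## baseline opsin compositions for seven plausible species: mostly
## sws2a/rh2a/lws retinas (long-wavelength subsets typical of turbid
## habitats), differing among species in lws and single-cone shares
defaultBaselines <- function(n = 7) {
    p <- rbind(
        c(0.010, 0.020, 0.200, 0.020, 0.300, 0.150, 0.300),
        c(0.020, 0.050, 0.250, 0.050, 0.250, 0.080, 0.300),
        c(0.010, 0.030, 0.150, 0.010, 0.400, 0.200, 0.200),
        c(0.030, 0.080, 0.300, 0.040, 0.200, 0.100, 0.250),
        c(0.010, 0.020, 0.100, 0.020, 0.350, 0.250, 0.250),
        c(0.020, 0.040, 0.220, 0.030, 0.280, 0.060, 0.350),
        c(0.010, 0.060, 0.180, 0.050, 0.320, 0.180, 0.200))
    colnames(p) <- OPSINS
    clr <- t(apply(p[seq_len(n), , drop = FALSE], 1,
                   function(r) log(r) - mean(log(r))))
    rownames(clr) <- paste0("sp", seq_len(n))
    clr
}

## CLR direction of an environment shift toward short-wavelength opsins:
## positive weight on sws opsins, strongly negative on lws; zero-sum
shortShiftDirection <- function() {
    w <- c(1.2, 1.0, 0.6, 0.3, -0.3, -0.8, -2.0)
    names(w) <- OPSINS
    w - mean(w)
}

#' Build a simulation configuration
#'
#' @param nSpecies Number of species (default 7).
#' @param nPerPopulation Individuals per species-by-environment
#'   population: a scalar, or a `nSpecies x 3` matrix (rows species,
#'   columns river/great_lake/crater_lake).
#' @param baselineClr Species baseline opsin compositions in CLR
#'   coordinates (`nSpecies x 7`); default: seven distinct
#'   long-wavelength-biased retinas.
#' @param sharedBaseline If TRUE all species share the first baseline row
#'   (used by the fully exchangeable `null` preset).
#' @param shiftMagnitude Cumulative CLR shift per environment, named
#'   `c(river =, great_lake =, crater_lake =)`; magnitude of the
#'   displacement along `shiftDirection`.
#' @param shiftDirection Zero-sum CLR direction of the environment shift;
#'   default pushes expression toward short-wavelength opsins.
#' @param dirichletPrecision Concentration of the individual-level
#'   Dirichlet around the population composition (higher = less
#'   individual variation; default 150).
#' @param librarySizeMedian Median library size (default 1.4e6 reads,
#'   typical of retinal RNA-seq libraries at this depth).
#' @param librarySdLog Log-scale SD of library size (default 0.3).
#' @param opsinBudgetFraction Fraction of the library mapping to the
#'   seven cone opsins (default 0.005; absolute budgets do not affect any
#'   proportion-based statistic).
#' @param cypMeanPerMillion Mean cyp27c1 rate (reads per million) per
#'   environment; the turbid great lake is the natural maximum.
#' @param cypDispersion Negative-binomial size parameter for cyp27c1
#'   counts (smaller = more overdispersed).
#' @param switchSpecies Optional species name that swaps its sws2a
#'   expression to sws2b and gains rh2b in the crater lake (a qualitative
#'   paralog switch rather than a graded shift).
#' @return A `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(nSpecies = 7,
                             nPerPopulation = 5,
                             baselineClr = defaultBaselines(nSpecies),
                             sharedBaseline = FALSE,
                             shiftMagnitude = c(river = 0, great_lake = 0.5,
                                                crater_lake = 1.2),
                             shiftDirection = shortShiftDirection(),
                             dirichletPrecision = 150,
                             librarySizeMedian = 1.4e6,
                             librarySdLog = 0.3,
                             opsinBudgetFraction = 0.005,
                             cypMeanPerMillion = c(river = 10,
                                                   great_lake = 60,
                                                   crater_lake = 25),
                             cypDispersion = 5,
                             switchSpecies = NULL) {
    if (sharedBaseline)
        baselineClr <- matrix(baselineClr[1, ], nSpecies, ncol(baselineClr),
                              byrow = TRUE,
                              dimnames = list(paste0("sp", seq_len(nSpecies)),
                                              OPSINS))
    if (nrow(baselineClr) != nSpecies)
        stop("baselineClr needs one row per species")
    if (is.matrix(nPerPopulation)) {
        if (!all(dim(nPerPopulation) == c(nSpecies, 3)))
            stop("nPerPopulation matrix must be nSpecies x 3")
    } else {
        nPerPopulation <- matrix(nPerPopulation, nSpecies, 3)
    }
    dimnames(nPerPopulation) <- list(rownames(baselineClr), ENVIRONMENTS)
    if (dirichletPrecision <= 0) stop("dirichletPrecision must be positive")
    if (any(nPerPopulation < 1)) stop("each population needs >= 1 individual")
    cfg <- list(nSpecies = nSpecies,
                species = rownames(baselineClr),
                nPerPopulation = nPerPopulation,
                baselineClr = baselineClr,
                shiftMagnitude = shiftMagnitude[ENVIRONMENTS],
                shiftDirection = shiftDirection,
                dirichletPrecision = dirichletPrecision,
                librarySizeMedian = librarySizeMedian,
                librarySdLog = librarySdLog,
                opsinBudgetFraction = opsinBudgetFraction,
                cypMeanPerMillion = cypMeanPerMillion[ENVIRONMENTS],
                cypDispersion = cypDispersion,
                switchSpecies = switchSpecies)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Named simulation presets
#'
#' * `null` — fully exchangeable data: shared species baseline, zero
#'   environment shift, identical cyp27c1 means. The parallelism test is
#'   calibrated on this preset.
#' * `parallel_weak` — distinct species baselines, mild common shift
#'   toward short wavelengths.
#' * `parallel_strong` — distinct baselines, strong common shift with low
#'   individual noise: all species' mean vectors align within ~30 degrees
#'   of the preset direction.
#' * `paper_like` — distinct baselines, graded shift, one species with
#'   the sws2a-to-sws2b paralog switch in the crater lake, 5-6
#'   individuals per population with one population of 3.
#'
#' @param name Preset name.
#' @return A `SimulationConfig`.
#' @export
simulationPreset <- function(name = c("null", "parallel_weak",
                                      "parallel_strong", "paper_like")) {
    name <- match.arg(name)
    switch(name,
        null = simulationConfig(
            sharedBaseline = TRUE,
            shiftMagnitude = c(river = 0, great_lake = 0, crater_lake = 0),
            cypMeanPerMillion = c(river = 30, great_lake = 30,
                                  crater_lake = 30)),
        parallel_weak = simulationConfig(
            shiftMagnitude = c(river = 0, great_lake = 0.25,
                               crater_lake = 0.6),
            cypMeanPerMillion = c(river = 15, great_lake = 40,
                                  crater_lake = 25)),
        parallel_strong = simulationConfig(
            shiftMagnitude = c(river = 0, great_lake = 1.2,
                               crater_lake = 2.4),
            dirichletPrecision = 400,
            cypMeanPerMillion = c(river = 10, great_lake = 80,
                                  crater_lake = 30),
            cypDispersion = 20),
        paper_like = {
            n <- matrix(c(5, 6, 5, 6, 5, 6, 5,
                          5, 3, 6, 5, 6, 5, 6,
                          6, 5, 5, 6, 5, 6, 5), 7, 3)
            simulationConfig(nPerPopulation = n,
                             switchSpecies = "sp2")
        })
}

## population-level CLR composition for one species x environment cell
populationClr <- function(cfg, sp, env) {
    clr <- cfg$baselineClr[sp, ] +
        cfg$shiftMagnitude[[env]] * cfg$shiftDirection
    if (!is.null(cfg$switchSpecies) && sp == cfg$switchSpecies &&
        env == "crater_lake") {
        ## paralog switch: sws2a expression moves to sws2b, rh2b appears
        tmp <- clr[["sws2a"]]
        clr[["sws2a"]] <- clr[["sws2b"]]
        clr[["sws2b"]] <- tmp
        clr[["rh2b"]] <- clr[["rh2b"]] + 2
        clr <- clr - mean(clr)
    }
    clr
}

rdirichlet1 <- function(alpha) {
    if (any(alpha <= 0)) stop("invalid Dirichlet parameter")
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
}

#' Simulate an opsin expression dataset
#'
#' Per individual: the population composition (species baseline CLR plus
#' environment shift) is perturbed by a Dirichlet draw, opsin counts are
#' multinomial given an opsin read budget (a fixed fraction of the
#' log-normal library size), and cyp27c1 counts are negative-binomial
#' with an environment-specific mean rate. Byte-identical output under a
#' fixed seed.
#'
#' @param config A `SimulationConfig` (see [simulationConfig()],
#'   [simulationPreset()]).
#' @param seed Integer seed (required).
#' @return List: `experiment` ([OpsinExperiment]) and `truth` (per-
#'   individual true proportions, true population compositions and
#'   sensitivity indices, the shift direction/magnitudes, and the config).
#' @export
#' @examples
#' sim <- generateCounts(simulationPreset("paper_like"), seed = 1)
#' sim$experiment
generateCounts <- function(config, seed) {
    if (missing(seed)) stop("seed is required for reproducibility")
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(as.integer(seed))
    rows <- list(); truthP <- list()
    ids <- character(); spv <- character(); envv <- character()
    libs <- numeric(); cyps <- integer()
    counts <- NULL
    popClr <- list()
    for (sp in config$species) {
        for (env in ENVIRONMENTS) {
            clr <- populationClr(config, sp, env)
            popClr[[paste(sp, env, sep = ":")]] <- clr
            base <- softmaxClr(clr)
            n <- config$nPerPopulation[sp, env]
            for (i in seq_len(n)) {
                id <- sprintf("%s_%s_%02d", sp, env, i)
                lib <- round(rlnorm(1, log(config$librarySizeMedian),
                                    config$librarySdLog))
                budget <- max(1, round(config$opsinBudgetFraction * lib))
                p <- rdirichlet1(config$dirichletPrecision * base)
                ct <- rmultinom(1, budget, p)[, 1]
                cyp <- rnbinom(1, size = config$cypDispersion,
                               mu = config$cypMeanPerMillion[[env]] *
                                   lib / 1e6)
                ids <- c(ids, id); spv <- c(spv, sp); envv <- c(envv, env)
                libs <- c(libs, lib); cyps <- c(cyps, cyp)
                counts <- cbind(counts, c(ct, cyp))
                truthP[[id]] <- p
            }
        }
    }
    rownames(counts) <- c(OPSINS, "cyp27c1")
    colnames(counts) <- ids
    oe <- OpsinExperiment(counts, species = spv, environment = envv,
                          totalReads = pmax(libs, colSums(counts)))
    truth <- list(proportions = do.call(rbind, truthP),
                  populationClr = popClr,
                  populationComposition = lapply(popClr, softmaxClr),
                  shiftDirection = config$shiftDirection,
                  shiftMagnitude = config$shiftMagnitude,
                  config = config, seed = as.integer(seed))
    list(experiment = oe, truth = truth)
}

#' Simulate a pileup for a diploid genotype
#'
#' Per site, reads are drawn multinomially: each of `coverage` reads picks
#' one of the two alleles with probability 1/2 and is then corrupted to a
#' uniform random base with probability `errorRate`.
#'
#' @param hap1,hap2 Haplotype strings over A/C/G/T, equal length.
#' @param coverage Reads per site (scalar or per-site vector; 0 gives an
#'   empty column, which downstream consensus masks to N).
#' @param errorRate Per-read error probability in \[0, 1).
#' @param seed Integer seed (required).
#' @return data.frame with position, A, C, G, T.
#' @export
generatePileup <- function(hap1, hap2, coverage, errorRate = 0.001, seed) {
    if (missing(seed)) stop("seed is required for reproducibility")
    if (errorRate < 0 || errorRate >= 1)
        stop("errorRate must lie in [0, 1)")
    h1 <- strsplit(toupper(hap1), "")[[1]]
    h2 <- strsplit(toupper(hap2), "")[[1]]
    if (length(h1) != length(h2)) stop("haplotypes differ in length")
    if (!all(c(h1, h2) %in% BASES)) stop("haplotypes must be over A/C/G/T")
    L <- length(h1)
    coverage <- rep_len(coverage, L)
    if (any(coverage < 0)) stop("coverage must be non-negative")
    set.seed(as.integer(seed))
    m <- matrix(0L, L, 4, dimnames = list(NULL, BASES))
    for (i in seq_len(L)) {
        p <- setNames(rep(errorRate / 4, 4), BASES)
        p[h1[i]] <- p[h1[i]] + (1 - errorRate) / 2
        p[h2[i]] <- p[h2[i]] + (1 - errorRate) / 2
        if (coverage[i] > 0)
            m[i, ] <- rmultinom(1, coverage[i], p)[, 1]
    }
    data.frame(position = seq_len(L), m)
}

#' Write a simulated dataset to disk
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth.json` (true population
#' compositions, shift parameters and seed) under `outDir`.
#'
#' @param config A `SimulationConfig` or preset name.
#' @param seed Integer seed.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the list from [generateCounts()].
#' @export
simulateDataset <- function(config, seed, outDir) {
    if (is.character(config)) config <- simulationPreset(config)
    sim <- generateCounts(config, seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    oe <- sim$experiment
    cts <- data.frame(sample_id = colnames(oe),
                      t(assay(oe, "counts")),
                      total_reads = totalReads(oe),
                      check.names = FALSE, row.names = NULL)
    writeCountTable(cts, file.path(outDir, "counts.tsv"))
    meta <- data.frame(sample_id = colnames(oe),
                       species = speciesLabels(oe),
                       environment = as.character(photicEnv(oe)),
                       row.names = NULL)
    write.table(meta, file.path(outDir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(seed = sim$truth$seed,
             shiftMagnitude = as.list(sim$truth$shiftMagnitude),
             shiftDirection = as.list(sim$truth$shiftDirection),
             populationComposition = sim$truth$populationComposition),
        file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
    invisible(sim)
}
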