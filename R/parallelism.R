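## Vector analysis of parallel phenotypic change in the 2-D
## (predicted sensitivity index, relative cyp27c1 expression) plane.

eventEnvs <- function(event) {
    switch(event,
           colonization_1 = c("river", "great_lake"),
           colonization_2 = c("great_lake", "crater_lake"),
           stop("unknown event: ", event))
}

#' Extract individual phenotype points
#'
#' One row per individual with the two phenotype axes used by the
#' parallelism analysis: predicted sensitivity index (nm) and a cyp27c1
#' measure.
#'
#' @param profiles data.frame from [opsinProfiles()] (or any data.frame
#'   with species, environment, sensitivity_index and the chosen cyp
#'   column).
#' @param cyp `"relative"` (species-relative, default) or `"per_million"`.
#' @return data.frame with species, environment, x, y.
#' @export
phenotypePoints <- function(profiles, cyp = c("relative", "per_million")) {
    cyp <- match.arg(cyp)
    ycol <- if (cyp == "relative") "cyp_rel" else "cyp_per_million"
    data.frame(species = as.character(profiles$species),
               environment = as.character(profiles$environment),
               x = profiles$sensitivity_index,
               y = profiles[[ycol]])
}

## Scale each axis by its SD across population (species x environment)
## means. nm and relative-expression units are incommensurable and angles
## are scale-dependent, so some common scale is needed; SD of population
## means is the default. Degenerate axes (SD 0) are left unscaled.
scaleAxes <- function(points, scale = c("sd", "none")) {
    scale <- match.arg(scale)
    if (scale == "none") return(points)
    pop <- paste(points$species, points$environment, sep = ":")
    mx <- tapply(points$x, pop, mean)
    my <- tapply(points$y, pop, mean)
    sx <- sd(mx); sy <- sd(my)
    if (is.na(sx) || sx == 0) sx <- 1
    if (is.na(sy) || sy == 0) sy <- 1
    points$x <- points$x / sx
    points$y <- points$y / sy
    points
}

#' Build per-species change vectors for one colonization event
#'
#' Connects each species' population mean in the ancestral environment to
#' its mean in the derived environment (colonization 1: river to great
#' lake; colonization 2: great lake to crater lake). Species missing from
#' either environment are excluded with a warning. Axis scaling must be
#' applied to the points beforehand (see [parallelismTest()]); this
#' function works on the coordinates it is given.
#'
#' @param points data.frame from [phenotypePoints()] (scaled or not).
#' @param event `"colonization_1"` or `"colonization_2"`.
#' @return data.frame with species, dx, dy, length, angle (degrees,
#'   direction of the vector in the plane).
#' @export
buildSpeciesVectors <- function(points,
                                event = c("colonization_1",
                                          "colonization_2")) {
    event <- match.arg(event)
    envs <- eventEnvs(event)
    sp <- sort(unique(points$species))
    rows <- lapply(sp, function(s) {
        a <- points[points$species == s & points$environment == envs[1], ]
        b <- points[points$species == s & points$environment == envs[2], ]
        if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
        dx <- mean(b$x) - mean(a$x)
        dy <- mean(b$y) - mean(a$y)
        data.frame(species = s, event = event, dx = dx, dy = dy,
                   length = sqrt(dx^2 + dy^2),
                   angle = atan2(dy, dx) * 180 / pi)
    })
    dropped <- sp[vapply(rows, is.null, logical(1))]
    if (length(dropped))
        warning("species missing an environment for ", event, ": ",
                paste(dropped, collapse = ", "))
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Angle between two vectors
#'
#' Arc-cosine of the normalised dot product, in degrees within
#' \[0, 180\]. Undefined (NA, with a warning) if either vector has zero
#' length.
#'
#' @param v1,v2 Numeric length-2 vectors.
#' @return Angle in degrees.
#' @export
#' @examples
#' angleBetween(c(1, 0), c(0, 1))  # 90
angleBetween <- function(v1, v2) {
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) {
        warning("zero-length vector: angle undefined")
        return(NA_real_)
    }
    acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Sums of pairwise angle and length differences
#'
#' Over all `n(n-1)/2` unordered pairs of species vectors: the sum of
#' between-vector angles and the sum of absolute length differences.
#' Pairs involving a zero-length vector are excluded from the angle sum
#' (direction undefined) but retained in the length sum.
#'
#' @param vectors data.frame from [buildSpeciesVectors()].
#' @return Named numeric `c(angle =, length =, n_pairs =)`.
#' @export
pairwiseDifferenceSums <- function(vectors) {
    n <- nrow(vectors)
    if (is.null(n) || n < 2) stop("need at least 2 vectors")
    pr <- combn(n, 2)
    th <- atan2(vectors$dy, vectors$dx)
    len <- vectors$length
    d <- abs(th[pr[1, ]] - th[pr[2, ]])
    d <- pmin(d, 2 * pi - d) * 180 / pi
    zero <- len[pr[1, ]] == 0 | len[pr[2, ]] == 0
    if (any(zero)) {
        warning(sum(zero), " pair(s) with a zero-length vector excluded ",
                "from the angle sum")
        d[zero] <- 0
    }
    c(angle = sum(d), length = sum(abs(len[pr[1, ]] - len[pr[2, ]])),
      n_pairs = ncol(pr))
}

## Fast inner kernel used for the permutation null: given per-species
## displacement columns, return c(sum angle, sum length) over precomputed
## pair indices.
pairSumsKernel <- function(dx, dy, i1, i2) {
    th <- atan2(dy, dx)
    d <- abs(th[i1] - th[i2])
    d <- pmin(d, 2 * pi - d)
    len <- sqrt(dx^2 + dy^2)
    c(sum(d) * 180 / pi, sum(abs(len[i1] - len[i2])))
}

#' Permutation test of phenotypic parallelism
#'
#' Tests whether species change in parallel — similar direction (vector
#' angles) and magnitude (vector lengths) — when colonizing a novel photic
#' environment, in the 2-D plane of predicted sensitivity index and
#' relative cyp27c1 expression.
#'
#' Observed statistic: per-species vectors connect population means
#' between the ancestral and derived environment of each event; the sums
#' of all pairwise angle differences and pairwise absolute length
#' differences are formed (21 pairs for 7 species). For the combined
#' scope the sums from both colonization events are added.
#'
#' Null: species identity is randomized within each environment; in each
#' of `nPerm` permuted datasets one individual per pseudo-species is drawn
#' from each environment, vectors connect those individuals, and the same
#' pairwise sums are computed. (Observed vectors use population means
#' while null vectors use single individuals; this asymmetry follows the
#' procedure the test implements. `nullMeans = TRUE` instead averages all
#' individuals of each pseudo-species, for sensitivity analysis.)
#'
#' The p-value counts permuted sums strictly smaller than the observed sum
#' (small sums = parallel change), with the add-one convention
#' `p = (k + 1) / (nPerm + 1)`; ties count against rejection. Species
#' lacking individuals in an environment of the scope are excluded from
#' both the observed and the null datasets.
#'
#' @param profiles data.frame from [opsinProfiles()], or an
#'   [OpsinExperiment] (profiled with default lambda-max).
#' @param scope `"combined"` (both events; default), `"colonization_1"`
#'   or `"colonization_2"`.
#' @param nPerm Number of permutations (default 999).
#' @param seed Integer seed; required (every stochastic step is seeded).
#' @param scale `"sd"` (default: scale each axis by the SD of its
#'   population means) or `"none"` (raw nm / relative-expression axes).
#' @param cyp Which cyp27c1 normalisation to use for the y axis.
#' @param nullMeans Use pseudo-species means instead of single drawn
#'   individuals in the null (default FALSE).
#' @return A [ParallelismResult].
#' @export
parallelismTest <- function(profiles,
                            scope = c("combined", "colonization_1",
                                      "colonization_2"),
                            nPerm = 999, seed,
                            scale = c("sd", "none"),
                            cyp = c("relative", "per_million"),
                            nullMeans = FALSE) {
    scope <- match.arg(scope)
    if (missing(seed)) stop("seed is required for reproducibility")
    seed <- as.integer(seed)
    if (is(profiles, "OpsinExperiment")) profiles <- opsinProfiles(profiles)
    points <- scaleAxes(phenotypePoints(profiles, cyp = cyp), scale)
    events <- if (scope == "combined")
        c("colonization_1", "colonization_2") else scope

    ## species usable in every environment the scope touches
    envsNeeded <- unique(unlist(lapply(events, eventEnvs)))
    tab <- table(points$species, points$environment)
    sp <- rownames(tab)[apply(tab[, envsNeeded, drop = FALSE] > 0, 1, all)]
    dropped <- setdiff(rownames(tab), sp)
    if (length(dropped))
        warning("species excluded (missing an environment): ",
                paste(dropped, collapse = ", "))
    if (length(sp) < 2) stop("need >= 2 species present in all environments")
    points <- points[points$species %in% sp, ]
    S <- length(sp)

    vecs <- do.call(rbind, lapply(events, function(ev)
        buildSpeciesVectors(points, ev)))
    obs <- c(angle = 0, length = 0)
    for (ev in events) {
        s <- pairwiseDifferenceSums(vecs[vecs$event == ev, ])
        obs <- obs + s[c("angle", "length")]
    }

    ## per-environment individual coordinates and the label layout used to
    ## randomize species identity within the environment
    envData <- lapply(envsNeeded, function(e) {
        d <- points[points$environment == e, ]
        list(x = d$x, y = d$y, n = nrow(d),
             labels = d$species,
             firstPos = match(sp, d$species),
             groups = split(seq_len(nrow(d)), factor(d$species, levels = sp)))
    })
    names(envData) <- envsNeeded
    pr <- combn(S, 2); i1 <- pr[1, ]; i2 <- pr[2, ]

    set.seed(seed)
    null <- matrix(NA_real_, nPerm, 2,
                   dimnames = list(NULL, c("angle", "length")))
    for (k in seq_len(nPerm)) {
        ## one draw per pseudo-species per environment: a uniform random
        ## permutation of individuals against the fixed label layout,
        ## reading one slot per species label
        drawX <- drawY <- list()
        for (e in envsNeeded) {
            ed <- envData[[e]]
            idx <- sample.int(ed$n)  # individual idx[j] takes label j's species
            if (nullMeans) {
                drawX[[e]] <- vapply(ed$groups,
                                     function(g) mean(ed$x[idx[g]]), 0)
                drawY[[e]] <- vapply(ed$groups,
                                     function(g) mean(ed$y[idx[g]]), 0)
            } else {
                chosen <- idx[ed$firstPos]
                drawX[[e]] <- ed$x[chosen]
                drawY[[e]] <- ed$y[chosen]
            }
        }
        tot <- c(0, 0)
        for (ev in events) {
            ee <- eventEnvs(ev)
            dx <- drawX[[ee[2]]] - drawX[[ee[1]]]
            dy <- drawY[[ee[2]]] - drawY[[ee[1]]]
            tot <- tot + pairSumsKernel(dx, dy, i1, i2)
        }
        null[k, ] <- tot
    }

    p <- c(angle = (sum(null[, "angle"] < obs["angle"]) + 1) / (nPerm + 1),
           length = (sum(null[, "length"] < obs["length"]) + 1) / (nPerm + 1))
    new("ParallelismResult", observed = obs, null = null, p = p,
        scope = scope, nPerm = as.integer(nPerm), seed = seed,
        vectors = vecs)
}
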