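test_that("species vectors connect population means", {
    pts <- gaussianPoints(nSpecies = 7, seed = 4)
    vecs <- buildSpeciesVectors(
        phenotypePoints(data.frame(pts,
                                   cyp_per_million = pts$cyp_rel)),
        "colonization_2")
    expect_equal(nrow(vecs), 7)

    ## identical means in both environments give a zero vector
    one <- data.frame(species = "a",
                      environment = rep(c("great_lake", "crater_lake"),
                                        each = 2),
                      x = c(1, 3, 0, 4), y = c(2, 2, 1, 3))
    v <- buildSpeciesVectors(one, "colonization_2")
    expect_equal(v$dx, 0)
    expect_equal(v$dy, 0)
    expect_equal(v$length, 0)

    ## translating every point leaves the vectors unchanged
    pts2 <- phenotypePoints(data.frame(pts, cyp_per_million = 0))
    shifted <- pts2
    shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 3
    expect_equal(buildSpeciesVectors(shifted, "colonization_1")[, c("dx", "dy")],
                 buildSpeciesVectors(pts2, "colonization_1")[, c("dx", "dy")])

    ## a species missing an environment is dropped with a warning
    expect_warning(
        v3 <- buildSpeciesVectors(pts2[!(pts2$species == "sp3" &
                                         pts2$environment == "river"), ],
                                  "colonization_1"),
        "sp3")
    expect_equal(nrow(v3), 6)
})

test_that("vector angles follow the arc-cosine definition", {
    expect_equal(angleBetween(c(1, 2), c(1, 2)), 0, tolerance = 1e-4)
    expect_equal(angleBetween(c(1, 2), c(-1, -2)), 180, tolerance = 1e-4)
    expect_equal(angleBetween(c(1, 0), c(0, 1)), 90)
    expect_warning(a <- angleBetween(c(0, 0), c(1, 1)), "zero-length")
    expect_true(is.na(a))
})

test_that("pairwise sums enumerate n(n-1)/2 pairs", {
    mkv <- function(dx, dy)
        data.frame(dx = dx, dy = dy, length = sqrt(dx^2 + dy^2))
    ## 7 vectors -> 21 pairs
    set.seed(8)
    v7 <- mkv(rnorm(7), rnorm(7))
    s <- pairwiseDifferenceSums(v7)
    expect_equal(unname(s["n_pairs"]), 21)
    ## identical vectors -> zero sums
    vSame <- mkv(rep(1, 4), rep(2, 4))
    expect_equal(unname(pairwiseDifferenceSums(vSame)[c("angle", "length")]),
                 c(0, 0))
    ## unit vectors at 0, 90, 180 degrees -> 90 + 180 + 90
    v3 <- mkv(c(1, 0, -1), c(0, 1, 0))
    expect_equal(unname(pairwiseDifferenceSums(v3)["angle"]), 360)
    expect_error(pairwiseDifferenceSums(v3[1, ]), "at least 2")
    ## zero-length vectors leave the angle sum but stay in the length sum
    v0 <- mkv(c(0, 1, -1), c(0, 0, 0))
    expect_warning(s0 <- pairwiseDifferenceSums(v0), "zero-length")
    expect_equal(unname(s0["angle"]), 180)
    expect_equal(unname(s0["length"]), 2)
})

test_that("the permutation test is deterministic and seed-sensitive", {
    pts <- gaussianPoints(seed = 10)
    r1 <- parallelismTest(pts, scope = "combined", nPerm = 99, seed = 5)
    r2 <- parallelismTest(pts, scope = "combined", nPerm = 99, seed = 5)
    expect_identical(pValues(r1), pValues(r2))
    expect_identical(nullSums(r1), nullSums(r2))
    r3 <- parallelismTest(pts, scope = "combined", nPerm = 999, seed = 6)
    ## different seed: p differs at most by permutation noise
    expect_lt(abs(pValues(r3)["angle"] - pValues(r1)["angle"]), 0.2)
    expect_error(parallelismTest(pts, nPerm = 9), "seed is required")
})

test_that("observed sums are invariant to ordering and rigid translation", {
    pts <- gaussianPoints(seed = 12)
    r <- parallelismTest(pts, scope = "combined", nPerm = 49, seed = 1)
    o <- sample(nrow(pts))
    rPerm <- parallelismTest(pts[o, ], scope = "combined", nPerm = 49,
                             seed = 1)
    expect_equal(observedSums(rPerm), observedSums(r))
    shifted <- pts
    shifted$sensitivity_index <- shifted$sensitivity_index + 50
    shifted$cyp_rel <- shifted$cyp_rel - 0.2
    rShift <- parallelismTest(shifted, scope = "combined", nPerm = 49,
                              seed = 1)
    expect_equal(observedSums(rShift), observedSums(r))
})

test_that("p-values respect the add-one floor", {
    sim <- generateCounts(simulationPreset("parallel_strong"), seed = 2)
    r <- parallelismTest(opsinProfiles(sim$experiment), nPerm = 99, seed = 3)
    expect_gte(min(pValues(r)), 1 / 100)
    expect_lte(max(pValues(r)), 1)
})

test_that("permutation p converges to the exhaustive enumeration value", {
    ## 3 species x 2 individuals per environment: the full null space is
    ## 120 x 120 ordered distinct triples, small enough to enumerate
    set.seed(99)
    df <- expand.grid(ind = 1:2, species = c("a", "b", "c"),
                      environment = c("great_lake", "crater_lake"),
                      stringsAsFactors = FALSE)
    df$sensitivity_index <- rnorm(nrow(df), 500, 10)
    df$cyp_rel <- runif(nrow(df))

    ## oracle: scale axes, then enumerate every draw of one individual
    ## per pseudo-species per environment
    pop <- paste(df$species, df$environment)
    sx <- sd(tapply(df$sensitivity_index, pop, mean))
    sy <- sd(tapply(df$cyp_rel, pop, mean))
    pts <- data.frame(species = df$species, environment = df$environment,
                      x = df$sensitivity_index / sx, y = df$cyp_rel / sy)
    A <- pts[pts$environment == "great_lake", ]
    B <- pts[pts$environment == "crater_lake", ]
    statOf <- function(dx, dy) {
        th <- atan2(dy, dx)
        pr <- combn(3, 2)
        d <- abs(th[pr[1, ]] - th[pr[2, ]])
        d <- pmin(d, 2 * pi - d) * 180 / pi
        len <- sqrt(dx^2 + dy^2)
        c(sum(d), sum(abs(len[pr[1, ]] - len[pr[2, ]])))
    }
    obs <- statOf(tapply(B$x, B$species, mean) - tapply(A$x, A$species, mean),
                  tapply(B$y, B$species, mean) - tapply(A$y, A$species, mean))
    triples <- NULL
    for (i in 1:6) for (j in setdiff(1:6, i))
        for (k in setdiff(1:6, c(i, j)))
            triples <- rbind(triples, c(i, j, k))
    nullStats <- matrix(NA_real_, nrow(triples)^2, 2)
    row <- 0
    for (ia in seq_len(nrow(triples))) for (ib in seq_len(nrow(triples))) {
        a <- triples[ia, ]; b <- triples[ib, ]
        row <- row + 1
        nullStats[row, ] <- statOf(B$x[b] - A$x[a], B$y[b] - A$y[a])
    }
    pEnum <- (colSums(sweep(nullStats, 2, obs, "<")) + 1) /
        (nrow(nullStats) + 1)

    r <- parallelismTest(df, scope = "colonization_2", nPerm = 4999,
                         seed = 7)
    expect_equal(unname(observedSums(r)), obs, tolerance = 1e-9)
    mcSd <- 3 * sqrt(pEnum * (1 - pEnum) / 5000)
    expect_lt(abs(pValues(r)["angle"] - pEnum[1]), mcSd[1] + 0.005)
    expect_lt(abs(pValues(r)["length"] - pEnum[2]), mcSd[2] + 0.005)
})

test_that("strong parallel data is detected, exchangeable data is not", {
    sim <- generateCounts(simulationPreset("parallel_strong"), seed = 14)
    rs <- parallelismTest(opsinProfiles(sim$experiment), nPerm = 199,
                          seed = 15)
    expect_lt(pValues(rs)["angle"], 0.05)

    simNull <- generateCounts(simulationPreset("null"), seed = 16)
    rn <- parallelismTest(opsinProfiles(simNull$experiment), nPerm = 199,
                          seed = 17)
    expect_gt(pValues(rn)["angle"], 0.05)
})
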