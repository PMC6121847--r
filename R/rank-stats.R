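#' Scheirer-Ray-Hare two-factor rank test
#'
#' Non-parametric analogue of two-way ANOVA. All observations are replaced
#' by mid-ranks over the full dataset; sums of squares for the two factors
#' and their interaction are computed on the ranks; each term's statistic
#' is `H = SS_term / MS_total` with `MS_total = SS_total / (N - 1)`
#' computed from the realized (tied) ranks, which absorbs the tie
#' correction. P-values are chi-square upper tails with `df = a - 1`,
#' `b - 1` and `(a - 1)(b - 1)`.
#'
#' Sums of squares are sequential (factor A, then B, then A:B), which
#' coincides with the classical construction for balanced designs; for
#' mildly unbalanced designs (e.g. one small population) the decomposition
#' is order-dependent in the usual ANOVA sense.
#'
#' @param values Numeric response.
#' @param factorA,factorB Factors (coerced); each needs at least two
#'   levels.
#' @return data.frame with one row per term (`factorA`, `factorB`,
#'   `interaction`): H, df, p.
#' @export
#' @examples
#' set.seed(1)
#' scheirerRayHare(rnorm(24), gl(2, 12), gl(3, 4, 24))
scheirerRayHare <- function(values, factorA, factorB) {
    keep <- complete.cases(values, factorA, factorB)
    values <- values[keep]
    a <- droplevels(as.factor(factorA[keep]))
    b <- droplevels(as.factor(factorB[keep]))
    if (nlevels(a) < 2 || nlevels(b) < 2)
        stop("each factor needs >= 2 levels; for one factor use ",
             "kruskalWallis()")
    r <- rank(values)
    n <- length(r)
    ## only the sums of squares are used, so the F-test reliability
    ## warning on degenerate (constant-rank) data is irrelevant
    fit <- suppressWarnings(anova(lm(r ~ a * b)))
    ss <- fit[["Sum Sq"]][1:3]
    df <- fit[["Df"]][1:3]
    mstot <- sum((r - mean(r))^2) / (n - 1)
    H <- if (mstot == 0) rep(0, 3) else ss / mstot
    data.frame(term = c("factorA", "factorB", "interaction"),
               H = H, df = df,
               p = pchisq(H, df, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper over [stats::kruskal.test()] (mid-rank tie correction,
#' chi-square reference with `df = k - 1`) returning a plain row.
#'
#' @param values Numeric response.
#' @param groups Group labels; at least two non-empty groups.
#' @return data.frame with H, df, p.
#' @export
kruskalWallis <- function(values, groups) {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2) stop("need >= 2 groups")
    kt <- kruskal.test(values, groups)
    data.frame(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`); adjusted values are monotone
#' in the input and capped at 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bhFdr <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Per-species Kruskal-Wallis tests with FDR correction
#'
#' Tests one expression measure for environment effects separately within
#' each species, then corrects the species-level p-values as one
#' family per measure (the default; `family = "global"` corrects all
#' supplied measures together).
#'
#' @param profiles data.frame from [opsinProfiles()].
#' @param measures Columns of `profiles` to test.
#' @param family FDR family: `"per-measure"` (default) or `"global"`.
#' @return data.frame with measure, species, H, df, p, q. Samples with an
#'   undefined (NA) measure value are dropped for that measure only.
#' @export
perSpeciesTests <- function(profiles,
                            measures = c("single_cone", "rh2a_ratio",
                                         "lws_fraction", "cyp_per_million"),
                            family = c("per-measure", "global")) {
    family <- match.arg(family)
    rows <- list()
    for (m in measures) {
        for (sp in unique(profiles$species)) {
            sub <- profiles[profiles$species == sp & !is.na(profiles[[m]]), ]
            if (length(unique(droplevels(sub$environment))) < 2) next
            kw <- kruskalWallis(sub[[m]], sub$environment)
            rows[[length(rows) + 1L]] <-
                cbind(data.frame(measure = m, species = sp), kw)
        }
    }
    out <- do.call(rbind, rows)
    if (family == "per-measure") {
        out$q <- NA_real_
        for (m in unique(out$measure)) {
            i <- out$measure == m
            out$q[i] <- bhFdr(out$p[i])
        }
    } else {
        out$q <- bhFdr(out$p)
    }
    out
}

## all permutations of 1..n (lexicographic); n is tiny (<= 8)
permutationsOf <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

#' Exact Spearman rank-maintenance test
#'
#' Tests whether among-species differences in a trait are maintained
#' across two environments: Spearman's rho between per-species means in
#' the two environments, with an exact permutation p-value obtained by
#' enumerating all `n!` rank orderings when `n <= 8` (large-sample
#' approximation via [stats::cor.test()] otherwise). One-sided by default,
#' since the hypothesis is maintenance (positive association).
#'
#' @param meansEnv1,meansEnv2 Named numeric vectors of species means in
#'   the two environments; names must be the same species set, n >= 3.
#' @param alternative `"greater"` (maintenance, default) or
#'   `"two.sided"`.
#' @return data.frame with rho, p, n, method.
#' @export
#' @examples
#' x <- setNames(1:7, letters[1:7])
#' rankMaintenance(x, x * 2)  # rho = 1, p = 1/5040
rankMaintenance <- function(meansEnv1, meansEnv2,
                            alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    if (!setequal(names(meansEnv1), names(meansEnv2)))
        stop("species sets differ between environments")
    meansEnv2 <- meansEnv2[names(meansEnv1)]
    n <- length(meansEnv1)
    if (n < 3) stop("need at least 3 species")
    rho <- cor(meansEnv1, meansEnv2, method = "spearman")
    if (n <= 8) {
        r1 <- rank(meansEnv1)
        r2 <- rank(meansEnv2)
        perms <- permutationsOf(n)
        rhos <- apply(perms, 1, function(idx) cor(r1, r2[idx]))
        eps <- 1e-12
        p <- if (alternative == "greater")
            mean(rhos >= rho - eps)
        else
            mean(abs(rhos) >= abs(rho) - eps)
        method <- "exact enumeration"
    } else {
        ct <- cor.test(meansEnv1, meansEnv2, method = "spearman",
                       alternative = alternative, exact = FALSE)
        p <- ct$p.value
        method <- "asymptotic"
    }
    data.frame(rho = rho, p = p, n = n, method = method)
}
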