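## Shared fixtures, built in code at test time.

opsins <- opsinNames()

## a small valid count table data.frame
makeCountDf <- function(n = 2) {
    cts <- matrix(10L + seq_len(n * 7), n, 7,
                  dimnames = list(NULL, opsins))
    data.frame(sample_id = paste0("s", seq_len(n)), cts,
               cyp27c1 = rep(5L, n), total_reads = rep(1000L, n),
               check.names = FALSE)
}

writeTmpTsv <- function(df, name = "tbl.tsv") {
    path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                      name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

## individual phenotype table with iid Gaussian axes (no structure)
gaussianPoints <- function(nSpecies = 7, nPerPop = 5,
                           envs = environmentLevels(), seed = 1) {
    set.seed(seed)
    df <- expand.grid(ind = seq_len(nPerPop),
                      species = paste0("sp", seq_len(nSpecies)),
                      environment = envs, stringsAsFactors = FALSE)
    df$sample_id <- seq_len(nrow(df))
    df$sensitivity_index <- rnorm(nrow(df), 500, 5)
    df$cyp_rel <- rnorm(nrow(df), 0.5, 0.1)
    df
}

## named pe vector with all mass on one opsin
purePe <- function(op) {
    pe <- setNames(numeric(7), opsins)
    pe[op] <- 1
    pe
}

## a pileup matrix from explicit per-site counts
siteCounts <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("A", "C", "G", "T")
    m
}
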