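## Consensus calling of opsin coding sequences from site-level base counts,
## translation with IUPAC heterozygote codes, and detection of amino-acid
## sites variable within species.

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
IUPAC2REV <- setNames(names(IUPAC2), IUPAC2)
BASES <- c("A", "C", "G", "T")

#' Read a pileup table
#'
#' TSV with columns `gene`, `position` (1-based in the CDS), and base
#' counts `A`, `C`, `G`, `T`. Positions must be contiguous from 1 within
#' each gene (indel-free pileup against the reference CDS).
#'
#' @param path Path to the TSV.
#' @return data.frame split-ready by gene.
#' @export
readPileup <- function(path) {
    df <- readTsv(path)
    need <- c("gene", "position", BASES)
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("pileup missing column(s): ", paste(missing, collapse = ", "))
    if (any(df[, BASES] < 0)) stop("negative base count")
    for (g in unique(df$gene)) {
        pos <- sort(df$position[df$gene == g])
        if (!identical(as.integer(pos), seq_len(length(pos))))
            stop("pileup positions for gene '", g,
                 "' are not contiguous from 1")
    }
    df
}

#' Call a consensus sequence from per-site base counts
#'
#' Per site: coverage below `minCoverage` masks the site to `N`; otherwise
#' if the minor (second most frequent) allele's frequency exceeds
#' `noiseThreshold` the site is scored as a heterozygote with the IUPAC
#' two-base code of the top two bases; otherwise the majority base is
#' called. A tie among three or more bases for the major allele gives `N`
#' with a warning (only diploid two-allele heterozygotes are scored).
#' Calls depend only on base frequencies, so scaling all counts at a site
#' (above the coverage floor) leaves the call unchanged.
#'
#' @param counts Matrix of base counts: sites in rows, columns `A`, `C`,
#'   `G`, `T` (or a data.frame as from [readPileup()] for a single gene,
#'   ordered by position).
#' @param minCoverage Minimum reads per site to call (default 10).
#' @param noiseThreshold Minor-allele frequency above which a site is
#'   scored as heterozygous (default 0.35).
#' @return Character scalar: consensus sequence over A, C, G, T, N and
#'   two-base IUPAC codes.
#' @export
#' @examples
#' m <- rbind(c(A = 60, C = 0, G = 40, T = 0),
#'            c(A = 70, C = 0, G = 30, T = 0),
#'            c(A = 9,  C = 0, G = 0,  T = 0))
#' callConsensus(m)  # "RAN"
callConsensus <- function(counts, minCoverage = 10, noiseThreshold = 0.35) {
    if (is.data.frame(counts)) {
        counts <- as.matrix(counts[order(counts$position), BASES])
    }
    counts <- counts[, BASES, drop = FALSE]
    out <- character(nrow(counts))
    cov <- rowSums(counts)
    for (i in seq_len(nrow(counts))) {
        if (cov[i] < minCoverage) { out[i] <- "N"; next }
        cc <- counts[i, ]
        ord <- order(cc, decreasing = TRUE)
        top <- cc[ord[1]]
        if (sum(cc == top) >= 3) {
            warning("three-way tie for major allele at site ", i,
                    "; called N")
            out[i] <- "N"
            next
        }
        minorFreq <- cc[ord[2]] / cov[i]
        if (minorFreq > noiseThreshold) {
            pair <- paste(sort(BASES[ord[1:2]]), collapse = "")
            out[i] <- IUPAC2[[pair]]
        } else {
            out[i] <- BASES[ord[1]]
        }
    }
    paste(out, collapse = "")
}

## resolve one nucleotide symbol to its constituent bases
resolveBase <- function(b) {
    if (b %in% BASES) return(b)
    if (b %in% names(IUPAC2REV)) return(strsplit(IUPAC2REV[[b]], "")[[1]])
    "N"
}

#' Translate a consensus CDS with ambiguity expansion
#'
#' Standard genetic code. Codons containing IUPAC two-base codes are
#' expanded into all resolved codons (up to two amino acids per site for
#' a single heterozygous position; phase across multiple ambiguous
#' positions in one codon is unknown, so all combinations are reported).
#' Codons containing `N` translate to `X`. Internal stops are kept as
#' `*` and flagged; translation continues.
#'
#' @param cds Character scalar; length must be divisible by 3.
#' @return List with `states` (per-codon character vectors of amino-acid
#'   states, sorted unique), `protein` (single-state sites as is,
#'   multi-state sites collapsed with `/`), and `internalStop` (logical).
#' @export
#' @examples
#' translateCds("ATGGCT")$protein  # "MA"
#' translateCds("ATR")$states      # I and M
translateCds <- function(cds) {
    chars <- strsplit(toupper(cds), "")[[1]]
    if (length(chars) %% 3 != 0)
        stop("CDS length not divisible by 3")
    ncod <- length(chars) / 3
    states <- vector("list", ncod)
    for (i in seq_len(ncod)) {
        cod <- chars[(3 * i - 2):(3 * i)]
        if (any(cod == "N") ||
            any(!cod %in% c(BASES, names(IUPAC2REV)))) {
            states[[i]] <- "X"
            next
        }
        combos <- expand.grid(resolveBase(cod[1]), resolveBase(cod[2]),
                              resolveBase(cod[3]),
                              stringsAsFactors = FALSE)
        aa <- unique(GENETIC_CODE[apply(combos, 1, paste, collapse = "")])
        states[[i]] <- sort(aa)
    }
    protein <- vapply(states, paste, "", collapse = "/")
    nstop <- vapply(states, function(s) "*" %in% s, logical(1))
    internalStop <- any(nstop[-length(nstop)])
    if (internalStop) warning("internal stop codon in translation")
    list(states = states, protein = paste(protein, collapse = ""),
         internalStop = internalStop)
}

#' Map CDS codon positions to bovine RH1 residue numbering
#'
#' Opsin residues are conventionally reported by alignment to bovine
#' rhodopsin. The map is a user-supplied alignment table (one per gene)
#' with columns `codon_index`, `rh1_position`. Positions absent from the
#' map return the raw codon index, flagged unmapped.
#'
#' @param codonIndex Integer vector of 1-based codon positions.
#' @param offsetMap data.frame with columns `codon_index`, `rh1_position`,
#'   or a path to such a TSV.
#' @return data.frame with codon_index, rh1_position, mapped (logical).
#' @export
mapToBovineRh1 <- function(codonIndex, offsetMap) {
    if (is.character(offsetMap)) offsetMap <- readTsv(offsetMap)
    if (!all(c("codon_index", "rh1_position") %in% names(offsetMap)))
        stop("offset map needs columns 'codon_index', 'rh1_position'")
    if (anyDuplicated(offsetMap$codon_index))
        stop("offset map has duplicate codon_index entries")
    i <- match(codonIndex, offsetMap$codon_index)
    data.frame(codon_index = codonIndex,
               rh1_position = ifelse(is.na(i), codonIndex,
                                     offsetMap$rh1_position[i]),
               mapped = !is.na(i))
}

#' Amino-acid sites variable within species
#'
#' Given translated consensus sequences for individuals (with species and
#' population labels), reports every codon position at which conspecific
#' individuals — pooled across populations — carry two or more amino-acid
#' states. Heterozygous individuals contribute both of their states.
#' Sites where every state is `X` are skipped. Reported variable sites
#' are necessarily a subset of sites whose nucleotide consensus differs
#' or carries ambiguity codes.
#'
#' @param translations Named list: one element per individual, each the
#'   `states` list from [translateCds()] (all same length).
#' @param species,population Character vectors aligned with
#'   `translations`.
#' @param gene Gene label recorded in the report.
#' @param offsetMap Optional RH1 alignment table for [mapToBovineRh1()].
#' @return data.frame with one row per (species, variable site): gene,
#'   species, codon_index, rh1_position (if a map is given), states
#'   (collapsed with `/`), and per-population state summaries.
#' @export
variableSitesWithinSpecies <- function(translations, species, population,
                                       gene = NA_character_,
                                       offsetMap = NULL) {
    L <- unique(lengths(translations))
    if (length(L) != 1)
        stop("translations differ in length")
    species <- as.character(species)
    population <- as.character(population)
    rows <- list()
    for (sp in unique(species)) {
        idx <- which(species == sp)
        if (length(idx) < 2) next
        for (pos in seq_len(L)) {
            states <- unlist(lapply(idx,
                                    function(i) translations[[i]][[pos]]))
            states <- setdiff(unique(states), "X")
            if (length(states) < 2) next
            perpop <- vapply(split(idx, population[idx]), function(ii) {
                s <- setdiff(unique(unlist(
                    lapply(ii, function(i) translations[[i]][[pos]]))), "X")
                paste(sort(s), collapse = "/")
            }, "")
            rows[[length(rows) + 1L]] <- data.frame(
                gene = gene, species = sp, codon_index = pos,
                states = paste(sort(states), collapse = "/"),
                populations = paste(names(perpop), perpop,
                                    sep = "=", collapse = "; "))
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene = character(), species = character(),
                   codon_index = integer(), states = character(),
                   populations = character())
    if (!is.null(offsetMap) && nrow(out)) {
        m <- mapToBovineRh1(out$codon_index, offsetMap)
        out$rh1_position <- m$rh1_position
        out$rh1_mapped <- m$mapped
    }
    out
}

#' Call consensus sequences for a set of individuals from a pileup table
#'
#' Convenience wrapper: splits a multi-gene, multi-individual pileup
#' (columns `individual`, `gene`, `position`, `A`, `C`, `G`, `T`) and
#' calls [callConsensus()] per individual and gene.
#'
#' @param pileup data.frame (e.g. from [readPileup()] with an
#'   `individual` column).
#' @param minCoverage,noiseThreshold Passed to [callConsensus()].
#' @return Nested list: `result[[gene]][[individual]]` consensus strings.
#' @export
consensusFromPileup <- function(pileup, minCoverage = 10,
                                noiseThreshold = 0.35) {
    if (!"individual" %in% names(pileup))
        stop("pileup needs an 'individual' column")
    out <- list()
    for (g in unique(pileup$gene)) {
        sub <- pileup[pileup$gene == g, ]
        out[[g]] <- lapply(split(sub, sub$individual), callConsensus,
                           minCoverage = minCoverage,
                           noiseThreshold = noiseThreshold)
    }
    out
}
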