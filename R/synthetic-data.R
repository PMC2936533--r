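#' @include AllClasses.R AllGenerics.R bottleneck-sim.R mating-assay.R
NULL

## Sixteen fixed, plausible chromosome lengths (bp, haploid ~12.1 Mb).
## Positions are decorative for the count-based analyses: they carry no
## linkage and no reference sequence.
.chromLengths <- c(
    I = 230000, II = 813000, III = 316000, IV = 1532000,
    V = 577000, VI = 270000, VII = 1091000, VIII = 562000,
    IX = 440000, X = 745000, XI = 667000, XII = 1078000,
    XIII = 924000, XIV = 784000, XV = 1091000, XVI = 948000)

## Default substitution spectrum: pooled observed spectrum of the sequenced
## lines -- transversion-rich with a bias toward G-C -> A-T changes.
.defaultSpectrum <- c(
    "G>A" = 5, "C>T" = 5, "G>T" = 5, "C>A" = 4,   # GC -> AT
    "A>G" = 3, "T>C" = 2, "T>G" = 1, "A>C" = 1,   # AT -> GC
    "A>T" = 1, "T>A" = 1, "G>C" = 1, "C>G" = 0)

#' Generate a synthetic per-line mutation table
#'
#' Draws per-line mutation counts from the forward bottleneck model at the
#' ground-truth parameters and decorates each mutation with a chromosome
#' (sampled proportionally to 16 fixed chromosome lengths), a 1-based
#' position, and a base change drawn from a substitution spectrum with the
#' observed bias toward A-T base pairs. Zygosity follows the design:
#' vegetative lines yield only heterozygous records (a `vegetative_spore`
#' design thins them binomially, each heterozygous mutation being present in
#' the sequenced spore with probability 1/2); the meiotic design reports the
#' homozygous survivors of the 50 intra-tetrad mating bottlenecks.
#'
#' @param truth a [SyntheticTruth-class].
#' @param design `"vegetative_spore"`, `"vegetative_diploid"` or `"meiotic"`.
#' @param nLines number of lines to simulate.
#' @param nBottlenecks bottleneck count (default 87 vegetative, 50 meiotic).
#' @param spectrum named weights over `"ref>alt"` substitution classes.
#' @return data.frame with columns `line`, `chrom`, `pos_1based`, `ref_alt`,
#'   `zygosity`, `gene_note`.
#' @examples
#' tab <- generateMutationTable(syntheticTruth(seed = 3), "meiotic", nLines = 2)
#' table(tab$zygosity)
#' @export
generateMutationTable <- function(truth,
                                  design = c("vegetative_spore",
                                             "vegetative_diploid", "meiotic"),
                                  nLines,
                                  nBottlenecks = if (design == "meiotic") 50 else 87,
                                  spectrum = .defaultSpectrum) {
    design <- match.arg(design)
    stopifnot(nLines >= 1)
    set.seed(truth@seed)
    vegetative <- design != "meiotic"
    cfg <- simConfigNew(
        m = truth@m, muMultiplier = if (vegetative) 0 else truth@muMultiplier,
        scenario = if (vegetative) "vegetative_only" else "pre_replication",
        nBottlenecks = nBottlenecks, s = truth@s, nReplicates = 1L,
        seed = truth@seed)
    prefix <- switch(design, vegetative_spore = "B", vegetative_diploid = "B",
                     meiotic = "T")
    rows <- vector("list", nLines)
    for (i in seq_len(nLines)) {
        line <- if (vegetative) simulateBLine(cfg) else simulateTLine(cfg)
        k <- if (design == "meiotic") line@nFixed
             else if (design == "vegetative_spore")
                 stats::rbinom(1L, line@nHet, 0.5)
             else line@nHet
        if (k == 0L) next
        chromIdx <- sample.int(16L, k, replace = TRUE,
                               prob = .chromLengths / sum(.chromLengths))
        rows[[i]] <- data.frame(
            line = sprintf("%d%s-%d", i, prefix, nBottlenecks),
            chrom = paste0("Chr", names(.chromLengths)[chromIdx]),
            pos_1based = vapply(chromIdx, function(ci)
                sample.int(.chromLengths[ci], 1L), integer(1L)),
            ref_alt = sample(names(spectrum), k, replace = TRUE,
                             prob = spectrum / sum(spectrum)),
            zygosity = if (design == "meiotic") "homozygous" else "heterozygous",
            gene_note = "",
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(line = character(), chrom = character(),
                          pos_1based = integer(), ref_alt = character(),
                          zygosity = character(), gene_note = character(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Generate a synthetic intra-tetrad mating assay
#'
#' Forward model of the drug-marker assay: for each sampled diploid the mating
#' mode is self with probability `true s`; an inter-spore diploid is scored as
#' a self-mater with the crossover misclassification probability `q = rf`.
#' Tetrads whose two sampled diploids disagree in scored class are tallied as
#' "multiple". [correctedFrequencies()] inverts this forward model.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nTetrads tetrads sampled.
#' @param coloniesPerTetrad diploid colonies typed per tetrad (default 2).
#' @return a [MatingAssayTable-class] with a single `"synthetic"` method row.
#' @examples
#' generateMatingAssay(syntheticTruth(s = 0.18, rf = 0), nTetrads = 200)
#' @export
generateMatingAssay <- function(truth, nTetrads, coloniesPerTetrad = 2) {
    stopifnot(nTetrads >= 1, coloniesPerTetrad >= 1)
    set.seed(truth@seed)
    q <- truth@rf
    nInter <- 0L; nSelf <- 0L; nMultiple <- 0L
    for (t in seq_len(nTetrads)) {
        isSelf <- stats::runif(coloniesPerTetrad) < truth@s
        misScored <- !isSelf & stats::runif(coloniesPerTetrad) < q
        scoredSelf <- isSelf | misScored
        nSelf <- nSelf + sum(scoredSelf)
        nInter <- nInter + sum(!scoredSelf)
        if (coloniesPerTetrad >= 2L && length(unique(scoredSelf[1:2])) > 1L)
            nMultiple <- nMultiple + 1L
    }
    matingAssayTable(
        method = "synthetic",
        tetradsGerminated = nTetrads,
        coloniesTyped = nTetrads * coloniesPerTetrad,
        nInter = nInter, nSelf = nSelf,
        nMultipleTetrads = nMultiple,
        tetradsTwoTyped = if (coloniesPerTetrad >= 2L) nTetrads else 0L)
}

#' Generate synthetic PD/TT/NPD tetrad class counts
#'
#' Single-crossover regime: a tetratype arises with probability
#' `2 * Rf = cm / 50` and NPDs are negligible at small map distances, so the
#' Perkins distance recovers `cm` in expectation. An optional `pNPD` allows
#' non-zero NPDs (the tetratype probability is then `cm/50 - 6 * pNPD` so that
#' the expectation is preserved).
#'
#' @param truth a [SyntheticTruth-class].
#' @param nTetrads number of tetrads scored.
#' @param pNPD probability of a non-parental ditype (default 0).
#' @return a [TetradClassCounts-class].
#' @examples
#' perkinsDistance(generateTetradClasses(syntheticTruth(cm = 1), 5000))
#' @export
generateTetradClasses <- function(truth, nTetrads, pNPD = 0) {
    stopifnot(nTetrads >= 1, pNPD >= 0)
    pTT <- truth@cm / 50 - 6 * pNPD
    if (pTT < 0 || pTT + pNPD > 1)
        stop("inconsistent cm/pNPD combination")
    set.seed(truth@seed)
    draw <- stats::rmultinom(1L, nTetrads, c(1 - pTT - pNPD, pTT, pNPD))
    tetradClassCounts(pd = draw[1L], tt = draw[2L], npd = draw[3L])
}
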