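#' @include AllClasses.R AllGenerics.R tetrad-genetics.R
NULL

#' Classify a diploid colony from its drug-resistance phenotype
#'
#' Diploids resistant to both G418 and nourseothricin arise from inter-spore
#' mating (the two parental spores carried different markers); diploids
#' resistant to exactly one drug arise from self-mating. Resistance to neither
#' drug is impossible for a diploid of this cross and flags an assay failure.
#' Vectorised and symmetric in the two drugs.
#'
#' @param g418Resistant logical vector.
#' @param natResistant logical vector.
#' @return character vector: `"inter_spore"`, `"self"` or `"invalid"`.
#' @examples
#' classifyDiploid(TRUE, TRUE)    # inter_spore
#' classifyDiploid(FALSE, TRUE)   # self
#' @export
classifyDiploid <- function(g418Resistant, natResistant) {
    stopifnot(is.logical(g418Resistant), is.logical(natResistant))
    nRes <- as.integer(g418Resistant) + as.integer(natResistant)
    c("invalid", "self", "inter_spore")[nRes + 1L]
}

#' Pooled mating frequencies across assay methods
#'
#' Pools colonies across all methods: the inter-spore fraction is the total
#' inter-spore-scored colonies over total colonies typed, the self fraction
#' its complement, and the multiple-mating fraction the number of tetrads
#' whose two sampled diploids disagree over the number of tetrads with two
#' typed colonies.
#'
#' @param table a [MatingAssayTable-class].
#' @return list with `fInter`, `fSelf`, `fMultiple`, `nColonies`,
#'   `nTetradsTwoTyped`, and whole-percent `percentInter`, `percentSelf`.
#' @examples
#' tab <- matingAssayTable(method = "streak", tetradsGerminated = 100,
#'                         coloniesTyped = 200, nInter = 168, nSelf = 32,
#'                         nMultipleTetrads = 14)
#' pooledFrequencies(tab)$percentInter
#' @export
pooledFrequencies <- function(table) {
    d <- assayCounts(table)
    nCol <- sum(d$coloniesTyped)
    if (nCol == 0L)
        stop("empty input: no colonies typed")
    fInter <- sum(d$nInter) / nCol
    nTwo <- sum(d$tetradsTwoTyped)
    fMultiple <- if (nTwo > 0L) sum(d$nMultipleTetrads) / nTwo else NA_real_
    list(fInter = fInter, fSelf = 1 - fInter, fMultiple = fMultiple,
         nColonies = nCol, nTetradsTwoTyped = nTwo,
         percentInter = round(100 * fInter),
         percentSelf = round(100 * (1 - fInter)))
}

#' Crossover-corrected mating frequencies
#'
#' Composes [pooledFrequencies()] with [correctMatingFrequencies()]: the
#' observed self fraction is inflated by inter-spore matings in which a single
#' crossover between the drug marker and MAT left both mated spores with the
#' same marker (probability `rf` per inter-spore mating).
#'
#' @param table a [MatingAssayTable-class].
#' @param rf per-spore recombination frequency between the markers and MAT
#'   (default 0.01, the observed 1.0 cM).
#' @return list as [correctMatingFrequencies()], plus whole-percent
#'   `percentInter`, `percentSelf` and the pooled (uncorrected) frequencies
#'   under `observed`.
#' @examples
#' tab <- matingAssayTable(method = c("streak", "microdissection"),
#'                         tetradsGerminated = c(100, 84),
#'                         coloniesTyped = c(200, 145),
#'                         nInter = c(168, 115), nSelf = c(32, 30),
#'                         nMultipleTetrads = c(14, 13))
#' correctedFrequencies(tab, rf = 0.01)$percentInter  # 83
#' @export
correctedFrequencies <- function(table, rf = 0.01) {
    obs <- pooledFrequencies(table)
    corr <- correctMatingFrequencies(obs$fInter, obs$fSelf, rf = rf)
    corr$percentInter <- round(100 * corr$fInter)
    corr$percentSelf <- round(100 * corr$fSelf)
    corr$observed <- obs
    corr
}
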