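#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a simulation configuration
#'
#' Defaults are the experimental design of the meiotic ("T") mutation
#' accumulation lines: mitotic rate m = 2.9e-10 per base per division (the
#' pooled vegetative estimate), diploid genome of 24,483,546 bp, 20 mitotic
#' divisions between bottlenecks, 50 meiotic bottlenecks, self-mating fraction
#' s = 0.17, and ensembles of 10,000 replicate lines. Vegetative ("B") lines
#' use `scenario = "vegetative_only"` with 87 bottlenecks.
#'
#' @param m mitotic base-substitution rate per base per division.
#' @param muMultiplier meiotic rate as a multiple of `m`.
#' @param genomeSize diploid genome size in bp.
#' @param divisionsPerBottleneck mitotic divisions per bottleneck.
#' @param nBottlenecks number of bottlenecks.
#' @param scenario `"pre_replication"`, `"post_replication"` or
#'   `"vegetative_only"`.
#' @param s self-mating fraction.
#' @param nReplicates ensemble size.
#' @param seed master RNG seed.
#' @param matingModel `"independent"` or `"joint"`.
#' @return a validated [SimConfig-class] object.
#' @examples
#' simConfigNew(muMultiplier = 30, nReplicates = 100)
#' @export
simConfigNew <- function(m = vegetativeRateDefault,
                         muMultiplier = 0,
                         genomeSize = yeastDiploidGenomeSize,
                         divisionsPerBottleneck = 20,
                         nBottlenecks = if (scenario == "vegetative_only") 87 else 50,
                         scenario = c("pre_replication", "post_replication",
                                      "vegetative_only"),
                         s = 0.17,
                         nReplicates = 10000,
                         seed = 1,
                         matingModel = c("independent", "joint")) {
    scenario <- match.arg(scenario)
    matingModel <- match.arg(matingModel)
    obj <- new("SimConfig",
        m = as.numeric(m),
        muMultiplier = as.numeric(muMultiplier),
        genomeSize = as.numeric(genomeSize),
        divisionsPerBottleneck = as.integer(divisionsPerBottleneck),
        nBottlenecks = as.integer(nBottlenecks),
        scenario = scenario,
        s = as.numeric(s),
        nReplicates = as.integer(nReplicates),
        seed = as.integer(seed),
        matingModel = matingModel)
    validObject(obj)
    obj
}

#' Construct tetrad class counts
#'
#' @param pd,tt,npd parental-ditype, tetratype and non-parental-ditype counts.
#' @return a [TetradClassCounts-class] object.
#' @examples
#' tetradClassCounts(pd = 95, tt = 4, npd = 1)
#' @export
tetradClassCounts <- function(pd, tt, npd = 0) {
    obj <- new("TetradClassCounts", pd = as.integer(pd), tt = as.integer(tt),
               npd = as.integer(npd))
    validObject(obj)
    obj
}

#' Construct a mating-assay table
#'
#' One entry per scoring method. `tetradsTwoTyped` defaults to
#' `coloniesTyped - tetradsGerminated`, the number of tetrads that contributed
#' two typed diploid colonies when every germinated tetrad contributed at
#' least one.
#'
#' @param method character vector of method labels.
#' @param tetradsGerminated tetrads germinated per method.
#' @param coloniesTyped diploid colonies phenotyped per method.
#' @param nInter colonies scored inter-spore (doubly drug-resistant).
#' @param nSelf colonies scored self (singly resistant).
#' @param nMultipleTetrads tetrads whose two sampled diploids disagree.
#' @param tetradsTwoTyped tetrads contributing two typed colonies.
#' @return a [MatingAssayTable-class] object.
#' @examples
#' matingAssayTable(method = c("streak", "microdissection"),
#'                  tetradsGerminated = c(100, 84),
#'                  coloniesTyped = c(200, 145),
#'                  nInter = c(168, 115), nSelf = c(32, 30),
#'                  nMultipleTetrads = c(14, 13))
#' @export
matingAssayTable <- function(method, tetradsGerminated, coloniesTyped,
                             nInter, nSelf, nMultipleTetrads = 0,
                             tetradsTwoTyped = coloniesTyped - tetradsGerminated) {
    d <- data.frame(
        method = as.character(method),
        tetradsGerminated = as.integer(tetradsGerminated),
        coloniesTyped = as.integer(coloniesTyped),
        nInter = as.integer(nInter),
        nSelf = as.integer(nSelf),
        nMultipleTetrads = as.integer(rep_len(nMultipleTetrads, length(method))),
        tetradsTwoTyped = as.integer(tetradsTwoTyped),
        stringsAsFactors = FALSE)
    obj <- new("MatingAssayTable", assay = d)
    validObject(obj)
    obj
}

#' Construct a ground-truth parameter set for the synthetic generators
#'
#' Defaults are the study's stated world: m = 2.9e-10, meiotic rate equal to
#' the mitotic rate (multiplier 1), s = 0.17, marker-MAT recombination
#' frequency 0.01 (1.0 cM over 1.5 kb).
#'
#' @param m true mitotic rate per base per division.
#' @param muMultiplier true meiotic rate as a multiple of m.
#' @param s true self-mating fraction.
#' @param rf true per-spore recombination frequency.
#' @param cm true map distance in cM; defaults to `100 * rf`.
#' @param seed RNG seed.
#' @return a [SyntheticTruth-class] object.
#' @examples
#' syntheticTruth(s = 0.17, rf = 0.01)
#' @export
syntheticTruth <- function(m = vegetativeRateDefault, muMultiplier = 1,
                           s = 0.17, rf = 0.01, cm = 100 * rf, seed = 1) {
    obj <- new("SyntheticTruth", m = as.numeric(m),
               muMultiplier = as.numeric(muMultiplier), s = as.numeric(s),
               rf = as.numeric(rf), cm = as.numeric(cm), seed = as.integer(seed))
    validObject(obj)
    obj
}
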