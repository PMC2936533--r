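#' @import methods
NULL

## Diploid nuclear genome size (bp) of the SK1-derived parent strain and the
## pooled vegetative base-substitution rate used throughout as defaults.
#' Default genome size and vegetative mutation rate
#'
#' `yeastDiploidGenomeSize` is the diploid nuclear genome size (24,483,546 bp)
#' used as the denominator of all per-base rates; `vegetativeRateDefault`
#' (2.9e-10 substitutions per base per division) is the pooled vegetative rate
#' used as the mitotic rate of the simulator.
#'
#' @name tetradMA-defaults
#' @aliases yeastDiploidGenomeSize vegetativeRateDefault
#' @export yeastDiploidGenomeSize vegetativeRateDefault
yeastDiploidGenomeSize <- 24483546
vegetativeRateDefault <- 2.9e-10

#' SimConfig: parameters of the bottleneck simulator
#'
#' Holds every parameter of the forward Monte-Carlo simulation of mutation
#' accumulation: the mitotic base-substitution rate \eqn{m} per base per
#' division, the meiotic rate expressed as a multiple of \eqn{m}, the diploid
#' genome size \eqn{G}, the bottleneck design (divisions per bottleneck and
#' number of bottlenecks), the meiotic-mutation timing scenario, the
#' self-mating fraction \eqn{s}, the replicate count and the master seed.
#'
#' @slot m mitotic base-substitution rate per base per division.
#' @slot muMultiplier meiotic rate \eqn{\mu} as a multiple of `m`.
#' @slot genomeSize diploid genome size in bp.
#' @slot divisionsPerBottleneck mitotic divisions between bottlenecks.
#' @slot nBottlenecks number of bottlenecks (50 meiotic for T lines, 87
#'   vegetative for B lines).
#' @slot scenario one of `"pre_replication"`, `"post_replication"`,
#'   `"vegetative_only"`.
#' @slot s self-mating fraction in \[0,1\].
#' @slot nReplicates ensemble size.
#' @slot seed master RNG seed.
#' @slot matingModel `"independent"` (each mutation resolved independently
#'   given the shared mating mode) or `"joint"` (explicit spore genotypes and a
#'   shared mated pair).
#'
#' @export
setClass("SimConfig",
    representation(
        m = "numeric",
        muMultiplier = "numeric",
        genomeSize = "numeric",
        divisionsPerBottleneck = "integer",
        nBottlenecks = "integer",
        scenario = "character",
        s = "numeric",
        nReplicates = "integer",
        seed = "integer",
        matingModel = "character"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@m) != 1L || is.na(object@m) || object@m < 0)
        msg <- c(msg, "m: must be a single non-negative rate")
    if (length(object@muMultiplier) != 1L || is.na(object@muMultiplier) ||
        object@muMultiplier < 0)
        msg <- c(msg, "muMultiplier: must be a single non-negative multiple")
    if (length(object@genomeSize) != 1L || is.na(object@genomeSize) ||
        object@genomeSize <= 0)
        msg <- c(msg, "genomeSize: must be a single positive bp count")
    if (length(object@divisionsPerBottleneck) != 1L ||
        is.na(object@divisionsPerBottleneck) ||
        object@divisionsPerBottleneck < 0L)
        msg <- c(msg, "divisionsPerBottleneck: must be a non-negative integer")
    if (length(object@nBottlenecks) != 1L || is.na(object@nBottlenecks) ||
        object@nBottlenecks < 1L)
        msg <- c(msg, "nBottlenecks: must be a positive integer")
    if (length(object@scenario) != 1L ||
        !object@scenario %in% c("pre_replication", "post_replication",
                                "vegetative_only"))
        msg <- c(msg, paste("scenario: must be one of pre_replication,",
                            "post_replication, vegetative_only"))
    if (length(object@s) != 1L || is.na(object@s) ||
        object@s < 0 || object@s > 1)
        msg <- c(msg, "s: self-mating fraction must lie in [0, 1]")
    if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
        object@nReplicates < 1L)
        msg <- c(msg, "nReplicates: must be a positive integer")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed: must be a single integer")
    if (length(object@matingModel) != 1L ||
        !object@matingModel %in% c("independent", "joint"))
        msg <- c(msg, "matingModel: must be 'independent' or 'joint'")
    if (length(msg)) msg else TRUE
})

#' LineState: the state of one simulated mutation-accumulation line
#'
#' Segregating heterozygous mutations are tracked as counts (the analysis is
#' count-based; positions carry no linkage). `nGenerated` and `nLost` allow the
#' conservation identity generated = fixed + heterozygous + lost to be checked
#' for every line.
#'
#' @slot nHet number of segregating heterozygous mutations.
#' @slot nFixed number of mutations fixed to homozygosity (non-decreasing).
#' @slot bottleneckIndex bottlenecks completed.
#' @slot nGenerated total mutations generated so far.
#' @slot nLost total mutations lost so far.
#'
#' @export
setClass("LineState",
    representation(
        nHet = "integer",
        nFixed = "integer",
        bottleneckIndex = "integer",
        nGenerated = "integer",
        nLost = "integer"
    )
)

setValidity("LineState", function(object) {
    msg <- character()
    for (sl in c("nHet", "nFixed", "bottleneckIndex", "nGenerated", "nLost")) {
        v <- slot(object, sl)
        if (length(v) != 1L || is.na(v) || v < 0L)
            msg <- c(msg, paste0(sl, ": must be a single non-negative integer"))
    }
    if (!length(msg) &&
        object@nGenerated != object@nHet + object@nFixed + object@nLost)
        msg <- c(msg, "conservation violated: generated != het + fixed + lost")
    if (length(msg)) msg else TRUE
})

#' EnsembleResult: replicate-level outcome of an ensemble simulation
#'
#' @slot finalHom integer vector of final homozygous counts, one per replicate.
#' @slot finalHet integer vector of final heterozygous counts.
#' @slot nGenerated integer vector of total mutations generated per replicate.
#' @slot nLost integer vector of mutations lost per replicate.
#' @slot config the [SimConfig-class] that produced the ensemble.
#'
#' @export
setClass("EnsembleResult",
    representation(
        finalHom = "integer",
        finalHet = "integer",
        nGenerated = "integer",
        nLost = "integer",
        config = "SimConfig"
    )
)

setValidity("EnsembleResult", function(object) {
    n <- object@config@nReplicates
    msg <- character()
    if (length(object@finalHom) != n || length(object@finalHet) != n ||
        length(object@nGenerated) != n || length(object@nLost) != n)
        msg <- c(msg, "all per-replicate vectors must have length nReplicates")
    if (any(object@finalHom < 0L) || any(object@finalHet < 0L) ||
        any(object@nLost < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (!length(msg) &&
        any(object@nGenerated !=
            object@finalHom + object@finalHet + object@nLost))
        msg <- c(msg, "conservation violated in at least one replicate")
    if (length(msg)) msg else TRUE
})

#' TetradClassCounts: PD / TT / NPD tetrad class counts for two markers
#'
#' @slot pd parental ditype count.
#' @slot tt tetratype count.
#' @slot npd non-parental ditype count.
#'
#' @export
setClass("TetradClassCounts",
    representation(pd = "integer", tt = "integer", npd = "integer")
)

setValidity("TetradClassCounts", function(object) {
    counts <- c(object@pd, object@tt, object@npd)
    if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0L))
        return("pd, tt, npd must each be a single non-negative count")
    TRUE
})

#' MatingAssayTable: per-method tallies of an intra-tetrad mating assay
#'
#' One row per scoring method. Diploids doubly drug-resistant are scored as
#' inter-spore maters; singly resistant diploids as self-maters. A "multiple"
#' tetrad is one whose two sampled diploids disagree in scored class.
#'
#' @slot assay data.frame with columns `method`, `tetradsGerminated`,
#'   `coloniesTyped`, `nInter`, `nSelf`, `nMultipleTetrads`,
#'   `tetradsTwoTyped`.
#'
#' @export
setClass("MatingAssayTable", representation(assay = "data.frame"))

setValidity("MatingAssayTable", function(object) {
    d <- object@assay
    need <- c("method", "tetradsGerminated", "coloniesTyped", "nInter",
              "nSelf", "nMultipleTetrads", "tetradsTwoTyped")
    if (!all(need %in% names(d)))
        return(paste("assay must have columns:", paste(need, collapse = ", ")))
    if (nrow(d) < 1L)
        return("assay must have at least one method row")
    num <- d[setdiff(need, "method")]
    if (any(vapply(num, function(x) any(is.na(x) | x < 0), logical(1L))))
        return("all counts must be non-negative")
    if (any(d$nInter + d$nSelf != d$coloniesTyped))
        return("nInter + nSelf must equal coloniesTyped in every row")
    if (any(d$nMultipleTetrads > d$tetradsTwoTyped))
        return("nMultipleTetrads cannot exceed tetradsTwoTyped")
    TRUE
})

#' RateEstimate: a per-base per-division mutation-rate estimate
#'
#' rate = correctionFactor * k / (genomeSize * generations). The correction
#' factor is 2 when only one haploid spore clone was sequenced (half of the
#' diploid genome observed) or when meiotic-line homozygous counts are doubled
#' to recover mutations purged during intra-tetrad mating, and 1 for diploid
#' sequencing.
#'
#' @slot rate substitutions per base per cell division.
#' @slot k observed mutation count.
#' @slot correctionFactor 1 or 2.
#' @slot genomeSize diploid genome size in bp.
#' @slot generations total cell divisions (including meioses where relevant).
#'
#' @export
setClass("RateEstimate",
    representation(
        rate = "numeric",
        k = "integer",
        correctionFactor = "numeric",
        genomeSize = "numeric",
        generations = "numeric"
    )
)

setValidity("RateEstimate", function(object) {
    msg <- character()
    if (object@k < 0L) msg <- c(msg, "k must be non-negative")
    if (!object@correctionFactor %in% c(1, 2))
        msg <- c(msg, "correctionFactor must be 1 or 2")
    if (object@genomeSize <= 0 || object@generations <= 0)
        msg <- c(msg, "genomeSize and generations must be positive")
    expected <- object@correctionFactor * object@k /
        (object@genomeSize * object@generations)
    if (!length(msg) && abs(object@rate - expected) > 1e-15 * max(1, expected))
        msg <- c(msg, "rate inconsistent with correctionFactor*k/(G*g)")
    if (length(msg)) msg else TRUE
})

#' UpperLimitScan: empirical P-values over a grid of meiotic-rate multipliers
#'
#' @slot multipliers ordered grid of meiotic-rate multipliers (multiples of m).
#' @slot pValues lower-tail empirical P-values, one per multiplier.
#' @slot alpha significance threshold.
#' @slot observedHom observed homozygous count used as the comparison value.
#' @slot scenario meiotic-mutation timing scenario scanned.
#' @slot smallestInconsistent smallest multiplier with P < alpha (NA if none).
#' @slot largestConsistent largest multiplier with P >= alpha (NA if none).
#' @slot muMax rate upper limit, largestConsistent * m.
#'
#' @export
setClass("UpperLimitScan",
    representation(
        multipliers = "numeric",
        pValues = "numeric",
        alpha = "numeric",
        observedHom = "numeric",
        scenario = "character",
        smallestInconsistent = "numeric",
        largestConsistent = "numeric",
        muMax = "numeric"
    )
)

setValidity("UpperLimitScan", function(object) {
    msg <- character()
    if (length(object@multipliers) != length(object@pValues))
        msg <- c(msg, "multipliers and pValues must have equal length")
    if (length(object@multipliers) < 1L)
        msg <- c(msg, "scan grid must be non-empty")
    if (any(object@pValues < 0 | object@pValues > 1))
        msg <- c(msg, "pValues must lie in [0, 1]")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (is.unsorted(object@multipliers, strictly = TRUE))
        msg <- c(msg, "multipliers must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground-truth parameters for the synthetic-data generators
#'
#' @slot m true mitotic base-substitution rate per base per division.
#' @slot muMultiplier true meiotic rate as a multiple of m.
#' @slot s true self-mating fraction.
#' @slot rf true per-spore recombination frequency between marker and MAT.
#' @slot cm true genetic map distance in cM (100 * rf in the single-crossover
#'   regime).
#' @slot seed RNG seed; generators are deterministic given (truth, seed).
#'
#' @export
setClass("SyntheticTruth",
    representation(
        m = "numeric",
        muMultiplier = "numeric",
        s = "numeric",
        rf = "numeric",
        cm = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (object@m < 0 || object@muMultiplier < 0)
        msg <- c(msg, "rates must be non-negative")
    if (object@s < 0 || object@s > 1)
        msg <- c(msg, "s must lie in [0, 1]")
    if (object@rf < 0 || object@rf >= 0.5)
        msg <- c(msg, "rf must lie in [0, 0.5)")
    if (object@cm < 0)
        msg <- c(msg, "cm must be non-negative")
    if (length(msg)) msg else TRUE
})
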