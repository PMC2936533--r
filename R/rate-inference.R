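#' @include AllClasses.R AllGenerics.R bottleneck-sim.R
NULL

.rateEstimate <- function(k, G, g, correction) {
    if (length(k) != 1L || is.na(k) || k < 0)
        stop("'k' must be a single non-negative count")
    if (G <= 0 || g <= 0)
        stop("'G' and 'g' must be positive")
    obj <- new("RateEstimate", rate = correction * k / (G * g),
               k = as.integer(k), correctionFactor = correction,
               genomeSize = as.numeric(G), generations = as.numeric(g))
    validObject(obj)
    obj
}

#' Vegetative rate from a single sequenced spore clone
#'
#' When one haploid spore clone of a vegetative line is sequenced, only half
#' of the diploid genome is observed (every mutation is heterozygous), so the
#' detected count is doubled: rate = 2k / (G g).
#'
#' @param k base substitutions detected in the spore clone.
#' @param G diploid genome size in bp.
#' @param g vegetative generations.
#' @param coverage optional callable fraction of the genome; the default 1
#'   reproduces the reported rates, set 0.96 for the coverage-adjusted
#'   variant.
#' @return a [RateEstimate-class].
#' @examples
#' vegetativeRateFromSpore(8, g = 1740)  # ~3.8e-10
#' @export
vegetativeRateFromSpore <- function(k, G = yeastDiploidGenomeSize, g,
                                    coverage = 1) {
    .rateEstimate(k, G * coverage, g, correction = 2)
}

#' Vegetative rate from diploid sequencing
#'
#' Diploid sequencing observes the whole genome; rate = k / (G g).
#'
#' @inheritParams vegetativeRateFromSpore
#' @return a [RateEstimate-class].
#' @examples
#' vegetativeRateFromDiploid(5, g = 1040)  # ~2.0e-10
#' @export
vegetativeRateFromDiploid <- function(k, G = yeastDiploidGenomeSize, g,
                                      coverage = 1) {
    .rateEstimate(k, G * coverage, g, correction = 1)
}

#' Meiotic-line rate from homozygous counts
#'
#' All mutations surviving the meiotic bottlenecks are homozygous, but half of
#' the substitutions accumulated in the vegetative phases were purged during
#' intra-tetrad mating, so the homozygous count is doubled:
#' rate = 2 k / (G g_total), with g_total the vegetative divisions plus
#' meioses (default 1000 + 50).
#'
#' @param kHom homozygous base substitutions in the final bottleneck.
#' @param G diploid genome size in bp.
#' @param gTotal total divisions including meioses.
#' @param coverage optional callable fraction, as in
#'   [vegetativeRateFromSpore()].
#' @return a [RateEstimate-class].
#' @examples
#' meioticLineRate(5)  # ~3.9e-10
#' @export
meioticLineRate <- function(kHom, G = yeastDiploidGenomeSize, gTotal = 1050,
                            coverage = 1) {
    .rateEstimate(kHom, G * coverage, gTotal, correction = 2)
}

#' Average of several rate estimates
#'
#' By default the arithmetic mean of the full-precision member rates. Setting
#' `sigfigs` rounds each member to that many significant figures before
#' averaging; `sigfigs = 2` reproduces the reported arithmetic, in which the
#' average of the displayed two-significant-figure rates is itself displayed
#' to two significant figures ((3.8 + 2.8 + 2.0)/3 = 2.87 -> 2.9e-10).
#'
#' @param estimates list of [RateEstimate-class] objects.
#' @param sigfigs optional significant figures applied to members first.
#' @return arithmetic mean rate (numeric).
#' @examples
#' ests <- list(vegetativeRateFromSpore(8, g = 1740),
#'              vegetativeRateFromSpore(6, g = 1740),
#'              vegetativeRateFromDiploid(5, g = 1040))
#' averageRate(ests)              # 2.845e-10
#' averageRate(ests, sigfigs = 2) # 2.867e-10, i.e. 2.9e-10 to 2 s.f.
#' @export
averageRate <- function(estimates, sigfigs = NULL) {
    if (length(estimates) == 0L)
        stop("empty input: need at least one rate estimate")
    rates <- vapply(estimates, mutationRate, numeric(1L))
    if (!is.null(sigfigs))
        rates <- signif(rates, sigfigs)
    mean(rates)
}

#' Upper bound on the in-del rate per homopolymeric tract
#'
#' With zero 1-2 nt in-dels observed across all homopolymeric tracts of the
#' diploid genome over `g` generations, the rate per tract per division is
#' bounded by fewer than one event in total: bound = 1 / (nTracts * g).
#'
#' @param nTracts number of homopolymeric tracts (154,850 in the diploid
#'   genome).
#' @param g generations of the line.
#' @return the rate bound (numeric).
#' @examples
#' indelRateBound(154850, 1740)  # < 3.7e-9
#' @export
indelRateBound <- function(nTracts = 154850, g) {
    if (nTracts <= 0 || g <= 0)
        stop("'nTracts' and 'g' must be positive")
    1 / (nTracts * g)
}

#' Empirical lower-tail P-value of an ensemble
#'
#' The fraction of simulated replicates whose final homozygous count is less
#' than or equal to the observed count (inclusive comparison).
#'
#' @param ensemble an [EnsembleResult-class].
#' @param observedHom observed homozygous count.
#' @return probability in \[0, 1\].
#' @export
ensemblePValue <- function(ensemble, observedHom) {
    hom <- finalHom(ensemble)
    if (length(hom) == 0L)
        stop("empty ensemble")
    mean(hom <= observedHom)
}

#' Scan meiotic-rate multipliers for the largest value consistent with the data
#'
#' For each multiplier in the grid, simulates an ensemble with the meiotic
#' rate set to that multiple of the mitotic rate and computes the lower-tail
#' empirical P-value against the observed homozygous count. A multiplier is
#' inconsistent when P < alpha. The coarse grid (default 0 to 100 in steps of
#' 5) is refined in steps of 1 around the alpha crossing. Each grid point uses
#' a seed derived deterministically from `base@seed`, so scans are
#' reproducible.
#'
#' @param base a [SimConfig-class]; its `muMultiplier` is overridden per grid
#'   point.
#' @param multipliers ascending grid of multipliers.
#' @param observedHom observed homozygous count (default 5, the mean of the
#'   two sequenced meiotic lines).
#' @param alpha significance threshold (default 0.05).
#' @param refine refine to step 1 around the crossing (default TRUE).
#' @return an [UpperLimitScan-class].
#' @export
scanUpperLimit <- function(base, multipliers = seq(0, 100, by = 5),
                           observedHom = 5, alpha = 0.05, refine = TRUE) {
    if (length(multipliers) == 0L)
        stop("empty input: multiplier grid must be non-empty")
    if (is.unsorted(multipliers, strictly = TRUE))
        stop("'multipliers' must be strictly increasing")
    if (base@scenario == "vegetative_only")
        stop("scan requires a meiotic scenario")

    evalGrid <- function(ms) {
        vapply(ms, function(mult) {
            cfg <- base
            cfg@muMultiplier <- as.numeric(mult)
            # derived per-point seed keeps points independent yet reproducible
            cfg@seed <- as.integer((base@seed + round(1000 * mult)) %%
                                   .Machine$integer.max)
            ensemblePValue(simulateEnsemble(cfg), observedHom)
        }, numeric(1L))
    }

    pv <- evalGrid(multipliers)
    if (refine) {
        bad <- which(pv < alpha)
        if (length(bad) && bad[1L] > 1L) {
            lo <- multipliers[bad[1L] - 1L]
            hi <- multipliers[bad[1L]]
            extra <- setdiff(seq(lo, hi, by = 1), multipliers)
            if (length(extra)) {
                pvExtra <- evalGrid(extra)
                ord <- order(c(multipliers, extra))
                multipliers <- c(multipliers, extra)[ord]
                pv <- c(pv, pvExtra)[ord]
            }
        }
    }

    inconsistent <- multipliers[pv < alpha]
    consistent <- multipliers[pv >= alpha]
    smallestInconsistent <- if (length(inconsistent)) min(inconsistent)
        else NA_real_
    largestConsistent <- if (length(consistent)) max(consistent) else NA_real_
    obj <- new("UpperLimitScan", multipliers = as.numeric(multipliers),
               pValues = pv, alpha = alpha,
               observedHom = as.numeric(observedHom),
               scenario = base@scenario,
               smallestInconsistent = smallestInconsistent,
               largestConsistent = largestConsistent,
               muMax = largestConsistent * base@m)
    validObject(obj)
    obj
}
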