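#' @include AllClasses.R AllGenerics.R
NULL

#' Exact outcome distribution of one intra-tetrad mating
#'
#' Enumerates every equally likely configuration of a tetrad carrying a
#' mutation on `carriers` of its four spores, together with every legal mating
#' of the given mode, and returns the exact probability that the resulting
#' diploid is mutant homozygous (`fixed`), heterozygous, or wild-type
#' (`lost`). Spores 1 and 2 are MATa, spores 3 and 4 are MATalpha; because the
#' tracked mutations are unlinked to MAT, every subset of `carriers` spores is
#' equally likely. Self-mating picks one of the four spores uniformly and
#' diploidises it by mating-type switching; inter-spore mating picks one of
#' the four MATa x MATalpha pairs uniformly (`pairing = "mat_pairs"`).
#' `pairing = "any_pair"` instead draws two distinct spores uniformly from the
#' six unordered pairs, which is provably equivalent for MAT-unlinked
#' mutations and is exposed so that the equivalence can be demonstrated.
#'
#' Probabilities are computed by integer counting, so they are exact rationals;
#' the integer numerators and common denominator are attached as attributes
#' `"numerators"` and `"denominator"`.
#'
#' @param carriers number of carrier spores, 0 to 4.
#' @param mode `"inter_spore"` or `"self"`.
#' @param pairing inter-spore pairing rule, `"mat_pairs"` (default) or
#'   `"any_pair"`.
#' @return named numeric vector `c(fixed=, heterozygous=, lost=)`.
#' @examples
#' enumerateMatingOutcomes(2, "inter_spore")  # 1/6, 2/3, 1/6
#' enumerateMatingOutcomes(1, "self")         # 1/4, 0, 3/4
#' @export
enumerateMatingOutcomes <- function(carriers,
                                    mode = c("inter_spore", "self"),
                                    pairing = c("mat_pairs", "any_pair")) {
    mode <- match.arg(mode)
    pairing <- match.arg(pairing)
    carriers <- as.integer(carriers)
    if (length(carriers) != 1L || is.na(carriers) || carriers < 0L ||
        carriers > 4L)
        stop("'carriers' must be a single integer in 0..4")

    subsets <- utils::combn(4L, carriers)
    if (carriers == 0L)
        subsets <- matrix(integer(0), nrow = 0L, ncol = 1L)
    nSubsets <- ncol(subsets)

    if (mode == "self") {
        matings <- lapply(1:4, function(i) c(i, i))
    } else if (pairing == "mat_pairs") {
        matings <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
    } else {
        matings <- utils::combn(4L, 2L, simplify = FALSE)
    }

    counts <- c(fixed = 0L, heterozygous = 0L, lost = 0L)
    for (j in seq_len(nSubsets)) {
        carrierSet <- subsets[, j]
        for (pair in matings) {
            nCarried <- sum(pair %in% carrierSet)
            if (mode == "self")           # one spore counted as both gametes
                nCarried <- 2L * as.integer(pair[1L] %in% carrierSet)
            cls <- c("lost", "heterozygous", "fixed")[nCarried + 1L]
            counts[cls] <- counts[cls] + 1L
        }
    }
    denom <- nSubsets * length(matings)
    prob <- counts / denom
    attr(prob, "numerators") <- counts
    attr(prob, "denominator") <- denom
    prob
}

#' Analytic fate probabilities of a segregating mutation over one meiosis
#'
#' Closed-form probabilities that a mutation carried by 1 or 2 of the four
#' spores of a tetrad is fixed to homozygosity (P_F), remains heterozygous
#' (P_H), or is lost (P_L) after one round of meiosis followed by intra-tetrad
#' mating, where the mating is self with probability `s` and inter-spore with
#' probability `1 - s`. A mutation heterozygous in the parent diploid (or
#' arising before meiotic DNA replication) segregates 2:2 (`carriers = 2`);
#' one arising during or after replication is carried by a single chromatid
#' (`carriers = 1`). For `carriers = 2`:
#' \deqn{P_H = (1-s)\,2/3, \quad P_F = P_L = s/2 + (1-s)/6.}
#' For `carriers = 1`:
#' \deqn{P_F = s/4, \quad P_H = (1-s)/2, \quad P_L = 3s/4 + (1-s)/2.}
#' These mix the exact [enumerateMatingOutcomes()] distributions with weights
#' `(1-s, s)`.
#'
#' @param carriers 1 or 2 carrier spores.
#' @param s self-mating fraction in \[0,1\].
#' @return named numeric vector `c(pFix=, pHet=, pLoss=)`, with attribute
#'   `"s"`.
#' @examples
#' analyticFateProbs(2, s = 0)     # 1/6, 2/3, 1/6
#' analyticFateProbs(2, s = 0.17)  # P_H = 0.83 * 2/3
#' @export
analyticFateProbs <- function(carriers, s) {
    carriers <- as.integer(carriers)
    if (length(carriers) != 1L || is.na(carriers) ||
        !carriers %in% c(1L, 2L))
        stop("unsupported carriage: 'carriers' must be 1 or 2")
    if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
        stop("'s' must be a single probability in [0, 1]")
    if (carriers == 2L) {
        pHet <- (1 - s) * 2 / 3
        pFix <- s / 2 + (1 - s) / 6
        pLoss <- pFix
    } else {
        pFix <- s / 4
        pHet <- (1 - s) / 2
        pLoss <- 3 * s / 4 + (1 - s) / 2
    }
    out <- c(pFix = pFix, pHet = pHet, pLoss = pLoss)
    stopifnot(abs(sum(out) - 1) < 1e-12)
    attr(out, "s") <- s
    out
}

#' Probability that a heterozygous mutation is resolved within n meioses
#'
#' A 2:2-segregating heterozygous mutation survives one meiotic bottleneck as
#' heterozygous with probability \eqn{(1-s)\cdot 2/3}; the probability that it
#' has been fixed or lost after `n` bottlenecks is therefore
#' \deqn{1 - ((1-s)\, 2/3)^n.}
#' With the observed s = 0.17 this exceeds 99\% after nine meioses.
#'
#' @param n number of meiotic bottlenecks (non-negative integer, vectorised).
#' @param s self-mating fraction.
#' @return probability vector, same length as `n`.
#' @examples
#' fixOrLossProbAfterN(9, s = 0.17)  # > 0.99
#' @export
fixOrLossProbAfterN <- function(n, s) {
    if (any(n < 0) || any(n != floor(n)))
        stop("'n' must contain non-negative integers")
    if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
        stop("'s' must be a single probability in [0, 1]")
    1 - ((1 - s) * 2 / 3)^n
}

#' @describeIn perkinsDistance map distance in cM from PD/TT/NPD counts,
#'   `50 * (TT + 6 NPD) / (PD + TT + NPD)`.
#' @export
setMethod("perkinsDistance", "TetradClassCounts", function(object) {
    total <- object@pd + object@tt + object@npd
    if (total == 0L)
        stop("empty input: pd + tt + npd must be positive")
    50 * (object@tt + 6 * object@npd) / total
})

#' Crossover correction of observed intra-tetrad mating frequencies
#'
#' An inter-spore mating is scored as a self-mating whenever a single
#' crossover between the drug marker and the MAT locus leaves both mated
#' spores with the same marker. With per-spore recombination frequency `rf`
#' the tetratype frequency is `2 * rf`, and within a tetratype tetrad half of
#' the four MATa x MATalpha pairings produce a same-marker diploid, so the
#' misclassification probability per inter-spore mating is `q = rf`. The
#' observed self fraction is then `s + (1 - s) * q`, which is solved for the
#' true self-mating fraction `s`. Observed fractions at or below the
#' misclassification floor `q` return `s = 0` with a warning.
#'
#' @param fInter observed inter-spore mating fraction.
#' @param fSelf observed self-mating fraction (`1 - fInter`).
#' @param rf per-spore recombination frequency between marker and MAT,
#'   in \[0, 0.5).
#' @return list with corrected `fInter`, `fSelf`, the `rf` used, and logical
#'   `atFloor`.
#' @examples
#' correctMatingFrequencies(0.82, 0.18, rf = 0.01)  # ~0.83 / 0.17
#' @export
correctMatingFrequencies <- function(fInter, fSelf = 1 - fInter, rf) {
    if (abs(fInter + fSelf - 1) > 1e-8)
        stop("fInter + fSelf must equal 1")
    if (length(rf) != 1L || is.na(rf) || rf < 0 || rf >= 0.5)
        stop("'rf' must lie in [0, 0.5)")
    q <- rf
    atFloor <- FALSE
    if (fSelf < q) {
        warning("observed self-mating fraction is below the crossover ",
                "misclassification floor q = ", q, "; returning s = 0")
        s <- 0
        atFloor <- TRUE
    } else {
        s <- (fSelf - q) / (1 - q)
        if (s == 0) atFloor <- TRUE
    }
    list(fInter = 1 - s, fSelf = s, rf = rf, atFloor = atFloor)
}
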