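#' @include AllClasses.R AllGenerics.R tetrad-genetics.R
NULL

## Conditional resolution probabilities, by mating mode and carriage.
## These are the exact enumeration outcomes:
##   carriage 2, inter-spore: fixed 1/6, het 2/3, lost 1/6
##   carriage 2, self:        fixed 1/2, het 0,   lost 1/2
##   carriage 1, inter-spore: fixed 0,   het 1/2, lost 1/2
##   carriage 1, self:        fixed 1/4, het 0,   lost 3/4
.resolveCounts <- function(pool, selfMode, carriage) {
    n <- length(pool)
    fixed <- integer(n)
    het <- integer(n)
    if (carriage == 2L) {
        i <- selfMode
        fixed[i] <- stats::rbinom(sum(i), pool[i], 0.5)
        fixed[!i] <- stats::rbinom(sum(!i), pool[!i], 1 / 6)
        # remaining mutations are het with prob (2/3)/(2/3 + 1/6) = 4/5
        het[!i] <- stats::rbinom(sum(!i), pool[!i] - fixed[!i], 4 / 5)
    } else {
        i <- selfMode
        fixed[i] <- stats::rbinom(sum(i), pool[i], 1 / 4)
        het[!i] <- stats::rbinom(sum(!i), pool[!i], 1 / 2)
    }
    list(fixed = fixed, het = het, lost = pool - fixed - het)
}

#' Draw the number of new mitotic mutations over a growth phase
#'
#' Base substitutions per division are Poisson with mean `m * G`, the standard
#' thinning of a per-base Bernoulli process at these rates, so a phase of
#' `nDivisions` divisions contributes `Poisson(nDivisions * m * G)` new
#' heterozygous mutations (carriage 2 at the next meiosis).
#'
#' @param config a [SimConfig-class].
#' @param nDivisions number of mitotic divisions.
#' @param n number of independent draws (default 1).
#' @return integer vector of length `n`.
#' @export
drawMitoticMutations <- function(config, nDivisions = config@divisionsPerBottleneck,
                                 n = 1L) {
    if (nDivisions < 0)
        stop("'nDivisions' must be non-negative")
    stats::rpois(n, nDivisions * config@m * config@genomeSize)
}

#' Draw the number of new meiotic mutations for one meiosis
#'
#' Counts are Poisson with mean `mu * G` where `mu = muMultiplier * m`. Under
#' the pre-replication scenario each mutation is present in two of the four
#' chromatids (carriage 2); under the post-replication scenario in a single
#' chromatid (carriage 1).
#'
#' @inheritParams drawMitoticMutations
#' @return integer vector of length `n`, with attribute `"carriage"`.
#' @export
drawMeioticMutations <- function(config, n = 1L) {
    if (config@scenario == "vegetative_only")
        stop("meiotic mutations are not applicable to scenario 'vegetative_only'")
    counts <- stats::rpois(n, config@muMultiplier * config@m * config@genomeSize)
    attr(counts, "carriage") <-
        if (config@scenario == "pre_replication") 2L else 1L
    counts
}

## Joint-mode resolution of one bottleneck for a single line: explicit carrier
## spore subsets per mutation, one shared mating event.
.resolveJoint <- function(pool2, pool1, s) {
    fixed <- 0L; het <- 0L
    selfMode <- stats::runif(1) < s
    if (selfMode) {
        k <- sample.int(4L, 1L)
        if (pool2 > 0L)
            for (i in seq_len(pool2)) {
                carrierSet <- sample.int(4L, 2L)
                if (k %in% carrierSet) fixed <- fixed + 1L
            }
        if (pool1 > 0L)
            for (i in seq_len(pool1)) {
                if (sample.int(4L, 1L) == k) fixed <- fixed + 1L
            }
    } else {
        pair <- c(sample.int(2L, 1L), sample.int(2L, 1L) + 2L)
        if (pool2 > 0L)
            for (i in seq_len(pool2)) {
                carrierSet <- sample.int(4L, 2L)
                nIn <- sum(pair %in% carrierSet)
                if (nIn == 2L) fixed <- fixed + 1L
                else if (nIn == 1L) het <- het + 1L
            }
        if (pool1 > 0L)
            for (i in seq_len(pool1)) {
                if (sample.int(4L, 1L) %in% pair) het <- het + 1L
            }
    }
    list(fixed = fixed, het = het, lost = pool2 + pool1 - fixed - het)
}

#' Apply one meiotic bottleneck to a line
#'
#' Draws one mating mode for the bottleneck (self with probability `s`) and
#' resolves every segregating mutation conditional on that mode using the
#' exact tetrad outcome distributions: pre-existing heterozygous mutations and
#' pre-replication meiotic mutations segregate 2:2 (carriage 2);
#' post-replication meiotic mutations are carried by one spore (carriage 1).
#' Fixed mutations increment the homozygous tally, lost ones are removed, and
#' surviving heterozygous mutations (all carriage 2 at the next meiosis)
#' persist. Draws from the current RNG stream.
#'
#' @param line a [LineState-class].
#' @param config a [SimConfig-class].
#' @param newMeiotic number of new meiotic mutations entering this meiosis;
#'   they are added to the line's generated tally here.
#' @return the updated [LineState-class].
#' @export
applyMeioticBottleneck <- function(line, config, newMeiotic = 0L) {
    carriage1 <- 0L
    carriage2 <- line@nHet
    if (newMeiotic > 0L) {
        if (config@scenario == "pre_replication")
            carriage2 <- carriage2 + as.integer(newMeiotic)
        else
            carriage1 <- as.integer(newMeiotic)
    }
    if (config@matingModel == "joint") {
        res <- .resolveJoint(carriage2, carriage1, config@s)
    } else {
        selfMode <- stats::runif(1) < config@s
        r2 <- .resolveCounts(carriage2, selfMode, 2L)
        r1 <- .resolveCounts(carriage1, selfMode, 1L)
        res <- list(fixed = r2$fixed + r1$fixed, het = r2$het + r1$het,
                    lost = r2$lost + r1$lost)
    }
    new("LineState",
        nHet = as.integer(res$het),
        nFixed = line@nFixed + as.integer(res$fixed),
        bottleneckIndex = line@bottleneckIndex + 1L,
        nGenerated = line@nGenerated + as.integer(newMeiotic),
        nLost = line@nLost + as.integer(res$lost))
}

.emptyLine <- function() {
    new("LineState", nHet = 0L, nFixed = 0L, bottleneckIndex = 0L,
        nGenerated = 0L, nLost = 0L)
}

#' Simulate one meiotic ("T") mutation-accumulation line
#'
#' Repeats `nBottlenecks` cycles of: `divisionsPerBottleneck` mitotic
#' divisions accruing Poisson heterozygous mutations, one meiosis accruing
#' Poisson meiotic mutations (carriage set by the scenario), and one
#' intra-tetrad mating bottleneck resolving every segregating mutation.
#' Draws from the current RNG stream; seed externally (or use
#' [simulateEnsemble()]).
#'
#' @param config a [SimConfig-class] with scenario `"pre_replication"` or
#'   `"post_replication"`.
#' @return final [LineState-class].
#' @export
simulateTLine <- function(config) {
    if (config@scenario == "vegetative_only")
        stop("use simulateBLine() for scenario 'vegetative_only'")
    line <- .emptyLine()
    for (b in seq_len(config@nBottlenecks)) {
        nm <- drawMitoticMutations(config)
        line@nHet <- line@nHet + as.integer(nm)
        line@nGenerated <- line@nGenerated + as.integer(nm)
        mm <- drawMeioticMutations(config)
        line <- applyMeioticBottleneck(line, config, newMeiotic = mm)
    }
    validObject(line)
    line
}

#' Simulate one vegetative ("B") mutation-accumulation line
#'
#' Accumulates only heterozygous mutations over
#' `nBottlenecks * divisionsPerBottleneck` mitotic divisions; nothing is ever
#' fixed or lost (vegetative-line mutations stay heterozygous).
#'
#' @param config a [SimConfig-class] with scenario `"vegetative_only"`.
#' @return final [LineState-class].
#' @export
simulateBLine <- function(config) {
    if (config@scenario != "vegetative_only")
        stop("simulateBLine() requires scenario 'vegetative_only'")
    line <- .emptyLine()
    for (b in seq_len(config@nBottlenecks)) {
        nm <- drawMitoticMutations(config)
        line@nHet <- line@nHet + as.integer(nm)
        line@nGenerated <- line@nGenerated + as.integer(nm)
        line@bottleneckIndex <- line@bottleneckIndex + 1L
    }
    validObject(line)
    line
}

## Vectorised independent-resolution engine: state vectors across replicates.
.simulateEnsembleIndependent <- function(config) {
    n <- config@nReplicates
    lamMito <- config@divisionsPerBottleneck * config@m * config@genomeSize
    vegetative <- config@scenario == "vegetative_only"
    lamMeio <- if (vegetative) 0 else
        config@muMultiplier * config@m * config@genomeSize
    het <- integer(n); fixed <- integer(n)
    generated <- integer(n); lost <- integer(n)
    for (b in seq_len(config@nBottlenecks)) {
        nm <- stats::rpois(n, lamMito)
        generated <- generated + nm
        het <- het + nm
        if (vegetative) next
        mm <- stats::rpois(n, lamMeio)
        generated <- generated + mm
        if (config@scenario == "pre_replication") {
            pool2 <- het + mm
            pool1 <- integer(n)
        } else {
            pool2 <- het
            pool1 <- mm
        }
        selfMode <- stats::runif(n) < config@s
        r2 <- .resolveCounts(pool2, selfMode, 2L)
        r1 <- .resolveCounts(pool1, selfMode, 1L)
        fixed <- fixed + r2$fixed + r1$fixed
        lost <- lost + r2$lost + r1$lost
        het <- as.integer(r2$het + r1$het)
    }
    list(hom = as.integer(fixed), het = as.integer(het),
         generated = as.integer(generated), lost = as.integer(lost))
}

## Joint engine: one derived seed per replicate, explicit spore genotypes.
.simulateEnsembleJoint <- function(config) {
    n <- config@nReplicates
    seeds <- sample.int(.Machine$integer.max, n)
    hom <- integer(n); het <- integer(n)
    generated <- integer(n); lost <- integer(n)
    one <- if (config@scenario == "vegetative_only") simulateBLine else
        simulateTLine
    for (r in seq_len(n)) {
        set.seed(seeds[r])
        line <- one(config)
        hom[r] <- line@nFixed
        het[r] <- line@nHet
        generated[r] <- line@nGenerated
        lost[r] <- line@nLost
    }
    list(hom = hom, het = het, generated = generated, lost = lost)
}

#' Simulate an ensemble of independent replicate lines
#'
#' Runs `nReplicates` independent lines under `config` and records the final
#' homozygous and heterozygous counts of each. The RNG is seeded from
#' `config@seed`, so the result is fully reproducible. The default
#' `"independent"` mating model resolves mutations independently given a
#' shared per-bottleneck mating mode and is vectorised across replicates; the
#' `"joint"` model simulates explicit carrier-spore subsets and a shared mated
#' pair per bottleneck, one derived RNG substream per replicate. The two are
#' statistically indistinguishable for MAT-unlinked mutations.
#'
#' @param config a [SimConfig-class].
#' @return an [EnsembleResult-class].
#' @examples
#' ens <- simulateEnsemble(simConfigNew(nReplicates = 200, seed = 7))
#' mean(finalHom(ens))
#' @export
simulateEnsemble <- function(config) {
    validObject(config)
    set.seed(config@seed)
    res <- if (config@matingModel == "joint")
        .simulateEnsembleJoint(config)
    else
        .simulateEnsembleIndependent(config)
    out <- new("EnsembleResult", finalHom = res$hom, finalHet = res$het,
               nGenerated = res$generated, nLost = res$lost, config = config)
    validObject(out)
    out
}
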