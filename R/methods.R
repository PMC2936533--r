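#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("finalHom", "EnsembleResult", function(object) object@finalHom)

#' @rdname accessors
#' @export
setMethod("finalHet", "EnsembleResult", function(object) object@finalHet)

#' @rdname accessors
#' @export
setMethod("simConfig", "EnsembleResult", function(object) object@config)

#' @rdname accessors
#' @export
setMethod("nHet", "LineState", function(object) object@nHet)

#' @rdname accessors
#' @export
setMethod("nFixed", "LineState", function(object) object@nFixed)

#' @rdname accessors
#' @export
setMethod("assayCounts", "MatingAssayTable", function(object) object@assay)

#' @rdname accessors
#' @export
setMethod("multipliers", "UpperLimitScan", function(object) object@multipliers)

#' @rdname accessors
#' @export
setMethod("pValues", "UpperLimitScan", function(object) object@pValues)

#' @rdname accessors
#' @export
setMethod("mutationRate", "RateEstimate", function(object) object@rate)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat("  m (mitotic rate):      ", format(object@m, digits = 3), "\n")
    cat("  mu multiplier:         ", object@muMultiplier,
        sprintf(" (mu = %s)", format(object@muMultiplier * object@m,
                                     digits = 3)), "\n")
    cat("  genome size (bp):      ", format(object@genomeSize, big.mark = ","),
        "\n")
    cat("  bottlenecks:           ", object@nBottlenecks, "x",
        object@divisionsPerBottleneck, "divisions\n")
    cat("  scenario:              ", object@scenario, "\n")
    cat("  self-mating fraction s:", object@s, "\n")
    cat("  replicates:            ", object@nReplicates,
        " seed:", object@seed, " model:", object@matingModel, "\n")
})

setMethod("show", "LineState", function(object) {
    cat("LineState after", object@bottleneckIndex, "bottleneck(s):",
        object@nFixed, "homozygous,", object@nHet, "heterozygous,",
        object@nLost, "lost of", object@nGenerated, "generated\n")
})

setMethod("show", "EnsembleResult", function(object) {
    cat("EnsembleResult:", length(object@finalHom), "replicates (",
        object@config@scenario, ", mu =", object@config@muMultiplier,
        "x m )\n")
    cat("  mean final homozygous:  ", round(mean(object@finalHom), 3), "\n")
    cat("  mean final heterozygous:", round(mean(object@finalHet), 3), "\n")
})

setMethod("show", "TetradClassCounts", function(object) {
    cat("TetradClassCounts: PD =", object@pd, " TT =", object@tt,
        " NPD =", object@npd, "\n")
    if (object@pd + object@tt + object@npd > 0L)
        cat("  Perkins distance:", round(perkinsDistance(object), 3), "cM\n")
})

setMethod("show", "MatingAssayTable", function(object) {
    cat("MatingAssayTable with", nrow(object@assay), "method(s)\n")
    print(object@assay, row.names = FALSE)
})

setMethod("show", "RateEstimate", function(object) {
    cat("RateEstimate:", format(signif(object@rate, 2), digits = 2),
        "substitutions per base per division\n")
    cat("  ", object@correctionFactor, "x", object@k, "mutations /(",
        format(object@genomeSize, big.mark = ","), "bp x",
        object@generations, "divisions )\n")
})

setMethod("show", "UpperLimitScan", function(object) {
    cat("UpperLimitScan (", object@scenario, "), observed homozygous =",
        object@observedHom, ", alpha =", object@alpha, "\n")
    cat("  grid:", length(object@multipliers), "multipliers in [",
        min(object@multipliers), ",", max(object@multipliers), "]\n")
    cat("  smallest inconsistent multiplier:",
        object@smallestInconsistent, "\n")
    cat("  largest consistent multiplier:  ",
        object@largestConsistent, " (mu_max =",
        format(object@muMax, digits = 3), ")\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: m =", format(object@m, digits = 3),
        " mu =", object@muMultiplier, "x m  s =", object@s,
        " Rf =", object@rf, " (", object@cm, "cM )  seed =", object@seed, "\n")
})
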