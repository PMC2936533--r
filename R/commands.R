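#' @include io.R rate-inference.R mating-assay.R synthetic-data.R
NULL

.writeManifest <- function(command, configList, seed, outputs, prefix) {
    path <- paste0(prefix, ".manifest.json")
    jsonlite::write_json(
        list(command = command,
             package = "tetradMA",
             version = as.character(utils::packageVersion("tetradMA")),
             seed = seed,
             config = configList,
             config_hash = sum(utf8ToInt(paste(
                 vapply(configList, function(x) paste(format(x), collapse = ","),
                        character(1L)), collapse = "|"))),
             outputs = as.list(outputs)),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Run an ensemble simulation from a JSON config file
#'
#' Reads a [SimConfig-class] from JSON, runs [simulateEnsemble()], and writes
#' the per-replicate TSV, a JSON config sidecar, and a run manifest under
#' `outPrefix`.
#'
#' @param configPath path to a JSON simulation config.
#' @param outPrefix output path prefix.
#' @return the [EnsembleResult-class], invisibly.
#' @export
cmdSimulate <- function(configPath, outPrefix) {
    config <- readSimConfig(configPath)
    ens <- simulateEnsemble(config)
    outputs <- writeEnsembleResult(ens, outPrefix)
    .writeManifest("simulate", .simConfigToList(config), config@seed,
                   outputs, outPrefix)
    invisible(ens)
}

#' Run a meiotic-rate upper-limit scan from a JSON config file
#'
#' @param configPath path to a JSON simulation config (base configuration; the
#'   meiotic-rate multiplier is overridden per grid point).
#' @param outPrefix output path prefix.
#' @param multipliers ascending multiplier grid.
#' @param observedHom observed homozygous count.
#' @param alpha significance threshold.
#' @return the [UpperLimitScan-class], invisibly.
#' @export
cmdScan <- function(configPath, outPrefix, multipliers = seq(0, 100, by = 5),
                    observedHom = 5, alpha = 0.05) {
    config <- readSimConfig(configPath)
    scan <- scanUpperLimit(config, multipliers = multipliers,
                           observedHom = observedHom, alpha = alpha)
    outputs <- writeScan(scan, outPrefix, m = config@m)
    .writeManifest("scan", .simConfigToList(config), config@seed, outputs,
                   outPrefix)
    invisible(scan)
}

#' Per-line and average mutation rates from a mutation table
#'
#' Counts mutations per line in a TSV mutation table and applies the
#' design-appropriate estimator: `vegetative_spore` (count doubled, half the
#' genome observed), `vegetative_diploid` (no correction), or `meiotic`
#' (homozygous count doubled for mating losses). Designs and generation
#' counts are supplied per line.
#'
#' @param tablePath path to a mutation-table TSV.
#' @param designs named character vector mapping line IDs to designs.
#' @param generations named numeric vector mapping line IDs to total
#'   divisions.
#' @param genomeSize diploid genome size in bp.
#' @param outPrefix optional output prefix; if given, a JSON report and
#'   manifest are written.
#' @return data.frame with one row per line (`line`, `design`, `k`,
#'   `generations`, `rate`, `rate2sf`) plus the average rate as attribute
#'   `"averageRate"`.
#' @export
cmdRates <- function(tablePath, designs, generations,
                     genomeSize = yeastDiploidGenomeSize, outPrefix = NULL) {
    tab <- readMutationTable(tablePath)
    lines <- names(designs)
    if (is.null(lines) || is.null(names(generations)))
        stop("'designs' and 'generations' must be named by line ID")
    bad <- setdiff(unique(tab$line), lines)
    if (length(bad))
        stop("no design given for line(s): ", paste(bad, collapse = ", "))
    if (!all(designs %in% c("vegetative_spore", "vegetative_diploid",
                            "meiotic")))
        stop("unknown design flag; use vegetative_spore, vegetative_diploid ",
             "or meiotic")
    k <- vapply(lines, function(l) sum(tab$line == l), integer(1L))
    ests <- lapply(seq_along(lines), function(i) {
        g <- generations[[lines[i]]]
        switch(designs[[i]],
            vegetative_spore = vegetativeRateFromSpore(k[i], genomeSize, g),
            vegetative_diploid = vegetativeRateFromDiploid(k[i], genomeSize, g),
            meiotic = meioticLineRate(k[i], genomeSize, g))
    })
    rates <- vapply(ests, mutationRate, numeric(1L))
    out <- data.frame(line = lines, design = unname(designs), k = unname(k),
                      generations = unname(generations[lines]),
                      rate = rates, rate2sf = signif(rates, 2),
                      stringsAsFactors = FALSE)
    if (all(k == 0L)) warning("empty table: all per-line counts are zero")
    attr(out, "averageRate") <- mean(rates)
    if (!is.null(outPrefix)) {
        path <- paste0(outPrefix, ".rates.json")
        jsonlite::write_json(
            list(perLine = out, average_rate = mean(rates),
                 # printed-arithmetic average: mean of the 2 s.f. rates
                 average_rate_2sf = signif(mean(signif(rates, 2)), 2)),
            path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        .writeManifest("rates",
                       list(table = tablePath, genomeSize = genomeSize),
                       NA, c(rates = path), outPrefix)
    }
    out
}

#' Pooled and corrected mating frequencies from an assay table
#'
#' @param assayPath path to a mating-assay TSV.
#' @param rf per-spore recombination frequency for the crossover correction;
#'   `NULL` reports raw pooled frequencies only.
#' @param tetradClassesPath optional path to a PD/TT/NPD TSV; when given, the
#'   Perkins map distance is included in the report.
#' @param outPrefix optional output prefix for a JSON report and manifest.
#' @return list with `pooled`, and `corrected` / `perkinsCM` when requested.
#' @export
cmdMating <- function(assayPath, rf = NULL, tetradClassesPath = NULL,
                      outPrefix = NULL) {
    tab <- readMatingAssay(assayPath)
    report <- list(pooled = pooledFrequencies(tab))
    if (!is.null(rf))
        report$corrected <- correctedFrequencies(tab, rf = rf)
    if (!is.null(tetradClassesPath))
        report$perkinsCM <- perkinsDistance(readTetradClasses(tetradClassesPath))
    if (!is.null(outPrefix)) {
        path <- paste0(outPrefix, ".mating.json")
        jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        .writeManifest("mating",
                       list(assay = assayPath, rf = rf,
                            tetradClasses = tetradClassesPath),
                       NA, c(mating = path), outPrefix)
    }
    report
}
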