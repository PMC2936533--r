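#' @include AllClasses.R constructors.R
NULL

#' Read and write tetrad class counts
#'
#' Three-column TSV with a header line (`pd`, `tt`, `npd`).
#'
#' @param path file path.
#' @param x a [TetradClassCounts-class].
#' @return `readTetradClasses` returns a [TetradClassCounts-class];
#'   `writeTetradClasses` returns `path` invisibly.
#' @name tetradClassIO
NULL

#' @rdname tetradClassIO
#' @export
readTetradClasses <- function(path) {
    d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("pd", "tt", "npd") %in% names(d)) || nrow(d) != 1L)
        stop("tetrad class file must be a one-row TSV with columns pd, tt, npd")
    tetradClassCounts(pd = d$pd, tt = d$tt, npd = d$npd)
}

#' @rdname tetradClassIO
#' @export
writeTetradClasses <- function(x, path) {
    stopifnot(is(x, "TetradClassCounts"))
    utils::write.table(data.frame(pd = x@pd, tt = x@tt, npd = x@npd),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write mating-assay tables
#'
#' TSV mirroring the assay's per-method layout: columns `method`,
#' `tetrads_germinated`, `colonies_typed`, `n_inter`, `n_self`,
#' `n_multiple_tetrads`, `tetrads_two_typed`.
#'
#' @param path file path.
#' @param x a [MatingAssayTable-class].
#' @return `readMatingAssay` returns a [MatingAssayTable-class];
#'   `writeMatingAssay` returns `path` invisibly.
#' @name matingAssayIO
NULL

#' @rdname matingAssayIO
#' @export
readMatingAssay <- function(path) {
    d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("method", "tetrads_germinated", "colonies_typed", "n_inter",
              "n_self", "n_multiple_tetrads", "tetrads_two_typed")
    if (!all(need %in% names(d)))
        stop("mating assay file must have columns: ",
             paste(need, collapse = ", "))
    matingAssayTable(method = d$method,
                     tetradsGerminated = d$tetrads_germinated,
                     coloniesTyped = d$colonies_typed,
                     nInter = d$n_inter, nSelf = d$n_self,
                     nMultipleTetrads = d$n_multiple_tetrads,
                     tetradsTwoTyped = d$tetrads_two_typed)
}

#' @rdname matingAssayIO
#' @export
writeMatingAssay <- function(x, path) {
    stopifnot(is(x, "MatingAssayTable"))
    d <- assayCounts(x)
    out <- data.frame(method = d$method,
                      tetrads_germinated = d$tetradsGerminated,
                      colonies_typed = d$coloniesTyped,
                      n_inter = d$nInter, n_self = d$nSelf,
                      n_multiple_tetrads = d$nMultipleTetrads,
                      tetrads_two_typed = d$tetradsTwoTyped)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write per-line mutation tables
#'
#' TSV with columns `line`, `chrom`, `pos_1based`, `ref_alt`, `zygosity`,
#' `gene_note` (1-based coordinates).
#'
#' @param path file path.
#' @param x data.frame as produced by [generateMutationTable()].
#' @return `readMutationTable` returns the data.frame; `writeMutationTable`
#'   returns `path` invisibly.
#' @name mutationTableIO
NULL

#' @rdname mutationTableIO
#' @export
readMutationTable <- function(path) {
    d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("line", "chrom", "pos_1based", "ref_alt", "zygosity")
    if (!all(need %in% names(d)))
        stop("mutation table must have columns: ", paste(need, collapse = ", "))
    if (!"gene_note" %in% names(d)) d$gene_note <- ""
    d$gene_note <- as.character(d$gene_note)
    d$gene_note[is.na(d$gene_note)] <- ""
    d
}

#' @rdname mutationTableIO
#' @export
writeMutationTable <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write simulation configurations as JSON
#'
#' @param path file path.
#' @param config a [SimConfig-class].
#' @return `readSimConfig` returns a [SimConfig-class]; `writeSimConfig`
#'   returns `path` invisibly.
#' @name simConfigIO
NULL

.simConfigToList <- function(config) {
    list(m = config@m, muMultiplier = config@muMultiplier,
         genomeSize = config@genomeSize,
         divisionsPerBottleneck = config@divisionsPerBottleneck,
         nBottlenecks = config@nBottlenecks, scenario = config@scenario,
         s = config@s, nReplicates = config@nReplicates, seed = config@seed,
         matingModel = config@matingModel)
}

#' @rdname simConfigIO
#' @export
readSimConfig <- function(path) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    known <- names(formals(simConfigNew))
    unknown <- setdiff(names(lst), known)
    if (length(unknown))
        stop("unknown config fields: ", paste(unknown, collapse = ", "))
    do.call(simConfigNew, lst)
}

#' @rdname simConfigIO
#' @export
writeSimConfig <- function(config, path) {
    stopifnot(is(config, "SimConfig"))
    jsonlite::write_json(.simConfigToList(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' Write and read an ensemble result
#'
#' `writeEnsembleResult` writes `<prefix>.tsv` (columns `final_hom`,
#' `final_het`, `n_generated`, `n_lost`) and a JSON sidecar
#' `<prefix>.config.json` echoing the configuration.
#'
#' @param x an [EnsembleResult-class].
#' @param prefix output path prefix.
#' @return `writeEnsembleResult` returns the two paths invisibly;
#'   `readEnsembleResult` returns an [EnsembleResult-class].
#' @name ensembleIO
NULL

#' @rdname ensembleIO
#' @export
writeEnsembleResult <- function(x, prefix) {
    stopifnot(is(x, "EnsembleResult"))
    tsv <- paste0(prefix, ".tsv")
    side <- paste0(prefix, ".config.json")
    utils::write.table(
        data.frame(final_hom = x@finalHom, final_het = x@finalHet,
                   n_generated = x@nGenerated, n_lost = x@nLost),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(.simConfigToList(x@config), side, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(c(tsv = tsv, config = side))
}

#' @rdname ensembleIO
#' @export
readEnsembleResult <- function(prefix) {
    d <- utils::read.delim(paste0(prefix, ".tsv"), sep = "\t")
    cfg <- readSimConfig(paste0(prefix, ".config.json"))
    new("EnsembleResult", finalHom = as.integer(d$final_hom),
        finalHet = as.integer(d$final_het),
        nGenerated = as.integer(d$n_generated),
        nLost = as.integer(d$n_lost), config = cfg)
}

#' Write an upper-limit scan
#'
#' Writes `<prefix>.tsv` (columns `multiplier`, `mu_rate`, `p_value`) and a
#' JSON summary `<prefix>.summary.json` (largest consistent multiplier,
#' smallest inconsistent multiplier, mu_max, alpha, observed count, scenario).
#'
#' @param x an [UpperLimitScan-class].
#' @param m mitotic rate used to express multipliers as rates.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeScan <- function(x, prefix, m = vegetativeRateDefault) {
    stopifnot(is(x, "UpperLimitScan"))
    tsv <- paste0(prefix, ".tsv")
    summ <- paste0(prefix, ".summary.json")
    utils::write.table(
        data.frame(multiplier = x@multipliers, mu_rate = x@multipliers * m,
                   p_value = x@pValues),
        tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(scenario = x@scenario, alpha = x@alpha,
             observed_hom = x@observedHom,
             smallest_inconsistent_multiplier = x@smallestInconsistent,
             largest_consistent_multiplier = x@largestConsistent,
             mu_max = x@muMax),
        summ, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(tsv = tsv, summary = summ))
}
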