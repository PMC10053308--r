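# End-to-end orchestration: simulate (optional) -> Icity -> compositions ->
# codon bias -> profiles, with one config, seeded reproducibility and a run
# manifest. Outputs are deterministic: a rerun with the same config and
# seed reproduces every file byte-identically.

#' Build a pipeline configuration
#'
#' Aggregates every stage's tunables with their standard defaults: 10 kbp
#' co-localization window, 0.7 Icity threshold, strict all-runs selection,
#' the >20 occurrences / >=4 long-contig composition filter with a 20 kbp
#' long-contig cutoff, 10 kbp codon-bias flank, 20 kbp minimum region gap,
#' 360 nt minimum ORF and alpha 0.05.
#'
#' @param inputDir directory with the \code{\link{writeDataset}} layout
#'   plus \code{immune_pfams.txt}; ignored when \code{simConfig} is given.
#' @param simConfig optional \code{\link{DgrSimConfig-class}}; when
#'   present the pipeline simulates its own input.
#' @param outDir output directory.
#' @param D neighborhood window flank (bp).
#' @param threshold Icity selection threshold.
#' @param selectionMode \code{"all_runs"} (strict) or \code{"any_run"}.
#' @param subsampleFraction per-run contig subsample fraction.
#' @param minRuns,maxRuns Icity convergence floor and cap.
#' @param minOccurrences,minLong,lLong composition filter parameters.
#' @param E,gMin,minOrf,alpha,minN codon-bias screen parameters.
#' @param seed integer seed for the Icity runs.
#' @return a \code{dgrPipelineConfig} list.
#' @export
pipelineConfig <- function(inputDir = NULL, simConfig = NULL,
                           outDir = tempfile("dgrscan_"), D = 10000,
                           threshold = 0.7,
                           selectionMode = c("all_runs", "any_run"),
                           subsampleFraction = 0.8, minRuns = 2,
                           maxRuns = 25, minOccurrences = 20, minLong = 4,
                           lLong = 20000, E = 10000, gMin = 20000,
                           minOrf = 360, alpha = 0.05, minN = 3,
                           seed = 1L) {
  selectionMode <- match.arg(selectionMode)
  cfg <- list(inputDir = inputDir, simConfig = simConfig, outDir = outDir,
              D = D, threshold = threshold, selectionMode = selectionMode,
              subsampleFraction = subsampleFraction, minRuns = minRuns,
              maxRuns = maxRuns, minOccurrences = minOccurrences,
              minLong = minLong, lLong = lLong, E = E, gMin = gMin,
              minOrf = minOrf, alpha = alpha, minN = minN,
              seed = as.integer(seed))
  num <- c("D", "threshold", "subsampleFraction", "minRuns", "maxRuns",
           "minOccurrences", "minLong", "lLong", "E", "gMin", "minOrf",
           "alpha", "minN")
  bad <- num[vapply(cfg[num], function(v) !is.numeric(v) || v <= 0,
                    logical(1))]
  if (length(bad))
    stop("pipeline parameters must be positive: ",
         paste(bad, collapse = ", "))
  if (is.null(inputDir) && is.null(simConfig))
    stop("either inputDir or simConfig is required")
  class(cfg) <- "dgrPipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map onto \code{\link{pipelineConfig}} arguments; a
#' \code{sim:} block maps onto \code{\link{dgrSimConfig}} arguments.
#' Explicit arguments in \code{...} override file values.
#'
#' @param path YAML file.
#' @param ... overrides passed to \code{pipelineConfig}.
#' @return a \code{dgrPipelineConfig}.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  simConfig <- NULL
  if (!is.null(y$sim)) {
    simConfig <- do.call(dgrSimConfig, y$sim)
    y$sim <- NULL
  }
  args <- utils::modifyList(c(y, list(simConfig = simConfig)), list(...))
  do.call(pipelineConfig, args)
}

#' Run the full pipeline
#'
#' Executes simulate (optional), the multi-run Icity protocol, composition
#' assignment/selection and arrangement analysis, the codon-usage-bias
#' screen (when sequences are available) and residence/clade/taxon
#' profiling with gene-map export. Writes every stage table as TSV under
#' \code{config$outDir} plus \code{manifest.json} with seeds, run counts
#' and per-stage record counts.
#'
#' @param config a \code{dgrPipelineConfig} from
#'   \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runAll <- function(config) {
  stopifnot(inherits(config, "dgrPipelineConfig"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simConfig)) {
    sim <- simulateDataset(config$simConfig)
    dataset <- sim$dataset
    immune <- sim$immuneCatalog
    writeSimulation(sim, file.path(outDir, "sim"))
  } else {
    catalogPath <- file.path(config$inputDir, "immune_pfams.txt")
    if (!file.exists(catalogPath))
      stop("immune catalog not found: ", catalogPath)
    dataset <- readDataset(config$inputDir)
    immune <- readImmuneCatalog(catalogPath)
    sim <- NULL
  }

  icity <- runIcity(dataset, D = config$D, threshold = config$threshold,
                    subsampleFraction = config$subsampleFraction,
                    seed = config$seed, minRuns = config$minRuns,
                    maxRuns = config$maxRuns)
  writeTable(as.data.frame(icity), file.path(outDir, "icity.tsv"))

  selected <- selectPfams(icity, mode = config$selectionMode,
                          threshold = config$threshold)
  comps <- assignCompositions(dataset, selected, immune, D = config$D,
                              lLong = config$lLong)
  kept <- selectCompositions(comps, minOccurrences = config$minOccurrences,
                             minLong = config$minLong)
  compTab <- compositionSummary(comps)
  compTab$selected <- compTab$composition %in%
    compositionSummary(kept)$composition
  writeTable(compTab, file.path(outDir, "compositions.tsv"))
  if (nrow(compositionSummary(comps)))
    writeTable(upsetMatrix(comps), file.path(outDir, "upset_matrix.tsv"))

  arr <- arrangementProfile(kept, dataset)
  writeTable(arr$arrangements, file.path(outDir, "arrangements.tsv"))
  writeTable(arr$modal, file.path(outDir, "arrangements_modal.tsv"))

  bias <- NULL
  if (length(contigSequences(dataset)) &&
      nrow(compositionSummary(kept))) {
    bias <- biasScreen(dataset, kept, E = config$E, gMin = config$gMin,
                       minOrf = config$minOrf, alpha = config$alpha,
                       minN = config$minN)
    writeTable(bias$perGene, file.path(outDir, "nc_per_gene.tsv"))
    writeTable(bias$perLocus, file.path(outDir, "ks_per_contig.tsv"))
    writeTable(bias$perComposition,
               file.path(outDir, "bias_by_composition.tsv"))
  }

  res <- residenceProfile(kept, dataset)
  cl <- cladeProfile(kept, dataset)
  profiles <- merge(res, cl, by = "composition", sort = TRUE)
  writeTable(profiles, file.path(outDir, "profiles.tsv"))
  tx <- suppressWarnings(taxonProfile(kept, dataset))
  cbt <- as.data.frame(tx$cladeByTaxon)
  cbt <- cbind(data.frame(taxon = rownames(cbt), stringsAsFactors = FALSE),
               cbt)
  rownames(cbt) <- NULL
  writeTable(cbt, file.path(outDir, "clade_by_taxon.tsv"))
  maps <- exportGeneMaps(kept, dataset, file.path(outDir, "maps"))

  manifest <- list(
    package = "dgrscan",
    version = as.character(utils::packageVersion("dgrscan")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("simConfig", "inputDir", "outDir"))],
    icity_runs = icity@nRuns,
    icity_run_seeds = icity@runSeeds,
    counts = list(
      contigs = nrow(contigTable(dataset)),
      genes = nrow(geneTable(dataset)),
      dgr_systems = nrow(dgrSystemTable(dataset)),
      clusters_scored = nrow(icity@keys),
      clusters_selected = length(selected),
      compositions = nrow(compositionSummary(comps)),
      compositions_kept = nrow(compositionSummary(kept)),
      bias_loci_tested = if (is.null(bias)) 0L
                         else sum(bias$perLocus$status == "tested"),
      maps = length(maps)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, sim = sim, icity = icity,
                 selected = selected, compositions = comps, kept = kept,
                 arrangements = arr, bias = bias, profiles = profiles,
                 taxon = tx, manifest = manifest))
}
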