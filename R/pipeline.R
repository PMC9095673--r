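## End-to-end orchestration: run the stages in dependency order from a
## single config, capture provenance, and emit machine-readable reports.

#' Pipeline configuration
#'
#' Collects input paths, analysis thresholds and the master seed. Every
#' threshold default is the analysis convention used throughout the
#' package: confidence cutoff 0.3, 10-residue adjacency window, disorder
#' threshold 0.5 with 20-residue minimum runs, similarity cutoff 0.6,
#' degronon minimum length 6, 10 random networks, 100 rank bins.
#'
#' @param outDir output directory (created if needed).
#' @param seed master seed (also fans out to per-stage streams).
#' @param inputs named list of input paths for non-synthetic runs:
#'   `degrons`, `mitab`, `disorderDir`, `obo`, `gaf`, `blacklist`,
#'   `paxdbDir`, `modules`, `edges`, `halflife`, `coexpr`, `motifs`.
#'   When `NULL` (default) the simulate stage must provide them.
#' @param synth a [synthConfig()] for the simulate stage (defaults to
#'   `synthConfig(seed = seed)`).
#' @param minConfidence,window,disorderThreshold,minIdrRun,semsimCutoff,
#'   degrononMinLength,nRandom,nBins analysis thresholds (see above).
#' @return classed list `degronon_pipeline_config`.
#' @export
pipelineConfig <- function(outDir, seed = 1L, inputs = NULL, synth = NULL,
                           minConfidence = 0.3, window = 10,
                           disorderThreshold = 0.5, minIdrRun = 20,
                           semsimCutoff = 0.6, degrononMinLength = 6,
                           nRandom = 10, nBins = 100) {
  for (nm in c("minConfidence", "window", "disorderThreshold", "minIdrRun",
               "semsimCutoff", "degrononMinLength", "nRandom", "nBins")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stopConfig("threshold %s must be a positive scalar", nm)
  }
  if (is.null(synth)) synth <- synthConfig(seed = seed)
  structure(list(outDir = outDir, seed = as.integer(seed), inputs = inputs,
                 synth = synth, minConfidence = minConfidence,
                 window = window, disorderThreshold = disorderThreshold,
                 minIdrRun = minIdrRun, semsimCutoff = semsimCutoff,
                 degrononMinLength = degrononMinLength, nRandom = nRandom,
                 nBins = nBins),
            class = "degronon_pipeline_config")
}

.stageOrder <- c("simulate", "mask", "semsim", "abundance", "network")

.provenance <- function(cfg) {
  plain <- unclass(cfg)
  plain$synth <- unclass(plain$synth)
  list(schema_version = "1.0",
       package_version = as.character(utils::packageVersion("degronon")),
       seed = cfg$seed,
       config = plain,
       config_hash = rlang::hash(plain))
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Runs the requested stages in dependency order
#' (simulate -> mask -> semsim -> abundance -> network). Each stage writes
#' its tables and a JSON report carrying provenance (config, config hash,
#' seed, package version); reruns with the same config are byte-identical.
#' A stage whose upstream outputs are missing raises a dependency error
#' naming the stage.
#'
#' @param cfg a [pipelineConfig()].
#' @param stages subset of
#'   `c("simulate", "mask", "semsim", "abundance", "network")`.
#' @return (invisibly) named list of stage result objects.
#' @export
runPipeline <- function(cfg, stages = .stageOrder) {
  if (!inherits(cfg, "degronon_pipeline_config"))
    stopInput("cfg must come from pipelineConfig()")
  stages <- match.arg(stages, .stageOrder, several.ok = TRUE)
  stages <- .stageOrder[.stageOrder %in% stages]
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  synthDir <- file.path(cfg$outDir, "synthetic")
  paths <- if (!is.null(cfg$inputs)) cfg$inputs else list(
    degrons = file.path(synthDir, "degrons.tsv"),
    mitab = file.path(synthDir, "interactions.mitab.tsv"),
    disorderDir = file.path(synthDir, "disorder"),
    obo = file.path(synthDir, "ontology.obo"),
    gaf = file.path(synthDir, "annotations.gaf.tsv"),
    blacklist = file.path(synthDir, "ups_blacklist.txt"),
    paxdbDir = file.path(synthDir, "paxdb"),
    modules = file.path(synthDir, "modules.json"),
    edges = file.path(synthDir, "network_edges.tsv"),
    halflife = file.path(synthDir, "halflives.tsv"),
    coexpr = file.path(synthDir, "coexpression.tsv"),
    motifs = file.path(synthDir, "motifs.tsv"))
  needFiles <- function(stage, keys) {
    for (k in keys) {
      p <- paths[[k]]
      if (is.null(p) || !file.exists(p))
        stopDependency("stage '%s' requires missing input '%s' (%s); run upstream stages first",
                       stage, k, if (is.null(p)) "unset" else p)
    }
  }
  results <- list()
  message(sprintf("[degronon] running stages: %s",
                  paste(stages, collapse = ", ")))

  if ("simulate" %in% stages) {
    dir.create(synthDir, recursive = TRUE, showWarnings = FALSE)
    sub <- simulateSubstrates(cfg$synth)
    inter <- simulateInteractions(cfg$synth, sub$substrates, sub$degrons,
                                  window = cfg$window)
    goa <- simulateGoAnnotations(cfg$synth)
    motifs <- simulateMotifs(cfg$synth, sub$substrates, sub$degrons,
                             window = cfg$window)
    roles <- c(
      setNames(rep("substrate", nrow(sub$substrates)),
               sub$substrates$substrate_id),
      setNames(rep("e3", nrow(sub$substrates)),
               sprintf("%s_E3", sub$substrates$substrate_id)),
      setNames(rep("ap", nrow(inter$recoverablePairs)),
               inter$recoverablePairs$partner_id))
    roles <- roles[!duplicated(names(roles))]
    datasets <- simulateAbundanceDatasets(cfg$synth, roles)
    netw <- simulateCodegradationNetwork(cfg$synth)
    writeDegronTable(sub$degrons, paths$degrons)
    writeMitab(inter$records, paths$mitab)
    writeDisorderProfiles(sub$profiles, paths$disorderDir)
    writeObo(goa$dag, paths$obo)
    writeGaf(goa$gaf, paths$gaf)
    writeLines(goa$blacklist, paths$blacklist)
    dir.create(paths$paxdbDir, showWarnings = FALSE)
    for (ds in datasets)
      writePaxdb(ds, file.path(paths$paxdbDir,
                               paste0(datasetId(ds), ".tsv")))
    .writeJson(lapply(inter$modules, unclass), paths$modules)
    writeEdgeList(netw$network, paths$edges)
    writeHalfLives(netw$halflives, paths$halflife)
    writeCoexpression(netw$coexpression, paths$coexpr)
    writeMotifTable(motifs, paths$motifs)
    truth <- list(
      masking_pairs = inter$maskingPairs,
      recoverable_pairs = inter$recoverablePairs,
      tertiary = sub$truth,
      membership = as.list(netw$truth$membership),
      planted_paths = netw$truth$plantedPaths)
    .writeJson(truth, file.path(synthDir, "ground_truth.json"))
    results$simulate <- list(paths = paths, truth = truth)
  }

  if ("mask" %in% stages) {
    needFiles("mask", c("degrons", "mitab", "disorderDir", "obo", "gaf",
                        "blacklist"))
    degrons <- readDegronTable(paths$degrons)
    records <- readMitab(paths$mitab)
    profiles <- readDisorderProfiles(paths$disorderDir)
    dag <- readObo(paths$obo)
    ann <- filterAnnotations(readGaf(paths$gaf), dag)
    blacklist <- readLines(paths$blacklist)
    ## infer tertiary degrons for substrates lacking one
    ub <- degrons[degrons$degron_class == "secondary", , drop = FALSE]
    haveTert <- unique(degrons$substrate_id[
      degrons$degron_class == "tertiary"])
    inferred <- list()
    for (i in seq_len(nrow(ub))) {
      sid <- ub$substrate_id[[i]]
      if (sid %in% haveTert || is.null(profiles[[sid]])) next
      tt <- inferTertiaryDegron(profiles[[sid]], ub$ubsite[[i]],
                                minRun = cfg$minIdrRun,
                                threshold = cfg$disorderThreshold)
      if (!is.null(tt))
        inferred[[length(inferred) + 1L]] <- data.frame(
          substrate_id = sid, degron_class = "tertiary", start = tt$start,
          end = tt$end, sequence = NA, ubsite = NA, provenance = "inferred",
          stringsAsFactors = FALSE)
    }
    if (length(inferred))
      degrons <- rbind(degrons, do.call(rbind, inferred))
    filtered <- filterInteractionRecords(records, cfg$minConfidence)
    partners <- unique(filtered$partner_id)
    kept <- filterUpsPartners(partners, ann, blacklist, dag)
    filtered <- filtered[filtered$partner_id %in% kept, , drop = FALSE]
    cens <- maskingCensus(filtered, degrons, window = cfg$window)
    motifCens <- if (!is.null(paths$motifs) && file.exists(paths$motifs))
      motifCategoryCensus(readMotifTable(paths$motifs), degrons,
                          window = cfg$window) else NULL
    maskDir <- file.path(cfg$outDir, "mask")
    dir.create(maskDir, showWarnings = FALSE)
    .writeTsv(cens$census, file.path(maskDir, "masking_census.tsv"))
    .writeTsv(cens$maskingPairs, file.path(maskDir, "masking_pairs.tsv"))
    if (!is.null(motifCens))
      .writeTsv(motifCens, file.path(maskDir, "motif_census.tsv"))
    .writeJson(c(.provenance(cfg),
                 list(n_substrates = nrow(cens$census),
                      n_masking_pairs = nrow(cens$maskingPairs),
                      removed_ups_partners =
                        as.list(attr(kept, "removed")),
                      segment_lengths = cens$segmentLengths)),
               file.path(maskDir, "mask_report.json"))
    results$mask <- c(cens, list(motifCensus = motifCens))
  }

  if ("semsim" %in% stages) {
    needFiles("semsim", c("obo", "gaf", "edges"))
    dag <- readObo(paths$obo)
    ann <- filterAnnotations(readGaf(paths$gaf), dag)
    net <- readEdgeList(paths$edges)
    simFun <- makeGeneSimilarity(ann, dag)
    ed <- networkEdges(net)
    sims <- vapply(seq_len(nrow(ed)), function(i)
      simFun(ed$a[[i]], ed$b[[i]]), 1)
    semDir <- file.path(cfg$outDir, "semsim")
    dir.create(semDir, showWarnings = FALSE)
    pairTab <- data.frame(a = ed$a, b = ed$b, semsim = sims,
                          stringsAsFactors = FALSE)
    .writeTsv(pairTab, file.path(semDir, "edge_semsim.tsv"))
    .writeJson(c(.provenance(cfg),
                 list(n_pairs = nrow(pairTab),
                      n_annotated = sum(!is.na(sims)))),
               file.path(semDir, "semsim_report.json"))
    results$semsim <- list(pairs = pairTab)
  }

  if ("abundance" %in% stages) {
    needFiles("abundance", c("paxdbDir", "modules"))
    datasets <- readPaxdbDir(paths$paxdbDir)
    modRaw <- jsonlite::read_json(paths$modules, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
    modules <- lapply(modRaw, function(m)
      regulatoryModule(m$substrate, unlist(m$e3s), unlist(m$aps)))
    comp <- roleAbundanceComparison(datasets, modules)
    corE3 <- substratePartnerCorrelation(modules, datasets, "per_e3")
    corAp <- substratePartnerCorrelation(modules, datasets, "summed_aps")
    heat <- moduleRankHeatmap(modules, datasets)
    abDir <- file.path(cfg$outDir, "abundance")
    dir.create(abDir, showWarnings = FALSE)
    heatDf <- data.frame(protein = rownames(heat), heat,
                         check.names = FALSE)
    .writeTsv(heatDf, file.path(abDir, "rank_heatmap.tsv"))
    .writeTsv(comp$tests, file.path(abDir, "role_tests.tsv"))
    .writeJson(c(.provenance(cfg),
                 list(n = as.list(comp$n),
                      medians = as.list(comp$medians),
                      substrate_e3_spearman = corE3[c("r", "p", "n")],
                      substrate_summed_ap_spearman =
                        corAp[c("r", "p", "n")])),
               file.path(abDir, "abundance_report.json"))
    results$abundance <- list(comparison = comp, perE3 = corE3,
                              summedAps = corAp, heatmap = heat)
  }

  if ("network" %in% stages) {
    needFiles("network", c("edges", "halflife", "coexpr"))
    semPath <- file.path(cfg$outDir, "semsim", "edge_semsim.tsv")
    if (!is.null(cfg$inputs) && !is.null(cfg$inputs$semsim))
      semPath <- cfg$inputs$semsim
    if (!file.exists(semPath))
      stopDependency("stage 'network' requires semsim outputs (%s); run the semsim stage first",
                     semPath)
    net <- readEdgeList(paths$edges)
    hlt <- readHalfLives(paths$halflife)
    coexpr <- readCoexpression(paths$coexpr)
    semTab <- read.delim(semPath, stringsAsFactors = FALSE)
    pr <- buildPairRecords(net, hlt, semsim = semTab,
                           coexpression = coexpr)
    dist <- ratioDistributionVsRandom(net, hlt, nRandom = cfg$nRandom,
                                      seed = cfg$seed)
    prof <- shortestPathRatioProfile(net, hlt)
    ## degronon detection needs similarity beyond edges: recompute lazily
    ## from ontology when available, else fall back to the edge table
    simSrc <- if (!is.null(paths$obo) && file.exists(paths$obo) &&
                  !is.null(paths$gaf) && file.exists(paths$gaf)) {
      dag <- readObo(paths$obo)
      makeGeneSimilarity(filterAnnotations(readGaf(paths$gaf), dag), dag)
    } else semTab
    deg <- detectDegronons(net, hlt, simSrc, cutoff = cfg$semsimCutoff,
                           minLength = cfg$degrononMinLength)
    corr <- degreeHalflifeCorrelation(net, hlt)
    netDir <- file.path(cfg$outDir, "network")
    dir.create(netDir, showWarnings = FALSE)
    .writeTsv(pr$pairs, file.path(netDir, "pair_records.tsv"))
    .writeTsv(data.frame(bin_upper = dist$breaks[-1],
                         observed = dist$observed,
                         random_mean = dist$randomMean,
                         random_sd = dist$randomSd),
              file.path(netDir, "ratio_distribution.tsv"))
    .writeJson(c(.provenance(cfg), list(
      path_tiebreak = "lexicographically smallest next node",
      halflife_dataset = hlt@datasetTag,
      group_sizes = as.list(as.integer(pr$groupSizes)),
      category_fractions = as.list(dist$categoryFractions),
      random_category_mean = as.list(dist$randomCategoryMean),
      random_category_sd = as.list(dist$randomCategorySd),
      profile_medians = as.list(prof$medians),
      degronons = lapply(deg$degronons, function(d)
        d[c("members", "length", "semsimToFirst", "ratioToFirst")]),
      n_ordered_paths = deg$nOrderedPaths,
      n_reverse_deduped = deg$nReverseDeduped,
      degree_halflife = corr$degree)),
      file.path(netDir, "network_report.json"))
    results$network <- list(pairs = pr, distribution = dist,
                            profile = prof, degronons = deg,
                            degreeCorrelation = corr)
  }
  invisible(results)
}

#' Write a consolidated report bundle
#'
#' Serializes a named list of stage results to a versioned JSON report
#' plus one TSV per tabular component (every figure-style output has its
#' underlying table emitted).
#'
#' @param results named list as returned by [runPipeline()].
#' @param dir output directory.
#' @param cfg the [pipelineConfig()] used (for provenance); optional.
#' @return (invisibly) the report path.
#' @export
writeReport <- function(results, dir, cfg = NULL) {
  if (!length(results)) stopInput("no stage results to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- if (is.null(cfg)) list(schema_version = "1.0") else
    .provenance(cfg)
  summary <- list(stages = names(results))
  if (!is.null(results$mask))
    summary$n_masking_pairs <- nrow(results$mask$maskingPairs)
  if (!is.null(results$network))
    summary$n_degronons <- length(results$network$degronons$degronons)
  .writeJson(c(meta, summary), file.path(dir, "report.json"))
  if (!is.null(results$mask))
    .writeTsv(results$mask$census, file.path(dir, "masking_census.tsv"))
  if (!is.null(results$network))
    .writeTsv(results$network$pairs$pairs,
              file.path(dir, "pair_records.tsv"))
  invisible(file.path(dir, "report.json"))
}

#' Round-trip reader for degronon reports
#'
#' @param path path to a JSON report written by the pipeline.
#' @return the parsed report list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
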