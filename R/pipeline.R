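# End-to-end workflow driver: simulate -> similarity -> train -> predict ->
# evaluate -> cluster-analysis, from a single configuration.

.readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the prediction workflow
#'
#' Executes the requested stages in order from one configuration (a list,
#' or a path to a YAML/JSON file). Supported stages:
#' \describe{
#'   \item{simulate}{generate a synthetic dataset and write it to
#'     \code{outDir/data}.}
#'   \item{similarity}{build S_m and S_l per the configured kinds/indices
#'     and write them.}
#'   \item{train}{train the ranking model; write a JSON checkpoint.}
#'   \item{predict}{write top-k ranking lists for every miRNA.}
#'   \item{evaluate}{run k-fold or LOOCV evaluation; write a per-fold
#'     report.}
#'   \item{cluster-analysis}{write the observed-vs-unobserved cluster
#'     similarity report.}
#' }
#' Configuration keys: \code{seed}, \code{outDir}, \code{stages},
#' \code{preset} ("small" or "reference") or generator fields under
#' \code{generator}; input paths under \code{inputs} (\code{interactions},
#' \code{mirnaExpression}, \code{lncrnaExpression}, \code{mirnaTargets},
#' \code{lncrnaTargets}, \code{mirnaSequences}, \code{lncrnaSequences});
#' model fields under \code{model} (passed to [bprParams()]); similarity
#' fields \code{kindMirna}, \code{kindLncrna}, \code{indexMirna},
#' \code{indexLncrna}; evaluation fields under \code{evaluation}
#' (\code{scheme}, \code{k}, \code{repeats}); \code{topK} for predict.
#' All referenced input files are checked before any stage runs. Every
#' output directory gains a \code{run_info.json} stamped with the seed and
#' a digest of the configuration.
#'
#' @param config list or path to a YAML/JSON config file.
#' @return invisibly, a list of the in-memory artifacts produced.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- .readConfigFile(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 7L)
  outDir <- config$outDir %||% stop("config must name an 'outDir'")
  stages <- config$stages %||%
    c("simulate", "similarity", "train", "predict", "evaluate",
      "cluster-analysis")
  known <- c("simulate", "similarity", "train", "predict", "evaluate",
             "cluster-analysis")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))

  # pre-flight: every referenced input must exist before any work starts
  inputs <- config$inputs %||% list()
  paths <- as.character(unlist(inputs))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  stampFile <- file.path(outDir, "config_stamp.json")
  writeLines(cfgJson, stampFile)
  jsonlite::write_json(
    list(seed = seed, configDigest = unname(tools::md5sum(stampFile)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(outDir, "run_info.json"), auto_unbox = TRUE)

  art <- list()

  if ("simulate" %in% stages) {
    gen <- config$generator %||% list()
    cfg <- if (identical(config$preset, "reference"))
      referenceScaleConfig(seed = seed)
    else do.call(syntheticConfig, c(gen, list(seed = seed)))
    art$data <- generateSyntheticData(cfg)
    writeSyntheticData(art$data, file.path(outDir, "data"))
  } else {
    if (is.null(inputs$interactions))
      stop("without the simulate stage, 'inputs$interactions' is required")
    art$data <- list(
      network = readInteractions(inputs$interactions),
      mirnaExpression = if (!is.null(inputs$mirnaExpression))
        readExpressionProfiles(inputs$mirnaExpression),
      lncrnaExpression = if (!is.null(inputs$lncrnaExpression))
        readExpressionProfiles(inputs$lncrnaExpression),
      mirnaTargets = if (!is.null(inputs$mirnaTargets))
        readTargetGenes(inputs$mirnaTargets),
      lncrnaTargets = if (!is.null(inputs$lncrnaTargets))
        readTargetGenes(inputs$lncrnaTargets),
      mirnaSequences = if (!is.null(inputs$mirnaSequences))
        readSequences(inputs$mirnaSequences),
      lncrnaSequences = if (!is.null(inputs$lncrnaSequences))
        readSequences(inputs$lncrnaSequences))
  }
  net <- art$data$network

  if (any(c("similarity", "train", "predict", "evaluate") %in% stages)) {
    art$sims <- selectSimilarity(
      net,
      kindMirna = config$kindMirna %||% "function",
      kindLncrna = config$kindLncrna %||% "expression",
      mirnaExpression = art$data$mirnaExpression,
      lncrnaExpression = art$data$lncrnaExpression,
      mirnaTargets = art$data$mirnaTargets,
      lncrnaTargets = art$data$lncrnaTargets,
      mirnaSequences = art$data$mirnaSequences,
      lncrnaSequences = art$data$lncrnaSequences,
      indexMirna = config$indexMirna %||% "AA",
      indexLncrna = config$indexLncrna %||% "SA")
    if ("similarity" %in% stages) {
      writeSimilarityMatrix(art$sims$Sm, file.path(outDir, "sim_mirna.tsv"))
      writeSimilarityMatrix(art$sims$Sl, file.path(outDir, "sim_lncrna.tsv"))
    }
  }

  params <- do.call(bprParams,
                    c(config$model %||% list(), list(seed = seed)))

  if (any(c("train", "predict") %in% stages)) {
    art$model <- trainGroupBPR(net, art$sims$Sm, art$sims$Sl,
                               params = params)
    writeModel(art$model, file.path(outDir, "model.json"))
  }

  if ("predict" %in% stages) {
    topK <- as.integer(config$topK %||% 50L)
    ranks <- do.call(rbind, lapply(mirnaIds(net), function(m)
      rankCandidates(art$model, net, art$sims$Sm, art$sims$Sl, m, topK)))
    art$rankings <- writeRankingLists(ranks, topK,
                                      file.path(outDir, "rankings.tsv"))
  }

  if ("evaluate" %in% stages) {
    ev <- config$evaluation %||% list()
    scheme <- ev$scheme %||% "kfold"
    art$cv <- if (identical(scheme, "loocv"))
      loocv(net, art$sims$Sm, art$sims$Sl, params = params, seed = seed)
    else kfoldCV(net, art$sims$Sm, art$sims$Sl, params = params,
                 k = as.integer(ev$k %||% 5L),
                 repeats = as.integer(ev$repeats %||% 1L), seed = seed)
    rep <- data.frame(fold = seq_along(foldAUCs(art$cv)),
                      auc = foldAUCs(art$cv))
    rep <- rbind(rep, data.frame(fold = NA, auc = meanAUC(art$cv)))
    utils::write.table(rep, file.path(outDir, "evaluation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("cluster-analysis" %in% stages) {
    sims <- art$sims %||% NULL
    simSide <- if (!is.null(sims)) sims$Sl else
      stop("cluster-analysis requires the similarity stage")
    art$cluster <- clusterPCCAnalysis(net, simSide, side = "lncrna")
    writeClusterReport(art$cluster, file.path(outDir, "cluster_report.tsv"))
  }

  invisible(art)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
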