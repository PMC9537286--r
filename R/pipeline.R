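# Orchestration of the three study tasks (subtype classification,
# gene-signature surrogates, prognostic signature combination) with a
# validated configuration, seeded reproducibility and plain-file artifacts
# between stages.

pipelineDefaults <- function() {
  list(
    task = "all",
    outdir = "pipeline_out",
    seed = 1L,
    simulate = list(nDiscovery = 122L, nValidation = 84L, images = TRUE),
    extract = list(nBins = 32L),
    stability = list(threshold = 0.75),
    harmonise = list(kRange = 2:6, nResamples = 100L, subsampleFrac = 0.8),
    modeling = list(reps = 33L, folds = 3L, horizon = 24),
    metagenes = list(keep = c("HALLMARK_HEDGEHOG_SIGNALING",
                              "HALLMARK_E2F_TARGETS"))
  )
}

#' Validate a pipeline configuration
#'
#' Merges user settings over the defaults; unknown top-level keys are
#' rejected.
#'
#' @param config list or path to a YAML file.
#' @return validated config list of class "PipelineConfig".
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(def[[nm]]))
      blockOk <- nm %in% c("simulate")   # simulate mirrors cohortConfig
      if (length(bad) && !blockOk)
        stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  tasks <- c("simulate", "extract", "stability", "harmonise", "subtype",
             "surrogate", "prognose", "evaluate", "all")
  if (!def$task %in% tasks)
    stop("task must be one of: ", paste(tasks, collapse = ", "))
  structure(def, class = "PipelineConfig")
}

md5OfFiles <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

stageSimulate <- function(cfg) {
  args <- cfg$simulate
  args$seed <- args$seed %||% cfg$seed
  cohort <- generateCohort(do.call(cohortConfig, args))
  writeCohort(cohort, file.path(cfg$outdir, "cohort"))
  cohort
}

stageExtract <- function(cfg, cohort) {
  stopifnot(length(cohort@volumes) > 0)
  X <- extractFeatureTable(cohort@volumes, cohort@masks,
                           preprocessConfig(nBins = cfg$extract$nBins))
  writeFeatureTable(X, file.path(cfg$outdir, "features"))
  X
}

stageStability <- function(cfg, cohort, features) {
  clin <- clinicalTable(cohort)
  ids <- intersect(clin$id[clin$split == "discovery"],
                   names(cohort@volumes))
  pc <- preprocessConfig(nBins = cfg$extract$nBins)
  arrs <- list()
  for (id in ids) {
    rs <- resampleIsotropic(cohort@volumes[[id]], cohort@masks[[id]],
                            pc$targetSpacing)
    variants <- augmentImage(rs$volume, rs$mask)
    # the LoG response depends on the image only: compute once per rotation
    logCache <- list()
    rows <- lapply(variants, function(v) {
      key <- as.character(v$rotation)
      if (is.null(logCache[[key]]))
        logCache[[key]] <<- logFilterBank(v$volume, pc$logSigmas)
      m2 <- resegmentIntensity(v$volume, v$mask, pc$huWindow)
      extractFeatures(v$volume, m2, logVol = logCache[[key]], cfg = pc)
    })
    arrs[[id]] <- do.call(rbind, rows)
  }
  nv <- min(vapply(arrs, nrow, integer(1)))
  feats <- colnames(arrs[[1]])
  A <- array(NA_real_, c(length(ids), nv, length(feats)),
             dimnames = list(ids, NULL, feats))
  for (i in seq_along(ids)) A[i, , ] <- arrs[[ids[i]]][seq_len(nv), ]
  rep <- stabilityFilter(A, cfg$stability$threshold)
  utils::write.csv(rep, file.path(cfg$outdir, "stability_report.csv"),
                   row.names = FALSE)
  # the GTV volume is a forced clinical covariate downstream; the volume
  # augmentation perturbs it by construction, so it bypasses the filter
  keep <- union(rep$feature[rep$retained], "morph_volume")
  md <- attr(features, "metadata")
  out <- features[, intersect(colnames(features), keep), drop = FALSE]
  attr(out, "metadata") <- md[md$feature %in% colnames(out), ]
  out
}

stageHarmonise <- function(cfg, cohort, features) {
  md <- attr(features, "metadata")
  fams <- c("statistical", "intensity_histogram", "texture")
  sel <- if (!is.null(md))
    intersect(colnames(features),
              md$feature[md$family %in% fams & md$image == "base"])
  else colnames(features)
  rc <- referenceCluster(features[, sel, drop = FALSE],
                         kRange = cfg$harmonise$kRange,
                         nResamples = cfg$harmonise$nResamples,
                         subsampleFrac = cfg$harmonise$subsampleFrac,
                         seed = deriveSeed(cfg$seed, "refclust"))
  if (length(rc$outliers) >= 2L) {
    batch <- ifelse(rownames(features) %in% rc$reference, "reference",
                    "outlier")
    adj <- combatAdjust(features, batch, "reference", "nonparametric")
  } else adj <- features
  jsonlite::write_json(list(reference = rc$reference,
                            outliers = rc$outliers),
                       file.path(cfg$outdir, "harmonisation.json"),
                       auto_unbox = TRUE)
  # expression: centre batches aligned to the first batch
  clin <- clinicalTable(cohort)
  exprAdj <- cohort@expression
  if (length(unique(clin$batch)) > 1L && min(table(clin$batch)) >= 2L)
    exprAdj <- t(combatAdjust(t(cohort@expression), clin$batch,
                              clin$batch[1], "nonparametric"))
  attr(adj, "metadata") <- md
  list(features = adj, expression = exprAdj)
}

buildClassifier <- function(Xdisc, yDisc, positiveClass, cfg, seed) {
  cr <- clusterRepresentatives(Xdisc)
  tp <- fitTransforms(Xdisc[, cr$representatives, drop = FALSE])
  Zd <- applyTransforms(Xdisc, tp)
  rk <- cvRankAggregate(Zd, y = yDisc, task = "classification",
                        reps = cfg$modeling$reps, folds = cfg$modeling$folds,
                        seed = seed)
  feats <- rk$ranking$feature[seq_len(min(rk$medianSize,
                                          nrow(rk$ranking)))]
  model <- fitLogisticOva(Zd[, feats, drop = FALSE], yDisc, positiveClass,
                          transforms = tp[tp$feature %in% feats, ],
                          seed = seed)
  model@provenance$ranking <- rk$ranking
  model@provenance$median_size <- rk$medianSize
  model
}

evalClassifier <- function(model, X, y, cutoff = NULL, seed = 1L) {
  pr <- predictModel(model, X)
  pos <- model@provenance$positive_class
  yb <- as.integer(y == pos)
  auc <- rocAuc(pr, yb, seed = seed)
  f1 <- if (is.null(cutoff))
    f1WithCutoff(pr, yb, "fit", seed = seed)
  else f1WithCutoff(pr, yb, "apply", cutoff = cutoff, seed = seed)
  hl <- tryCatch(hosmerLemeshow(pr, yb), error = function(e) NULL)
  list(auc = auc, f1 = f1, hl = hl)
}

stageSubtype <- function(cfg, cohort, features, expression) {
  clin <- clinicalTable(cohort)
  sub <- assignSubtypes(expression, cohort@centroids)
  utils::write.csv(data.frame(id = rownames(sub), sub),
                   file.path(cfg$outdir, "subtypes.csv"),
                   row.names = FALSE)
  ids <- intersect(rownames(features), clin$id)
  lab <- sub[ids, "label"]
  split <- clin$split[match(ids, clin$id)]
  keepPt <- lab != "unclassified" | TRUE    # OVA uses all labelled patients
  out <- list(assignments = sub, models = list(), evaluation = list())
  for (st in c("atypical", "basal", "classical", "mesenchymal")) {
    yAll <- ifelse(lab == st, st, "other")
    d <- split == "discovery"
    if (length(unique(yAll[d])) < 2L || sum(yAll == st & d) < 5L) next
    model <- buildClassifier(features[ids[d], , drop = FALSE], yAll[d], st,
                             cfg, deriveSeed(cfg$seed, paste0("sub-", st)))
    evD <- evalClassifier(model, features[ids[d], , drop = FALSE], yAll[d],
                          seed = deriveSeed(cfg$seed, "evd"))
    model@cutoff <- evD$f1$cutoff
    v <- split == "validation"
    evV <- if (length(unique(yAll[v])) == 2L)
      evalClassifier(model, features[ids[v], , drop = FALSE], yAll[v],
                     cutoff = evD$f1$cutoff,
                     seed = deriveSeed(cfg$seed, "evv")) else NULL
    writeModel(model, file.path(cfg$outdir,
                                paste0("model_subtype_", st, ".json")))
    out$models[[st]] <- model
    out$evaluation[[st]] <- list(discovery = evD, validation = evV)
  }
  out
}

stageSurrogate <- function(cfg, cohort, features, expression) {
  clin <- clinicalTable(cohort)
  sets <- cohort@truth$gene_sets
  sigs <- sets[grep("^SIG_", names(sets))]
  ids <- intersect(rownames(features), clin$id)
  split <- clin$split[match(ids, clin$id)]
  d <- split == "discovery"; v <- split == "validation"
  out <- list()
  for (nm in names(sigs)) {
    fitCl <- signatureClasses(expression[, ids[d], drop = FALSE],
                              sigs[[nm]], "fit",
                              seed = deriveSeed(cfg$seed, nm))
    trCl <- signatureClasses(expression[, ids[v], drop = FALSE],
                             sigs[[nm]], "transfer", fitted = fitCl)
    yD <- ifelse(fitCl$labels == 1L, "class1", "class2")
    if (length(unique(yD)) < 2L || min(table(yD)) < 5L) next
    model <- buildClassifier(features[ids[d], , drop = FALSE], yD,
                             "class1", cfg, deriveSeed(cfg$seed,
                                                       paste0("sur-", nm)))
    yV <- ifelse(trCl$labels == 1L, "class1", "class2")
    evV <- if (length(unique(yV)) == 2L)
      evalClassifier(model, features[ids[v], , drop = FALSE], yV,
                     cutoff = NULL,
                     seed = deriveSeed(cfg$seed, "sur-ev")) else NULL
    out[[nm]] <- list(model = model, classes_discovery = fitCl$labels,
                      classes_validation = trCl$labels, validation = evV)
  }
  out
}

buildCoxFromFeatures <- function(Zd, td, ed, tp, forced, cfg, seed) {
  rk <- cvRankAggregate(Zd[, setdiff(colnames(Zd), forced), drop = FALSE],
                        time = td, event = ed, task = "survival",
                        reps = cfg$modeling$reps, folds = cfg$modeling$folds,
                        horizon = cfg$modeling$horizon, seed = seed)
  feats <- union(forced,
                 rk$ranking$feature[seq_len(min(rk$medianSize,
                                                nrow(rk$ranking)))])
  model <- fitCox(Zd[, feats, drop = FALSE], td, ed, forced = forced,
                  transforms = tp[tp$feature %in% feats, ])
  model@provenance$ranking <- rk$ranking
  model
}

stagePrognose <- function(cfg, cohort, features, expression) {
  clin <- clinicalTable(cohort)
  ids <- intersect(rownames(features), clin$id)
  cl <- clin[match(ids, clin$id), ]
  d <- cl$split == "discovery"; v <- cl$split == "validation"
  Xd <- features[ids[d], , drop = FALSE]
  # radiomics signature: forced volume + volume-decorrelated features
  vol <- Xd[, "morph_volume"]
  keep <- volumeCorrelationFilter(
    Xd[, setdiff(colnames(Xd), "morph_volume"), drop = FALSE], vol)
  cr <- clusterRepresentatives(Xd[, keep, drop = FALSE])
  radFeats <- c("morph_volume", cr$representatives)
  tpRad <- fitTransforms(Xd[, radFeats, drop = FALSE])
  Zd <- applyTransforms(Xd, tpRad)
  mRad <- buildCoxFromFeatures(Zd, cl$time_months[d], cl$event[d], tpRad,
                               "morph_volume", cfg,
                               deriveSeed(cfg$seed, "cox-rad"))
  # metagenes, per cohort separately (no pooling)
  sets <- filterGeneSets(cohort@truth$gene_sets, cfg$metagenes$keep)
  mgD <- gsvaScores(expression[, ids[d], drop = FALSE], sets)
  mgV <- gsvaScores(expression[, ids[v], drop = FALSE], sets)
  tpMg <- fitTransforms(mgD)
  mMg <- fitCox(applyTransforms(mgD, tpMg), cl$time_months[d], cl$event[d],
                transforms = tpMg)
  # combined model on the union of selected features
  combRaw <- cbind(Xd[, mRad@features, drop = FALSE], mgD)
  tpComb <- fitTransforms(combRaw)
  mComb <- fitCox(applyTransforms(combRaw, tpComb), cl$time_months[d],
                  cl$event[d], forced = "morph_volume",
                  transforms = tpComb)
  # validation application
  Xv <- features[ids[v], , drop = FALSE]
  riskRadV <- predictModel(mRad, Xv)
  riskMgV <- predictModel(mMg, mgV)
  combV <- cbind(Xv[, mRad@features, drop = FALSE], mgV)
  riskCombV <- predictModel(mComb, combV)
  riskRadD <- predictModel(mRad, Xd)
  riskMgD <- predictModel(mMg, mgD)
  riskCombD <- predictModel(mComb, combRaw)
  res <- list(
    radiomics = list(model = mRad,
                     cindex_discovery = concordanceIndex(
                       riskRadD, cl$time_months[d], cl$event[d],
                       seed = cfg$seed),
                     cindex_validation = concordanceIndex(
                       riskRadV, cl$time_months[v], cl$event[v],
                       seed = cfg$seed)),
    metagene = list(model = mMg,
                    cindex_discovery = concordanceIndex(
                      riskMgD, cl$time_months[d], cl$event[d],
                      seed = cfg$seed),
                    cindex_validation = concordanceIndex(
                      riskMgV, cl$time_months[v], cl$event[v],
                      seed = cfg$seed)),
    combined = list(model = mComb,
                    cindex_discovery = concordanceIndex(
                      riskCombD, cl$time_months[d], cl$event[d],
                      seed = cfg$seed),
                    cindex_validation = concordanceIndex(
                      riskCombV, cl$time_months[v], cl$event[v],
                      seed = cfg$seed)))
  # stratification threshold fitted on discovery, applied to validation
  thr <- stratificationThreshold(riskCombD, cl$time_months[d], cl$event[d],
                                 "fit")
  res$combined$threshold <- thr$threshold
  res$combined$model@threshold <- thr$threshold
  strV <- stratificationThreshold(riskCombV, cl$time_months[v],
                                  cl$event[v], "apply",
                                  threshold = thr$threshold)
  res$combined$logrank_validation_p <- strV$p_value
  # calibration at the horizon (GND) for the combined model in validation
  sv <- predictModel(mComb, combV, horizon = cfg$modeling$horizon)
  res$combined$gnd <- tryCatch(
    gndCalibration(sv$survival, cl$time_months[v], cl$event[v],
                   horizon = cfg$modeling$horizon, g = 5L),
    error = function(e) list(p_value = NA_real_, error = conditionMessage(e)))
  for (nm in names(res))
    writeModel(res[[nm]]$model,
               file.path(cfg$outdir, paste0("model_prognosis_", nm,
                                            ".json")))
  res
}

#' Run the radiogenomics pipeline
#'
#' Executes the requested task(s) on a synthetic or on-disk cohort,
#' writing stage artifacts and a run manifest (config echo plus file
#' digests) under the configured output directory.
#'
#' @param config a \code{\link{pipelineConfig}}, plain list or YAML path.
#' @param cohort optional in-memory \linkS4class{SyntheticCohort}; when
#'   NULL the cohort is simulated (task "simulate"/"all") or read from
#'   \code{<outdir>/cohort}.
#' @return list with per-stage results and the manifest (invisibly the
#'   same list).
#' @export
runPipeline <- function(config = list(), cohort = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else pipelineConfig(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  task <- cfg$task
  res <- list(config = cfg)
  wants <- function(t) task %in% c(t, "all")
  if (is.null(cohort)) {
    cohort <- if (wants("simulate")) stageSimulate(cfg)
              else readCohort(file.path(cfg$outdir, "cohort"))
  } else if (wants("simulate")) {
    writeCohort(cohort, file.path(cfg$outdir, "cohort"))
  }
  res$cohort <- cohort
  features <- NULL
  if (wants("extract") || wants("stability") || wants("harmonise") ||
      wants("subtype") || wants("surrogate") || wants("prognose")) {
    featDir <- file.path(cfg$outdir, "features")
    features <- if (wants("extract") || !file.exists(
      file.path(featDir, "features.csv")))
      stageExtract(cfg, cohort) else readFeatureTable(featDir)
  }
  if (wants("stability"))
    features <- stageStability(cfg, cohort, features)
  expression <- cohort@expression
  if (wants("harmonise")) {
    h <- stageHarmonise(cfg, cohort, features)
    features <- h$features
    expression <- h$expression
  }
  if (wants("subtype"))
    res$subtype <- stageSubtype(cfg, cohort, features, expression)
  if (wants("surrogate"))
    res$surrogate <- stageSurrogate(cfg, cohort, features, expression)
  if (wants("prognose"))
    res$prognosis <- stagePrognose(cfg, cohort, features, expression)
  cfgPath <- file.path(cfg$outdir, "config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfgPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radiogenomix")),
    config_digest = unname(tools::md5sum(cfgPath)),
    artifacts = md5OfFiles(list.files(cfg$outdir, recursive = TRUE,
                                      full.names = TRUE,
                                      pattern = "\\.(csv|json)$")))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  res$manifest <- manifest
  invisible(res)
}
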