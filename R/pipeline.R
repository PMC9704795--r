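#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list; a run is fully reproducible from its configuration and seed.
#'
#' @param nSubjects,nNodes,nComponentsTruth cohort generation settings
#'   (ignored when \code{cohortDir} points at a serialized cohort).
#' @param cohortDir optional directory of an existing cohort written by
#'   \code{\link{writeCohort}}; \code{NULL} simulates one.
#' @param seed master seed for generation, splits and null models.
#' @param alpha edge-significance level (\code{NA} disables the surrogate
#'   masking).
#' @param nSurrogates surrogate replicates per subject.
#' @param logOffset structural log-transform offset.
#' @param interDenominator inter-strength denominator convention.
#' @param maxComponents LOO candidate depth cap.
#' @param selectAlpha component-selection level.
#' @param nNull scrambled-null replicates.
#' @param nSplits train/test split replicates.
#' @param trainFraction training fraction.
#' @param scale unit-scale predictors before PLS?
#' @return named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(nSubjects = 100L, nNodes = 100L,
                           nComponentsTruth = 2L, cohortDir = NULL,
                           seed = 1L, alpha = 0.05, nSurrogates = 199L,
                           logOffset = 1, interDenominator = "per-node",
                           maxComponents = 5L, selectAlpha = 0.01,
                           nNull = 100L, nSplits = 100L,
                           trainFraction = 0.8, scale = FALSE) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipelineConfig")
}

#' Run the full analysis pipeline into a directory
#'
#' Sequences the stages: cohort (simulate or load), cognition composite,
#' connectome construction and feature assembly, covariate residualization,
#' leave-one-out RMSEP with permutation-based component selection,
#' scrambled null models, repeated train/test splits, and profile
#' aggregation. Every stage writes plain-text artifacts into \code{outDir};
#' \code{manifest.json} records the configuration, package and R versions
#' and the MD5 hash of every written file, so a run is verifiable and two
#' runs of one configuration produce identical manifests.
#'
#' @param outDir output directory.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{cohort}, \code{cog}, \code{features}, \code{cv},
#'   \code{ncomp}, \code{nullRmsep}, \code{ensemble}, \code{profiles},
#'   \code{metrics}).
#' @export
runPipeline <- function(outDir, config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config

  # --- cohort ---------------------------------------------------------
  if (!is.null(cfg$cohortDir)) {
    parcFile <- file.path(cfg$cohortDir, "parcellation.tsv")
    if (!file.exists(parcFile))
      stop("missing parcellation file: ", parcFile)
    cohort <- readCohort(cfg$cohortDir)
  } else {
    cohort <- simulateCohort(cfg$nSubjects, nNodes = cfg$nNodes,
                             seed = cfg$seed,
                             nComponents = cfg$nComponentsTruth)
  }
  subjects <- subjectTable(cohort)
  parc <- parcellation(cohort)

  # --- cognition ------------------------------------------------------
  cogRes <- cognitionComposite(subjects)
  comp <- cogRes$composite
  keepIds <- comp@subjectIds
  subjects <- subjects[match(keepIds, subjects$subject_id), ]
  utils::write.table(
    data.frame(test = names(cogLoadings(comp)),
               loading = cogLoadings(comp)),
    file.path(outDir, "cog_loadings.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # --- connectomes and features --------------------------------------
  cohortKept <- cohort
  cohortKept@subjects <- subjects
  cohortKept@timeseries <- cohort@timeseries[keepIds]
  cohortKept@sc <- cohort@sc[keepIds]
  alpha <- if (is.na(cfg$alpha)) NULL else cfg$alpha
  fb <- cohortFeatures(cohortKept, cog = cogScores(comp)[keepIds],
                       alpha = alpha, nSurrogates = cfg$nSurrogates,
                       logOffset = cfg$logOffset,
                       interDenominator = cfg$interDenominator)
  fb <- residualize(fb)
  writeFeatureBlock(fb, file.path(outDir, "features.tsv"))

  # --- model selection ------------------------------------------------
  set.seed(cfg$seed)
  cv <- looRmsep(fb, maxComponents = cfg$maxComponents, scale = cfg$scale)
  ncomp <- selectNcomp(cv, alpha = cfg$selectAlpha)
  ncompFit <- max(ncomp, 1L)

  # --- null models ----------------------------------------------------
  set.seed(cfg$seed + 1L)
  nullR <- nullRmsep(fb, ncomp = ncompFit, nNull = cfg$nNull,
                     scale = cfg$scale)

  # --- repeated splits and profiles ----------------------------------
  ens <- repeatedSplits(fb, trainFraction = cfg$trainFraction,
                        nReps = cfg$nSplits, ncomp = ncompFit,
                        seed = cfg$seed + 2L, scale = cfg$scale)
  ens <- alignSigns(ens)
  profs <- meanLoadings(ens, subjects$age, parc = parc)
  for (pr in profs) {
    utils::write.table(
      data.frame(predictor = names(pr@predictorMeans),
                 mean = pr@predictorMeans, sd = pr@predictorSds),
      file.path(outDir, sprintf("profile_comp%d.tsv", pr@component)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      pr@networkSummary,
      file.path(outDir, sprintf("network_summary_comp%d.tsv",
                                pr@component)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # Table-shaped ensemble summary: one row per cumulative depth
  summaryTab <- data.frame(
    depth = seq_len(ncompFit),
    meanTestRmsep = colMeans(ens@testRmsep),
    sdTestRmsep = apply(ens@testRmsep, 2L, sd),
    meanTestR = colMeans(ens@testR),
    xVarianceUsed = cv@xVarianceUsed[seq_len(ncompFit)],
    yVarianceExplained = cv@yVarianceExplained[seq_len(ncompFit)])
  utils::write.table(summaryTab, file.path(outDir, "ensemble_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # frontal contrast is tested on the component with the strongest
  # structural signature
  scLoad <- vapply(profs, function(pr) {
    sel <- grepl("_SC_intra$", names(pr@predictorMeans))
    mean(abs(pr@predictorMeans[sel]))
  }, numeric(1))
  scComp <- which.max(scLoad)
  frontal <- c(list(component = scComp),
               frontalVsRestTest(profs[[scComp]], parc,
                                 family = "SC_intra"))
  ageCors <- componentAgeCorrelation(ens, subjects$age)
  metrics <- list(
    kmo = comp@kmo,
    cogExplainedVariance = comp@explainedVariance,
    corAgeCog = cor(subjects$age, cogScores(comp)[keepIds]),
    selectedComponents = ncomp,
    rmsep = as.list(rmsep(cv)),
    nullRmsepMean = mean(nullR),
    nullRmsepQ01 = unname(quantile(nullR, 0.01)),
    realRmsepAtDepth = unname(rmsep(cv)[as.character(ncompFit)]),
    componentAgeCorrelation = ageCors,
    frontalVsRest = frontal)
  writeMetrics(metrics, file.path(outDir, "metrics.json"))

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(outDir, files)))
  names(hashes) <- files
  manifest <- list(package = "agingProfiles",
                   version = as.character(utils::packageVersion("agingProfiles")),
                   rVersion = paste(R.version$major, R.version$minor, sep = "."),
                   config = unclass(cfg),
                   files = hashes)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, cog = comp, features = fb, cv = cv,
                 ncomp = ncomp, nullRmsep = nullR, ensemble = ens,
                 profiles = profs, metrics = metrics))
}

#' Restore a cohort serialized by \code{\link{writeCohort}}
#'
#' @param dir cohort directory.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
readCohort <- function(dir) {
  parcFile <- file.path(dir, "parcellation.tsv")
  if (!file.exists(parcFile)) stop("missing parcellation file: ", parcFile)
  parc <- readParcellation(parcFile)
  sub <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- makeGroundTruth(parc, nComponents = tr$nComponents,
                           ageEffectCog = tr$ageEffectCog,
                           frontalDeclineRate = tr$frontalDeclineRate,
                           otherDeclineRate = tr$otherDeclineRate,
                           noise = unlist(tr$noise))
  lat <- as.data.frame(tr$latents)
  sub <- cbind(sub, lat)
  ts <- sc <- stats::setNames(vector("list", nrow(sub)), sub$subject_id)
  for (id in sub$subject_id) {
    ts[[id]] <- readPlainMatrix(file.path(dir, sprintf("ts_%s.tsv", id)))
    rownames(ts[[id]]) <- sprintf("node%03d", nodeTable(parc)$node_id)
    sc[[id]] <- readPlainMatrix(file.path(dir, sprintf("sc_%s.tsv", id)))
    dimnames(sc[[id]]) <- rep(list(rownames(ts[[id]])), 2)
  }
  new("SyntheticCohort", subjects = sub, timeseries = ts, sc = sc,
      parcellation = parc, truth = truth,
      seed = as.integer(tr$seed))
}
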