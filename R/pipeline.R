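#' Configuration for an end-to-end experiment
#'
#' Composes every stage configuration of the two-step
#' detect-then-segment procedure. One global seed drives cohort
#' generation, the train/validation split, weight initialization,
#' shuffling and augmentation, making a full run deterministic on a given
#' platform.
#'
#' @param nSubjects cohort size, default 37.
#' @param splitFraction training fraction, default 0.70 (37 subjects give
#'   26 train / 11 validation).
#' @param seed global integer seed.
#' @param outDir output directory for per-stage artifacts, or \code{NULL}
#'   to keep everything in memory.
#' @param phantom a \code{\link{phantomSpec}}.
#' @param groundTruth a \code{\link{groundTruthConfig}}.
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param augment an \code{\link{augmentParams}} or \code{NULL} to disable
#'   augmentation.
#' @param unet a \code{\link{unetConfig}}.
#' @param train a \code{\link{trainConfig}} (its seed is re-derived from
#'   the global seed).
#' @param postprocess a \code{\link{postprocessConfig}}.
#' @param refine apply the dilation + adaptive-threshold refinement stage.
#' @return List of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(nSubjects = 37L, splitFraction = 0.70, seed = 1L,
                           outDir = NULL, phantom = phantomSpec(),
                           groundTruth = groundTruthConfig(),
                           preprocess = preprocessConfig(),
                           augment = augmentParams(), unet = unetConfig(),
                           train = trainConfig(), postprocess = postprocessConfig(),
                           refine = TRUE) {
  stopifnot(nSubjects >= 2, splitFraction > 0, splitFraction < 1)
  structure(list(nSubjects = as.integer(nSubjects),
                 splitFraction = splitFraction, seed = as.integer(seed),
                 outDir = outDir, phantom = phantom, groundTruth = groundTruth,
                 preprocess = preprocess, augment = augment, unet = unet,
                 train = train, postprocess = postprocess, refine = refine),
            class = "pipelineConfig")
}

# Reduce one phantom subject to what the learning pipeline needs:
# reference mask at native resolution, then network-space volumes.
prepareSubject <- function(subject, gtCfg, ppCfg) {
  gt <- groundTruthSegment(subject, gtCfg)
  xRaw <- resizeLinear(subject@summation, ppCfg$targetShape)
  x <- xRaw
  if (ppCfg$addGradient) x <- enhanceContours(x)
  if (ppCfg$normalize) x <- zNormalize(x)
  y <- resizeLinear(gt$mask, ppCfg$targetShape)
  list(seed = subject@seed, side = subject@lesionSide,
       backgroundMean = gt$backgroundMean,
       lesionVolumeMm3 = sum(subject@truthLesion@data) *
         prod(subject@truthLesion@spacing),
       xRaw = xRaw, x = x, y = y)
}

#' Run the full detect-then-segment experiment
#'
#' Simulates a cohort, derives the semi-automatic reference segmentation
#' of every subject, splits 70/30, preprocesses to network space, trains
#' the U-Net, predicts on the validation subjects, refines the predicted
#' masks, and evaluates voxel- and lesion-level performance. Per-stage
#' artifacts, a per-subject metrics report and a machine-readable manifest
#' are written when \code{outDir} is set.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param verbose print stage progress to stderr.
#' @return List of class \code{"experimentReport"}: \code{report} (one row
#'   per validation subject), \code{summary}, \code{history},
#'   \code{voxelMetrics}, \code{net}, \code{split}.
#' @export
runExperiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  note <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  note("stage simulate+groundtruth+preprocess: %d subjects", cfg$nSubjects)
  subjects <- generateCohort(cfg$nSubjects, cfg$phantom, cfg$seed,
                             transform = function(s)
                               prepareSubject(s, cfg$groundTruth, cfg$preprocess))

  split <- splitDataset(seq_len(cfg$nSubjects), cfg$splitFraction,
                        seed = deriveSeed(cfg$seed, 101L))

  note("stage train: %d train / %d validation subjects",
       length(split$trainIds), length(split$valIds))
  tc <- cfg$train
  tc$seed <- deriveSeed(cfg$seed, 202L)
  net <- buildUnet(cfg$unet, seed = deriveSeed(cfg$seed, 303L))
  pairs <- lapply(subjects, function(s) list(x = s$x, y = s$y))
  fit <- trainUnet(net, pairs[split$trainIds], pairs[split$valIds],
                   cfg = tc, aug = cfg$augment, verbose = verbose)

  note("stage predict+refine+evaluate")
  rows <- list()
  counts <- list()
  for (id in split$valIds) {
    s <- subjects[[id]]
    pred <- predictMask(fit$net, s$x)
    preDice <- dsc(pred$mask, s$y)
    refined <- pred$mask
    if (cfg$refine && sum(pred$mask@data) > 0)
      refined <- refineMask(pred$mask, s$xRaw, cfg$postprocess)
    postDice <- dsc(refined, s$y)
    det <- detectLesions(refined, list(s$y))
    cc <- confusionCounts(refined, s$y)
    counts[[length(counts) + 1]] <- cc
    rows[[length(rows) + 1]] <- data.frame(
      subject = id, seed = s$seed, side = s$side, set = "validation",
      backgroundMean = s$backgroundMean, lesionVolumeMm3 = s$lesionVolumeMm3,
      diceUnet = preDice, diceRefined = postDice,
      detected = det$nDetected == det$nLesions,
      falsePositiveComponents = det$nFalsePositiveComponents,
      TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN)
  }
  report <- do.call(rbind, rows)
  pooled <- poolCounts(counts)
  vm <- voxelMetrics(pooled)
  summary <- list(
    nSubjects = cfg$nSubjects, nTrain = length(split$trainIds),
    nVal = length(split$valIds), seed = cfg$seed,
    meanValDiceUnet = mean(report$diceUnet),
    meanValDiceRefined = mean(report$diceRefined),
    pooledDice = with(pooled, if (2 * TP + FP + FN > 0)
      2 * TP / (2 * TP + FP + FN) else NA_real_),
    allLesionsDetected = all(report$detected),
    totalFalsePositiveComponents = sum(report$falsePositiveComponents),
    Se = vm$Se, Sp = vm$Sp, PPV = vm$PPV, NPV = vm$NPV,
    ci95 = vm$ci95,
    finalTrainDice = utils::tail(fit$history$trainDice, 1),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(report = report, summary = summary, history = fit$history,
              voxelMetrics = vm, net = fit$net, split = split)
  class(out) <- "experimentReport"

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(cfg$outDir, "report.csv"), row.names = FALSE)
    write.csv(fit$history, file.path(cfg$outDir, "history.csv"),
              row.names = FALSE)
    manifest <- list(
      seed = cfg$seed, nSubjects = cfg$nSubjects,
      trainIds = split$trainIds, valIds = split$valIds,
      config = list(
        phantom = unclass(cfg$phantom), groundTruth = unclass(cfg$groundTruth),
        preprocess = unclass(cfg$preprocess),
        augment = if (is.null(cfg$augment)) NULL else unclass(cfg$augment),
        unet = unclass(cfg$unet), train = unclass(tc),
        postprocess = unclass(cfg$postprocess)),
      nParameters = networkParameterCount(fit$net),
      summary = summary[setdiff(names(summary), "elapsedSec")],
      package = as.character(utils::packageVersion("fetseg")))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveUnet(fit$net, file.path(cfg$outDir, "model"))
  }
  out
}

#' @export
print.experimentReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Experiment (seed %d): %d subjects, %d train / %d validation\n",
              s$seed, s$nSubjects, s$nTrain, s$nVal))
  cat(sprintf("  mean validation Dice: %.4f (U-Net) -> %.4f (refined)\n",
              s$meanValDiceUnet, s$meanValDiceRefined))
  cat(sprintf("  detection: %d/%d lesions, %d false-positive components\n",
              sum(x$report$detected), nrow(x$report),
              s$totalFalsePositiveComponents))
  cat(sprintf("  voxel level: Se %.3f Sp %.3f PPV %.3f NPV %.3f\n",
              s$Se, s$Sp, s$PPV, s$NPV))
  invisible(x)
}
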