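#' @include training.R inference.R evaluation.R io.R phantom.R
NULL

#' Unified pipeline configuration
#'
#' Bundles the per-stage configurations plus the TTA switch and the single
#' master seed through which all pipeline randomness is funnelled.
#' Validates every nested configuration and rejects unknown keys.
#'
#' @param preprocess A [preprocessConfig()].
#' @param agnet An [agnetConfig()].
#' @param train A [trainConfig()].
#' @param postprocess A [postprocessConfig()].
#' @param tta Logical: use test-time augmentation at inference.
#' @param patchSize Integer length-3 inference patch shape.
#' @param stride Optional inference stride (default half the patch).
#' @param seed Master seed.
#' @return Named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(),
                           agnet = agnetConfig(),
                           train = trainConfig(),
                           postprocess = postprocessConfig(),
                           tta = TRUE,
                           patchSize = c(160L, 160L, 16L),
                           stride = NULL,
                           seed = 1L) {
  stopifnot(inherits(preprocess, "PreprocessConfig"),
            inherits(agnet, "AGNetConfig"),
            inherits(train, "TrainConfig"),
            inherits(postprocess, "PostprocessConfig"))
  structure(list(preprocess = preprocess, agnet = agnet, train = train,
                 postprocess = postprocess,
                 tta = .assertFlag(tta, "tta"),
                 patchSize = as.integer(rep(patchSize, length.out = 3L)),
                 stride = if (is.null(stride)) NULL
                   else as.integer(rep(stride, length.out = 3L)),
                 seed = .assertCount(seed, "seed")),
            class = "PipelineConfig")
}

.configBuilders <- list(preprocess = preprocessConfig, agnet = agnetConfig,
                        train = trainConfig, postprocess = postprocessConfig)

#' Write a pipeline configuration to YAML
#' @param cfg A [pipelineConfig()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  x <- lapply(cfg, function(v) if (is.list(v)) unclass(v) else v)
  x$preprocess$cropSize <- as.integer(x$preprocess$cropSize)
  x$agnet <- x$agnet
  x$train$seed <- as.integer(x$train$seed)
  x$postprocess <- x$postprocess
  x$tissues <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys anywhere in the file are an error; every nested
#' configuration is rebuilt through its constructor so all invariants are
#' re-checked on load. Load and dump round-trip to the same
#' configuration.
#'
#' @param path YAML file written by [writePipelineConfig()] (or by hand).
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  topKnown <- c(names(.configBuilders), "tta", "patchSize", "stride", "seed")
  if (length(bad <- setdiff(names(x), topKnown)) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  args <- list()
  for (nm in names(.configBuilders)) {
    if (is.null(x[[nm]])) next
    builder <- .configBuilders[[nm]]
    known <- names(formals(builder))
    if (length(bad <- setdiff(names(x[[nm]]), known)) > 0)
      stop("unknown keys in '", nm, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    args[[nm]] <- do.call(builder, x[[nm]])
  }
  args$tta <- x$tta %||% TRUE
  args$patchSize <- x$patchSize %||% c(160L, 160L, 16L)
  args$stride <- x$stride
  args$seed <- x$seed %||% 1L
  do.call(pipelineConfig, args)
}

#' Segment one preprocessed-ready CT volume end to end
#'
#' Convenience wrapper used by [runPipeline()]: soft-tissue windowing,
#' central crop, (TTA) sliding-window inference, uncropping back to the
#' original grid, and postprocessing against the original HU volume.
#'
#' @param ct A [CTVolume-class] in HU.
#' @param model A trained [AGNetModel-class].
#' @param cfg A [pipelineConfig()].
#' @return List with `pred` ([LabelVolume-class] on the original grid),
#'   `probs` (cropped-grid [ProbabilityVolume-class]) and `report` (the
#'   postprocessing component report).
#' @export
segmentVolume <- function(ct, model, cfg = pipelineConfig()) {
  stopifnot(is(ct, "CTVolume"), is(model, "AGNetModel"))
  norm <- centralCrop(softTissueNormalize(ct, cfg$preprocess), cfg$preprocess)
  vol <- voxelData(norm)
  transforms <- if (cfg$tta) defaultTTA() else list()
  res <- ttaPredict(model, vol, transforms, patchSize = cfg$patchSize,
                    stride = cfg$stride)
  full <- uncrop(res$labels, dim(ct), cfg$preprocess)
  pp <- postprocessPipeline(LabelVolume(full, voxelSpacing(ct)), ct,
                            cfg$postprocess)
  list(pred = pp$pred,
       probs = ProbabilityVolume(res$probs, voxelSpacing(ct)),
       report = pp$report)
}

#' Run the full detection pipeline over a cohort manifest
#'
#' For each manifest row: read the CT (and labels when present),
#' preprocess, infer with or without TTA, uncrop, postprocess, write the
#' prediction NIfTI and classify the study. Cohort metrics, the resolved
#' configuration and the package version are written next to the
#' predictions. A failing study is recorded and the remaining studies are
#' still processed.
#'
#' @param manifest Path to a cohort manifest CSV (columns `study_id`,
#'   `ct_path`, `seg_path`, `is_case`, `risk_group`, `split`), as written
#'   by [writeCohort()].
#' @param config A [pipelineConfig()] or path to its YAML file.
#' @param checkpoint An [AGNetModel-class] or path to a checkpoint file.
#' @param outDir Output directory.
#' @param split Optional: restrict to manifest rows with this split value.
#' @return List with `metrics` ([cohortMetrics()] or `NULL`), `outcomes`,
#'   `failures` (data.frame of study_id/stage/message) and `ok` (logical:
#'   no failures).
#' @export
runPipeline <- function(manifest, config, checkpoint, outDir,
                        split = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config
    else readPipelineConfig(config)
  model <- if (is(checkpoint, "AGNetModel")) checkpoint
    else loadCheckpoint(checkpoint)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  outcomes <- list()
  failures <- data.frame(study_id = character(0), stage = character(0),
                         message = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    stage <- "read"
    res <- tryCatch({
      ct <- readVolume(row$ct_path)
      segPath <- row$seg_path
      truth <- if (!is.null(segPath) && !is.na(segPath) && nzchar(segPath) &&
                   file.exists(segPath))
        readVolume(segPath, label = TRUE) else NULL
      stage <- "segment"
      seg <- segmentVolume(ct, model, cfg)
      stage <- "write"
      writeVolume(seg$pred, file.path(outDir,
                                      paste0(row$study_id, "_pred.nii.gz")))
      stage <- "evaluate"
      outcome <- classifyStudy(seg$pred, truth, isCase = isTRUE(row$is_case),
                               studyId = row$study_id,
                               riskGroup = row$risk_group)
      list(outcome = outcome)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(study_id = row$study_id, stage = stage,
                                   message = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      outcomes[[length(outcomes) + 1L]] <- res$outcome
    }
  }
  metrics <- if (length(outcomes) > 0L) cohortMetrics(outcomes) else NULL
  writePipelineConfig(cfg, file.path(outDir, "resolved_config.yaml"))
  if (!is.null(metrics)) {
    jsonlite::write_json(
      list(sensitivity = metrics$sensitivity,
           specificity = metrics$specificity,
           sensitivityByGroup = as.list(metrics$sensitivityByGroup),
           dicePancreas = metrics$dicePancreas,
           diceCyst = metrics$diceCyst,
           counts = as.list(metrics$counts),
           package_version =
             as.character(utils::packageVersion("PCLseg"))),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  if (nrow(failures) > 0L)
    write.csv(failures, file.path(outDir, "failures.csv"), row.names = FALSE)
  list(metrics = metrics, outcomes = outcomes, failures = failures,
       ok = nrow(failures) == 0L)
}
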