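# End-to-end pipeline: enhance -> segment -> fuse -> trace -> evaluate,
# with YAML configuration, stage logging and full determinism per seed.

#' Pipeline configuration
#'
#' @param ... Field overrides. Fields: `image`, `checkpoint`, `out`, `gold`
#'   (optional SWC path), `gamma` (0.4), `alpha` (0.8), `trace_threshold`
#'   (0.1 on the fused scale), `soma` ((x,y,z) or `"auto"` = brightest
#'   voxel), `dtgt`, `fusion` (logical switches), `weak_threshold`,
#'   `match_radius`, `tile`, `overlap`, `prune_length`, `seed`.
#' @param file Optional YAML file whose fields are loaded first.
#' @return List of class `pipelineConfig`.
#' @export
pipelineConfig <- function(..., file = NULL) {
  cfg <- list(image = NULL, checkpoint = NULL, out = NULL, gold = NULL,
              gamma = 0.4, alpha = 0.8, trace_threshold = 0.1,
              soma = "auto", dtgt = TRUE, fusion = TRUE,
              weak_threshold = 20 / 255, match_radius = 2,
              tile = c(32, 32, 32), overlap = 8, prune_length = 2,
              seed = 1L)
  if (!is.null(file)) {
    loaded <- yaml::read_yaml(file)
    for (nm in names(loaded)) cfg[[nm]] <- loaded[[nm]]
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (cfg$gamma <= 0 || cfg$gamma > 1) stop("gamma must lie in (0, 1]")
  if (cfg$trace_threshold <= 0 || cfg$trace_threshold >= 1)
    stop("trace_threshold must lie in (0, 1)")
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips: `pipelineConfig(file = path)` reloads an equal object.
#'
#' @param cfg A [pipelineConfig()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
writePipelineConfig <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

autoSoma <- function(vol) {
  i <- which.max(vol)
  shape <- dim(vol)
  c((i - 1) %% shape[1],
    ((i - 1) %/% shape[1]) %% shape[2],
    (i - 1) %/% (shape[1] * shape[2]))
}

#' Run the full tracing pipeline on one volume
#'
#' Stages, in order: load image and checkpoint (all paths are validated
#' before any compute), derivative-truncated gamma enhancement, tiled
#' segmentation, fusion with the original image, skeleton tracing to SWC,
#' and (when a gold standard is configured) evaluation. Intermediates
#' (`enhanced.tif`, `prob.tif`, `fused.tif`, `recon.swc`, `report.json`) and
#' a `run_metadata.json` with the configuration and seed are written to
#' `cfg$out`. Reruns with the same configuration and seed are identical.
#'
#' @param cfg A [pipelineConfig()] with at least `image`, `checkpoint`, `out`.
#' @return Invisibly, a list with `recon` ([SwcTree-class]), `report`
#'   ([MetricsReport-class] or `NULL`) and the artifact paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  for (f in c("image", "checkpoint", "out"))
    if (is.null(cfg[[f]])) stop("pipeline config is missing '", f, "'")
  if (!file.exists(cfg$image)) stop("image not found: ", cfg$image)
  if (!file.exists(cfg$checkpoint)) stop("checkpoint not found: ", cfg$checkpoint)
  if (!is.null(cfg$gold) && !file.exists(cfg$gold))
    stop("gold standard not found: ", cfg$gold)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  img <- stage("load", readVolume(cfg$image))
  ckpt <- stage("load", loadCheckpoint(cfg$checkpoint))
  enhanced <- stage("enhance",
                    if (isTRUE(cfg$dtgt)) dtgtTransform(img, cfg$gamma) else img)
  writeVolume(enhanced, file.path(cfg$out, "enhanced.tif"))
  prob <- stage("segment",
                predictVolume(ckpt$net, enhanced, tile = cfg$tile,
                              overlap = cfg$overlap))
  writeVolume(prob, file.path(cfg$out, "prob.tif"))
  alpha <- if (isTRUE(cfg$fusion)) cfg$alpha else 1
  fused <- stage("fuse", fuseVolumes(img, prob, alpha))
  writeVolume(fused, file.path(cfg$out, "fused.tif"))
  soma <- if (identical(cfg$soma, "auto")) autoSoma(img) else as.numeric(cfg$soma)
  recon <- stage("trace",
                 extractReconstruction(fused, cfg$trace_threshold, soma,
                                       pruneLength = cfg$prune_length))
  writeSWC(recon, file.path(cfg$out, "recon.swc"))
  report <- NULL
  if (!is.null(cfg$gold)) {
    gold <- readSWC(cfg$gold)
    report <- stage("evaluate",
                    evaluatePair(gold, recon, image = img,
                                 matchRadius = cfg$match_radius,
                                 weakThreshold = cfg$weak_threshold))
    jsonlite::write_json(metricsAsList(report),
                         file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  meta <- list(package = "NeuriteTrace",
               version = as.character(utils::packageVersion("NeuriteTrace")),
               config = unclass(cfg)[!vapply(cfg, is.null, logical(1))])
  jsonlite::write_json(meta, file.path(cfg$out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(recon = recon, report = report, out = cfg$out))
}

#' Build a training dataset from synthetic scenes
#'
#' For each scene: paint the soma cuboid into the image at the image
#' maximum, enhance (optional), and rasterize the *labeled* (partial) tree
#' into the training label.
#'
#' @param scenes List of scenes from [generateScene()].
#' @param gamma Enhancement exponent.
#' @param dtgt Apply the derivative-truncated gamma transform.
#' @return List of `(image, label)` samples for [trainNetwork()].
#' @export
prepareDataset <- function(scenes, gamma = 0.4, dtgt = TRUE) {
  lapply(scenes, function(sc) {
    img <- applySomaToImage(sc$image, sc$labeled, intensity = 1)
    if (dtgt) img <- dtgtTransform(img, gamma)
    list(image = img,
         label = makeLabelVolume(sc$labeled, dim(sc$image)))
  })
}

#' Voxel recall of a probability map on weak gold-standard points
#'
#' Fraction of resampled gold points at image intensity below
#' `weakThreshold` whose voxel has foreground probability >= `probThreshold`.
#'
#' @param prob Probability volume.
#' @param gold Gold-standard [SwcTree-class].
#' @param image Intensity volume used for the weak stratification.
#' @param weakThreshold Normalized weak-fiber threshold.
#' @param probThreshold Segmentation decision threshold.
#' @return List with `weak` and `overall` voxel recall.
#' @export
weakVoxelRecall <- function(prob, gold, image, weakThreshold = 20 / 255,
                            probThreshold = 0.5) {
  A <- resampleTree(gold, 1)
  shape <- dim(prob)
  vox <- round(A)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), shape[a] - 1)
  pv <- prob[vox + 1] >= probThreshold
  inten <- image[vox + 1]
  weak <- inten < weakThreshold
  list(weak = if (any(weak)) mean(pv[weak]) else NA_real_,
       overall = mean(pv))
}

#' Train/evaluate benchmark comparing false-negative-mining weights
#'
#' Trains the tiny network on the training scenes for every combination of
#' `wFN` value and seed, then measures weak-fiber voxel recall of each model
#' on the test scenes. This is the package's synthetic stand-in for the
#' weak-fiber recall experiment: with identical seeds, the only difference
#' between runs is the false-negative weight.
#'
#' @param trainScenes,testScenes Scene lists from [generateScene()].
#' @param wFN Vector of false-negative weights to compare.
#' @param seeds Training seeds (one run per `wFN` x seed).
#' @param baseCfg Base [trainConfig()] (tiny profile by default).
#' @param gamma Enhancement exponent used for train and test images.
#' @return List: `runs` (data.frame with w_fn, seed, weak/overall recall,
#'   first/last training loss) and `checkpoints` (one per run).
#' @export
weakFiberBenchmark <- function(trainScenes, testScenes,
                               wFN = c(1.0, 1.5), seeds = 1:3,
                               baseCfg = trainConfig(tiny = TRUE),
                               gamma = 0.4) {
  dataset <- prepareDataset(trainScenes, gamma = gamma, dtgt = TRUE)
  testPrep <- lapply(testScenes, function(sc) {
    img <- applySomaToImage(sc$image, sc$labeled, intensity = 1)
    list(enhanced = dtgtTransform(img, gamma), image = sc$image,
         gold = sc$gold)
  })
  rows <- list(); ckpts <- list()
  for (w in wFN) for (sd in seeds) {
    cfg <- baseCfg
    cfg$w_fn <- w
    cfg$seed <- sd
    ck <- trainNetwork(dataset, cfg)
    recs <- vapply(testPrep, function(tp) {
      p <- predictVolume(ck$net, tp$enhanced, tile = cfg$crop)
      r <- weakVoxelRecall(p, tp$gold, tp$image)
      c(r$weak, r$overall)
    }, numeric(2))
    key <- sprintf("w%.1f_s%d", w, sd)
    ckpts[[key]] <- ck
    rows[[key]] <- data.frame(
      w_fn = w, seed = sd,
      weak_recall = mean(recs[1, ], na.rm = TRUE),
      overall_recall = mean(recs[2, ], na.rm = TRUE),
      first_loss = ck$log$loss[1],
      last_loss = ck$log$loss[nrow(ck$log)])
  }
  list(runs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       checkpoints = ckpts)
}

#' Ablation study over the pipeline switches
#'
#' Re-trains and re-evaluates the pipeline for each requested on/off
#' combination of the three components — false-negative mining (`fnm`),
#' the derivative-truncated gamma enhancement (`dtgt`) and image fusion
#' (`fusion`) — and tabulates one metrics row per combination (averaged over
#' the test scenes). `fnm = FALSE` trains with weight-map 1.0 everywhere;
#' `dtgt = FALSE` makes the enhancement stage the identity; `fusion = FALSE`
#' traces the raw image (alpha = 1).
#'
#' @param trainScenes,testScenes Scene lists from [generateScene()].
#' @param combos data.frame with logical columns fnm, dtgt, fusion; default
#'   all-on vs all-off.
#' @param baseCfg Base [trainConfig()].
#' @param gamma,alpha,traceThreshold Pipeline parameters.
#' @return data.frame: one row per combination with the switch settings and
#'   mean SD/SSD/PDS, weak recall and path-length ratio.
#' @export
runAblation <- function(trainScenes, testScenes,
                        combos = data.frame(fnm = c(TRUE, FALSE),
                                            dtgt = c(TRUE, FALSE),
                                            fusion = c(TRUE, FALSE)),
                        baseCfg = trainConfig(tiny = TRUE),
                        gamma = 0.4, alpha = 0.8, traceThreshold = 0.1) {
  stopifnot(all(c("fnm", "dtgt", "fusion") %in% names(combos)))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sw <- combos[i, ]
    dataset <- prepareDataset(trainScenes, gamma = gamma, dtgt = sw$dtgt)
    cfg <- baseCfg
    cfg$fnm <- sw$fnm
    ck <- trainNetwork(dataset, cfg)
    reps <- lapply(testScenes, function(sc) {
      img <- applySomaToImage(sc$image, sc$labeled, intensity = 1)
      enhanced <- if (sw$dtgt) dtgtTransform(img, gamma) else img
      p <- predictVolume(ck$net, enhanced, tile = cfg$crop)
      a <- if (sw$fusion) alpha else 1
      fused <- fuseVolumes(sc$image, p, a)
      soma <- as.numeric(rootNode(sc$gold)[, c("x", "y", "z")])
      recon <- tryCatch(
        extractReconstruction(fused, traceThreshold, soma),
        error = function(e) NULL)
      if (is.null(recon)) return(NULL)
      metricsAsList(evaluatePair(sc$gold, recon, image = sc$image))
    })
    reps <- reps[!vapply(reps, is.null, logical(1))]
    out <- data.frame(fnm = sw$fnm, dtgt = sw$dtgt, fusion = sw$fusion,
                      n_traced = length(reps))
    for (m in c("sd12", "sd21", "sd", "ssd12", "ssd21", "ssd",
                "pds12", "pds21", "pds", "weak_recall", "path_length_ratio"))
      out[[m]] <- if (length(reps))
        mean(vapply(reps, function(r) as.numeric(r[[m]]), numeric(1)),
             na.rm = TRUE)
      else NA_real_
    out
  })
  do.call(rbind, rows)
}
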