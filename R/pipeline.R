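# End-to-end orchestration: simulate (or load) -> segment -> map -> kinetics
# -> report, with a JSON manifest recording parameters, seeds and checksums.

#' Sparse training labels from a known cell mask
#'
#' Samples pixels from a reference mask into the sparse-label convention
#' (0 = unlabelled, 1 = cell, 2 = background), e.g. to train the pixel
#' classifier on simulated scenes with known truth.
#'
#' @param mask logical cell mask.
#' @param n_per_class pixels to label per class.
#' @param seed RNG seed.
#' @return integer label matrix.
#' @export
labels_from_truth <- function(mask, n_per_class = 200L, seed = 0L) {
  with_local_seed(seed, {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    cell <- which(mask); bg <- which(!mask)
    lab[sample(cell, min(n_per_class, length(cell)))] <- 1L
    lab[sample(bg, min(n_per_class, length(bg)))] <- 2L
    lab
  })
}

#' Run the full secretion-analysis pipeline
#'
#' Executes simulate/load, cell segmentation, secretion mapping, kinetics
#' and reporting for one sensing/reference well pair, writing every artefact
#' plus a manifest under `out_dir`. A stage failure is recorded in the
#' manifest (`status = "failed"`) and subsequent stages are skipped.
#'
#' @param config configuration list, or path to a YAML file. Blocks:
#'   \describe{
#'     \item{scene}{arguments for [scene_config()] (simulated input), or}
#'     \item{input}{`list(sensing=, reference=, frame_interval=)` TIFF paths
#'       for real data.}
#'     \item{segmentation}{`mode` `"classifier"` (default) or `"truth"`
#'       (simulated scenes only); `n_trees`, `seed`, `n_labels`,
#'       `train_frames`, `filter_radius`.}
#'     \item{mapping}{arguments passed to [build_secretion_maps()].}
#'     \item{kinetics}{`epsilon`, `persistence`, `noise_floor_multiple`.}
#'   }
#'   A top-level `seed` seeds every stage.
#' @param out_dir output directory.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("secretomap")),
                   seed = seed, config = config, stages = list())
  artefacts <- character(0)
  failed <- FALSE
  record <- function(name, status, params = NULL, outputs = NULL, error = NULL) {
    manifest$stages[[name]] <<- list(status = status, params = params,
                                     outputs = outputs, error = error)
    artefacts <<- c(artefacts, outputs)
  }
  run_stage <- function(name, params, expr) {
    if (failed) { record(name, "skipped"); return(NULL) }
    tryCatch(expr, error = function(e) {
      record(name, "failed", params = params, error = conditionMessage(e))
      failed <<- TRUE
      NULL
    })
  }

  if (is.null(config$scene) && is.null(config$input))
    stop("config needs a 'scene' (simulate) or 'input' (TIFF paths) block")
  if (!is.null(config$input)) {
    inp <- config$input
    for (f in c(inp$sensing, inp$reference))
      if (!file.exists(f)) stop("input file not found: ", f)
  }

  # --- stage: input --------------------------------------------------------
  scene <- NULL
  pair <- run_stage("input", config$scene, {
    if (!is.null(config$scene)) {
      sc_args <- config$scene
      if (is.null(sc_args$seed)) sc_args$seed <- seed
      if (!is.null(sc_args$profile) && !inherits(sc_args$profile, "secretion_profile"))
        sc_args$profile <- do.call(secretion_profile, sc_args$profile)
      scene <- do.call(scene_config, sc_args)
      scene <- simulate_scene(scene)
      write_scene(scene, file.path(out_dir, "scene"))
      record("input", "ok", params = config$scene,
             outputs = file.path(out_dir, "scene",
                                 c("sensing.tif", "reference.tif",
                                   "ground_truth.json")))
      list(sensing = scene$sensing, reference = scene$reference)
    } else {
      inp <- config$input
      meta <- acquisition_meta(frame_interval = inp$frame_interval %||% 10)
      s <- read_timelapse(inp$sensing, meta)
      r <- read_timelapse(inp$reference, meta)
      record("input", "ok", params = inp)
      list(sensing = structure(list(stack = s, well_id = "S1", role = "sensing",
                                    crop_origin = c(0L, 0L)), class = "well_stack"),
           reference = structure(list(stack = r, well_id = "R1",
                                      role = "reference", crop_origin = c(0L, 0L)),
                                 class = "well_stack"))
    }
  })

  # --- stage: segment ------------------------------------------------------
  seg <- utils::modifyList(list(mode = "classifier", n_trees = 100L,
                                seed = seed, n_labels = 200L,
                                train_frames = 3L, filter_radius = 1L),
                           config$segmentation %||% list())
  masks <- run_stage("segment", seg, {
    frames <- pair$sensing$stack$frames
    m <- if (identical(seg$mode, "truth")) {
      if (is.null(scene)) stop("segmentation mode 'truth' needs a simulated scene")
      scene$truth$cell_masks
    } else {
      idx <- unique(round(seq(1L, length(frames), length.out = seg$train_frames)))
      ref_mask <- if (!is.null(scene)) scene$truth$cell_masks else
        stop("classifier mode without labels requires a simulated scene; ",
             "supply segmentation$model for real data")
      feats <- lapply(frames[idx], compute_pixel_features)
      labs <- lapply(idx, function(i)
        labels_from_truth(ref_mask[[i]], seg$n_labels, seed = seg$seed + i))
      model <- train_pixel_classifier(feats, labs, n_trees = seg$n_trees,
                                      seed = seg$seed)
      lapply(frames, function(f)
        binarize_probability_map(predict_probability_map(model, f),
                                 filter_radius = seg$filter_radius))
    }
    mask_stack <- image_stack(lapply(m, function(x) x + 0), pair$sensing$stack$times)
    p <- file.path(out_dir, "cell_masks.tif")
    write_timelapse(mask_stack, p, bits = 8L)
    record("segment", "ok", params = seg, outputs = p)
    m
  })

  # --- stage: map ----------------------------------------------------------
  mp <- config$mapping %||% list()
  maps <- run_stage("map", mp, {
    m <- do.call(build_secretion_maps, c(list(pair = pair, masks = masks), mp))
    p <- file.path(out_dir, "secretion_maps.tif")
    write_secretion_maps(m, p)
    record("map", "ok", params = mp, outputs = c(p, paste0(p, ".json")))
    m
  })

  # --- stage: kinetics -----------------------------------------------------
  kin <- utils::modifyList(list(epsilon = 0.01, persistence = 1L,
                                noise_floor_multiple = 5),
                           config$kinetics %||% list())
  result <- run_stage("kinetics", kin, {
    meta_px <- if (!is.null(scene)) scene$config$object_pixel_size else
      object_pixel_size(acquisition_meta(
        frame_interval = config$input$frame_interval %||% 10))
    tic <- tic_curve(maps)
    area <- area_curve(maps, pixel_area = meta_px^2)
    ref_pair <- list(sensing = pair$reference, reference = pair$reference)
    empty <- lapply(maps$frames, function(f) matrix(FALSE, nrow(f), ncol(f)))
    ref_maps <- build_secretion_maps(ref_pair, empty, circle = maps$circle)
    floor_tic <- noise_floor_tic(ref_maps, kin$noise_floor_multiple)
    rec <- classify_and_fit(tic, area = area, noise_floor = floor_tic,
                            epsilon = kin$epsilon,
                            persistence = kin$persistence,
                            cell_id = pair$sensing$well_id)
    paths <- export_kinetics(curves = list(tic = tic, area = area),
                             records = list(rec), dir = out_dir)
    record("kinetics", "ok",
           params = c(kin, list(noise_floor = floor_tic)), outputs = paths)
    list(tic = tic, area = area, record = rec, noise_floor = floor_tic)
  })

  # --- stage: report -------------------------------------------------------
  run_stage("report", NULL, {
    stats <- population_summary(list(result$record))
    p <- file.path(out_dir, "population_stats.json")
    jsonlite::write_json(unclass(stats), p, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    pf <- file.path(out_dir, "overview.png")
    grDevices::png(pf, width = 900, height = 400)
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old), add = TRUE)
    plot(result$tic, main = sprintf("TIC (type %s)", result$record$secretion_type))
    plot(result$area, main = "Secretion area")
    grDevices::dev.off()
    record("report", "ok", outputs = c(p, pf))
    NULL
  })

  existing <- artefacts[file.exists(artefacts)]
  manifest$checksums <- as.list(tools::md5sum(existing))
  manifest$status <- if (failed) "partial" else "complete"
  if (!is.null(config$scene) && !is.null(scene))
    manifest$truth_label <- scene$truth$label
  if (!is.null(result)) {
    manifest$secretion_type <- result$record$secretion_type
    manifest$noise_floor <- result$noise_floor
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
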