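#' Pipeline configuration
#'
#' One object collecting every tunable parameter of the end-to-end pipeline
#' (recognition filters, path-planning geometry, MS event detection,
#' classification), each with a documented default.  Serializes to YAML and
#' round-trips.
#'
#' @param mode Sampling mode: `"cnd"` (cut-and-drop microdissection of
#'   dispersed cells) or `"raster"` (interior ablation of connected
#'   tissue).
#' @param preset Recognition preset, `"algae"` or `"onion"`
#'   (see [recognition_preset()]).
#' @param min_area,max_area,min_circularity Optional overrides of the
#'   preset's filters.
#' @param spacing,inset Raster-mode line spacing and boundary stand-off
#'   (µm).
#' @param margin Cut-mode outward clearance, also the isolation margin for
#'   [filter_isolated()] (µm).
#' @param n_passes Cut-loop repeats.
#' @param recalibrate Apply lock-mass recalibration to extracted spectra.
#' @param recal_tolerance Lock-mass match tolerance (m/z).
#' @param k_mad,min_gap Event-detection threshold multiplier and merge gap
#'   (s).
#' @param k Number of principal components for classification.
#' @param seed Integer seed governing all randomness.
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(mode = c("cnd", "raster"), preset = "algae",
                            min_area = NULL, max_area = NULL,
                            min_circularity = NULL, spacing = 5, inset = 2,
                            margin = 3, n_passes = 2, recalibrate = TRUE,
                            recal_tolerance = 0.1, k_mad = 5, min_gap = 1,
                            k = 2, seed = 1, output_dir = NULL) {
  mode <- match.arg(mode)
  pr <- recognition_preset(preset)
  cfg <- list(mode = mode, preset = preset,
              min_area = if (is.null(min_area)) pr$min_area else min_area,
              max_area = if (is.null(max_area)) pr$max_area else max_area,
              min_circularity = if (is.null(min_circularity))
                pr$min_circularity else min_circularity,
              spacing = spacing, inset = inset, margin = margin,
              n_passes = n_passes, recalibrate = recalibrate,
              recal_tolerance = recal_tolerance,
              k_mad = k_mad, min_gap = min_gap, k = k,
              seed = as.integer(seed), output_dir = output_dir)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[setdiff(names(raw),
    c("min_area", "max_area", "min_circularity"))]) -> cfg
  for (f in c("min_area", "max_area", "min_circularity"))
    if (!is.null(raw[[f]])) cfg[[f]] <- raw[[f]]
  cfg
}

config_hash <- function(config) rlang::hash(unclass(config))

plan_paths <- function(cells, config) {
  lapply(cells, function(cell) {
    if (config$mode == "cnd")
      cut_contour(cell, margin = config$margin, n_passes = config$n_passes)
    else
      raster_path(cell, spacing = config$spacing, inset = config$inset)
  })
}

#' Run the optically guided pipeline end to end
#'
#' Executes the full chain on one field of view: cell recognition,
#' isolation filtering (cut-and-drop mode), laser path planning and
#' ordering, MS event detection and per-cell spectrum extraction, optional
#' lock-mass recalibration, fixed-grid binning, and classification --
#' either apportionment with a supplied trained model or, when training
#' labels are given, PCA-LDA fitting with leave-one-out cross-validation.
#' Events are paired to cells in planned sampling order.  The run is fully
#' deterministic: identical config and inputs give an identical manifest
#' hash.
#'
#' @param config A [pipeline_config()].
#' @param image An [optical_image()].
#' @param run An `ms_run` (or `NULL` when the image contains no cells).
#' @param labels Optional per-cell class labels in planned sampling order
#'   (training mode).
#' @param model Optional trained [fit_pca_lda()] model (apportionment
#'   mode).
#' @return List with `manifest` (records data.frame plus hashes and
#'   software version), `cells`, `paths`, `events`, `features`
#'   ([feature_matrix()]), `model` or `apportionment`, `loocv`, and the
#'   structured `log` (one record per cell per stage).
#' @export
run_pipeline <- function(config, image, run = NULL, labels = NULL,
                         model = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(image, "optical_image"))
  log <- list()
  note <- function(stage, cell_id, message) {
    log[[length(log) + 1]] <<- list(stage = stage, cell_id = cell_id,
                                    message = message)
  }
  stage <- function(name, cell_id = NA_integer_, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed",
           if (!is.na(cell_id)) paste0(" (cell ", cell_id, ")"), ": ",
           conditionMessage(e), call. = FALSE))
  }

  cells <- stage("detect", expr = segment_cells(
    image, min_area = config$min_area, max_area = config$max_area,
    min_circularity = config$min_circularity))
  for (b in cells) note("detect", b$cell_id,
                        sprintf("area %.1f um^2", b$area))
  if (config$mode == "cnd") {
    cells <- stage("isolate", expr = filter_isolated(cells, config$margin))
    for (b in cells) note("isolate", b$cell_id, "kept")
  }

  version <- as.character(utils::packageVersion("lmdpipe"))
  if (!length(cells)) {
    manifest <- list(records = data.frame(), n_cells = 0L,
                     software_version = version,
                     config_hash = config_hash(config),
                     matrix_hash = rlang::hash(matrix(numeric(0), 0, 3000)))
    manifest$hash <- rlang::hash(manifest)
    out <- list(manifest = manifest, cells = cells, paths = list(),
                events = NULL, features = NULL, model = NULL,
                apportionment = NULL, loocv = NULL, log = log)
    write_artifacts(out, config, image)
    return(out)
  }

  paths <- stage("plan", expr = plan_paths(cells, config))
  paths <- order_cells(paths, start = image$stage_offset)
  for (p in paths) note("plan", p$cell_id,
                        sprintf("%s, %d waypoints", p$mode, nrow(p$waypoints)))
  planned_ids <- vapply(paths, function(p) p$cell_id, integer(1))
  cells_by_id <- stats::setNames(cells, vapply(cells, function(b)
    b$cell_id, integer(1)))

  if (is.null(run)) stop("run_pipeline: cells were recognized but no run given")
  chron <- stage("extract", expr = total_ion_chronogram(run))
  events <- stage("extract", expr = detect_cell_events(
    chron, k_mad = config$k_mad, min_gap = config$min_gap))
  n_pair <- min(nrow(events), length(paths))
  if (nrow(events) != length(paths))
    note("extract", NA_integer_,
         sprintf("event/cell count mismatch: %d events, %d cells",
                 nrow(events), length(paths)))
  binned <- vector("list", n_pair)
  for (i in seq_len(n_pair)) {
    cid <- planned_ids[i]
    sp <- stage("extract", cid,
                extract_cell_spectrum(run, events[i, ], all_events = events))
    if (config$recalibrate) {
      rc <- stage("recalibrate", cid, mass_recalibrate(
        sp, tolerance = config$recal_tolerance))
      sp <- rc$spectrum
      note("recalibrate", cid,
           if (rc$uncalibrated) "no lock-mass match; left uncalibrated"
           else sprintf("%d lock masses matched", nrow(rc$matches)))
    }
    binned[[i]] <- stage("bin", cid, normalize_and_bin(sp))
    note("bin", cid, "3000-bin feature vector")
  }
  used_labels <- if (!is.null(labels)) labels[seq_len(n_pair)]
  fm <- feature_matrix(binned, labels = used_labels,
                       ids = planned_ids[seq_len(n_pair)])

  fitted <- NULL; app <- NULL; loocv <- NULL
  if (!is.null(model)) {
    app <- stage("classify", expr = apportion(model, fm))
    for (i in seq_len(n_pair))
      note("classify", fm$ids[i], app$predicted[i])
  } else if (!is.null(used_labels) && length(unique(used_labels)) == 2 &&
             min(table(used_labels)) >= 2 && n_pair >= 4) {
    fitted <- stage("classify", expr = fit_pca_lda(fm, k = config$k))
    loocv <- stage("classify", expr = loocv_accuracy(fm, k = config$k))
    for (i in seq_len(n_pair))
      note("classify", fm$ids[i], loocv$verdicts$predicted[i])
  }

  records <- do.call(rbind, lapply(seq_len(n_pair), function(i) {
    b <- cells_by_id[[as.character(planned_ids[i])]]
    data.frame(cell_id = b$cell_id, x_um = b$centroid[1], y_um = b$centroid[2],
               area_um2 = b$area, circularity = b$circularity,
               mode = config$mode,
               n_waypoints = nrow(paths[[i]]$waypoints),
               event_id = events$cell_id[i], apex_time = events$apex_time[i],
               feature_row = i,
               label = if (!is.null(used_labels)) used_labels[i] else NA_character_,
               predicted = if (!is.null(app)) app$predicted[i]
                           else if (!is.null(loocv)) loocv$verdicts$predicted[i]
                           else NA_character_)
  }))
  manifest <- list(records = records, n_cells = n_pair,
                   software_version = version,
                   config_hash = config_hash(config),
                   matrix_hash = rlang::hash(fm$values))
  manifest$hash <- rlang::hash(manifest[c("records", "n_cells",
                                          "config_hash", "matrix_hash")])
  out <- list(manifest = manifest, cells = cells, paths = paths,
              events = events, features = fm, model = fitted,
              apportionment = app, loocv = loocv, log = log)
  write_artifacts(out, config, image)
  out
}

write_artifacts <- function(result, config, image) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config_yaml(config, file.path(dir, "config.yaml"))
  if (length(result$cells)) {
    write_boundaries_geojson(result$cells, file.path(dir, "boundaries.geojson"))
    write_boundaries_csv(result$cells, file.path(dir, "boundaries.csv"))
  }
  if (length(result$paths))
    write_paths_json(result$paths, file.path(dir, "paths.json"))
  if (!is.null(result$features))
    write_feature_matrix(result$features, file.path(dir, "features.csv"))
  if (!is.null(result$model)) {
    write_pca_lda(result$model, file.path(dir, "model.json"))
    plot_scores_png(result$model, path = file.path(dir, "scores.png"))
  }
  man <- result$manifest
  jsonlite::write_json(list(
    n_cells = man$n_cells, software_version = man$software_version,
    config_hash = man$config_hash, matrix_hash = man$matrix_hash,
    hash = man$hash, records = man$records),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(vapply(result$log, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"), character(1)),
    file.path(dir, "log.jsonl"))
  invisible(dir)
}

#' Simulate a complete single-cell sampling experiment
#'
#' Builds one synthetic slide of two algal classes, recognizes and plans it
#' exactly as the pipeline would, and synthesizes the matching MS run whose
#' event order follows the planned sampling order -- so that
#' [run_pipeline()] on the returned image and run reproduces the truth
#' table.  Optionally cross-contaminates selected cells with the other
#' class's signal, emulating co-capture of a previously microdissected
#' cell.
#'
#' @param n_class_a,n_class_b Cells of each class (defaults 50/50, the
#'   unmixed training design).
#' @param contamination Optional data.frame with columns `index` (position
#'   in the planned sampling order) and `fraction` (contaminant weight);
#'   the contaminant is a spectrum of the opposite class.
#' @param seed Integer seed governing the whole simulation.
#' @param profiles Two [species_profile()]s; names become the class labels.
#' @param config [pipeline_config()] used for recognition and planning.
#' @param pitch Centre-to-centre cell spacing on the slide (µm).
#' @param pixel_size Image pixel size (µm/px).
#' @param image_noise_sd Image noise sd on the \[0, 1\] scale.
#' @param total_intensity,spectrum_noise_sd Per-cell spectrum intensity
#'   budget and per-channel noise (counts).
#' @param grid_step Spectrum m/z grid step.
#' @param dwell Inter-cell sampling interval in the run (s).
#' @param scan_period,baseline,run_noise_sd MS run timing, per-channel
#'   baseline and scan noise.
#' @return List: `image`, `truth` (scene table with labels), `run`,
#'   `planned` (data.frame in sampling order: `order`, `cell_id`,
#'   `truth_id`, `label`, `contaminated`, `fraction`, `event_time`),
#'   `cells`, `paths`.
#' @export
simulate_experiment <- function(n_class_a = 50, n_class_b = 50,
                                contamination = NULL, seed = 1,
                                profiles = default_profiles(),
                                config = pipeline_config(seed = seed),
                                pitch = 40, pixel_size = 0.5,
                                image_noise_sd = 0.02,
                                total_intensity = 1e4,
                                spectrum_noise_sd = 5, grid_step = 0.01,
                                dwell = 10, scan_period = 0.05,
                                baseline = 0.01, run_noise_sd = 0) {
  stopifnot(n_class_a >= 0, n_class_b >= 0)
  n <- n_class_a + n_class_b
  classes <- names(profiles)
  stopifnot(length(classes) == 2)
  with_seed(seed, {
    labels <- sample(c(rep(classes[1], n_class_a), rep(classes[2], n_class_b)))
    # jittered grid placement keeps every cell isolated by construction
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    rows <- lapply(seq_len(n), function(i) {
      r <- (i - 1) %/% ncols; cc <- (i - 1) %% ncols
      a <- stats::runif(1, 4, 6); b <- stats::runif(1, 0.7 * a, a)
      cell_ground_truth(i,
        c((cc + 0.5) * pitch + stats::runif(1, -5, 5),
          (r + 0.5) * pitch + stats::runif(1, -5, 5)),
        c(a, b), stats::runif(1, 0, pi), labels[i])
    })
    truth <- do.call(rbind, rows)
    shape <- rep(ceiling(pitch * max(ncols, nrows) / pixel_size), 2)
    gen <- generate_image(truth, pixel_size = pixel_size,
                          image_shape = c(ceiling(nrows * pitch / pixel_size),
                                          ceiling(ncols * pitch / pixel_size)),
                          noise_sd = image_noise_sd, seed = NULL)
    image <- gen$image

    cells <- segment_cells(image, min_area = config$min_area,
                           max_area = config$max_area,
                           min_circularity = config$min_circularity)
    cells <- filter_isolated(cells, config$margin)
    paths <- order_cells(plan_paths(cells, config),
                         start = image$stage_offset)

    # planned sampling order -> ground truth, by nearest centroid
    planned <- do.call(rbind, lapply(seq_along(paths), function(i) {
      cid <- paths[[i]]$cell_id
      b <- Filter(function(x) x$cell_id == cid, cells)[[1]]
      d <- sqrt((truth$x_um - b$centroid[1])^2 + (truth$y_um - b$centroid[2])^2)
      ti <- which.min(d)
      if (d[ti] > 2) stop("simulate_experiment: recognized cell ", cid,
                          " matches no ground-truth cell within 2 um")
      data.frame(order = i, cell_id = cid, truth_id = truth$cell_id[ti],
                 label = truth$label[ti], contaminated = FALSE, fraction = 0,
                 event_time = 5 + (i - 1) * dwell)
    }))
    if (!is.null(contamination) && nrow(planned)) {
      contamination <- as.data.frame(contamination)
      if (any(contamination$index < 1 | contamination$index > nrow(planned)))
        stop("simulate_experiment: contamination index out of range")
      planned$contaminated[contamination$index] <- TRUE
      planned$fraction[contamination$index] <- contamination$fraction
    }

    events <- lapply(seq_len(nrow(planned)), function(i) {
      cls <- planned$label[i]
      sp <- generate_spectrum(profiles[[cls]], total_intensity = total_intensity,
                              noise_sd = spectrum_noise_sd, seed = NULL,
                              grid_step = grid_step)
      if (planned$contaminated[i]) {
        other <- setdiff(classes, cls)
        cont <- generate_spectrum(profiles[[other]],
                                  total_intensity = total_intensity,
                                  noise_sd = spectrum_noise_sd, seed = NULL,
                                  grid_step = grid_step)
        sp <- contaminate(sp, cont, planned$fraction[i])
      }
      list(time = planned$event_time[i], spectrum = sp)
    })
    run <- if (length(events))
      generate_run(events, baseline = baseline, scan_period = scan_period,
                   seed = NULL, noise_sd = run_noise_sd)
    else NULL

    list(image = image, truth = truth, run = run, planned = planned,
         cells = cells, paths = paths)
  })
}
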