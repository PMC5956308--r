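# Readers and writers for the pipeline's on-disk formats: PNG frame stacks,
# offset sidecars (CSV), capillary paths (CSV), ground truth and reports
# (JSON), and YAML configuration.

#' Write a video sequence as numbered PNG frames plus an offsets sidecar
#'
#' @param video a [video_sequence()].
#' @param dir output directory (created if needed).
#' @param prefix frame filename prefix.
#' @return the directory, invisibly.
#' @export
write_video_frames <- function(video, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    png::writePNG(clamp01(video$frames[[i]]),
                  file.path(dir, sprintf("%s_%04d.png", prefix, i)))
  }
  offs <- video$nominal_offsets %||% matrix(0, length(video$frames), 2)
  write.csv(data.frame(frame_index = seq_along(video$frames),
                       dx_px = offs[, 1], dy_px = offs[, 2]),
            file.path(dir, "offsets.csv"), row.names = FALSE)
  meta <- list(frame_rate_hz = video$frame_rate_hz,
               pixel_scale_um = video$pixel_scale_um)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a video sequence from a directory of PNG frames
#'
#' Expects the layout written by [write_video_frames()]; `offsets.csv` and
#' `meta.json` are optional (defaults: zero offsets and the supplied rate
#' and scale).
#'
#' @param dir directory of `*.png` frames.
#' @param frame_rate_hz,pixel_scale_um used when no `meta.json` is present.
#' @return a [video_sequence()].
#' @export
read_video_frames <- function(dir, frame_rate_hz = 120, pixel_scale_um = 1) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) {
    nf_error("nailfold_io_error", sprintf("no PNG frames found in %s", dir))
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  meta_file <- file.path(dir, "meta.json")
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    frame_rate_hz <- meta$frame_rate_hz %||% frame_rate_hz
    pixel_scale_um <- meta$pixel_scale_um %||% pixel_scale_um
  }
  off_file <- file.path(dir, "offsets.csv")
  offs <- if (file.exists(off_file)) {
    o <- read.csv(off_file)
    as.matrix(o[order(o$frame_index), c("dx_px", "dy_px")])
  }
  video_sequence(frames, frame_rate_hz, pixel_scale_um, offs)
}

#' Write / read a mosaic as PNG plus a JSON sidecar of offsets
#' @param mosaic a `nailfold_mosaic`.
#' @param path output PNG path (`<path>.json` holds offsets and scale).
#' @return the path, invisibly.
#' @export
write_mosaic <- function(mosaic, path) {
  png::writePNG(clamp01(mosaic$image), path)
  side <- list(pixel_scale_um = mosaic$pixel_scale_um,
               frame_offsets = mosaic$frame_offsets,
               source_frame_count = mosaic$source_frame_count)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side_file <- paste0(path, ".json")
  side <- if (file.exists(side_file)) {
    jsonlite::read_json(side_file, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(list(image = img,
                 pixel_scale_um = side$pixel_scale_um %||% 1,
                 frame_offsets = side$frame_offsets,
                 source_frame_count = side$source_frame_count %||% 1L),
            class = "nailfold_mosaic")
}

#' Write capillary paths to one tidy CSV
#'
#' One row per path point: capillary id, apex coordinates, point position,
#' orientation, width, measurability and arc distance from the apex.
#'
#' @param paths list of `capillary_path`s.
#' @param file output CSV path.
#' @return the file, invisibly.
#' @export
write_paths_csv <- function(paths, file) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    cbind(capillary_id = i, apex_x = p$apex_xy[1], apex_y = p$apex_xy[2],
          p$points)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Write phantom ground truth as JSON
#' @param truth a [phantom_truth()].
#' @param file output JSON path.
#' @return the file, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  obj <- list(
    apices = truth$apices,
    principal_orientations = truth$principal_orientations,
    velocities_mm_s = truth$velocities_mm_s,
    widths_um = truth$widths_um,
    density_truth = truth$density_truth,
    paths = lapply(truth$paths, function(p) p$points)
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Load a pipeline configuration from YAML or JSON
#' @param file path to a YAML/JSON mapping of [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

#' Write a cohort report to disk
#'
#' Writes `report.json` (full report), `table.csv` (the per-parameter
#' table) and `roc_curves.csv` (FPR/TPR points for every single-parameter
#' and combined curve).
#'
#' @param report a [cohort_report()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$table, file.path(dir, "table.csv"), row.names = FALSE)
  curves <- list()
  for (p in names(report$rocs)) {
    cv <- report$rocs[[p]]$curve
    curves[[p]] <- cbind(model = p, cv)
  }
  curves$combined_structure <- cbind(model = "combined_structure",
                                     report$combined_structure$combined_roc$curve)
  curves$combined_structure_flow <- cbind(model = "combined_structure_flow",
                                          report$combined_full$combined_roc$curve)
  write.csv(do.call(rbind, curves), file.path(dir, "roc_curves.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(table = report$table,
         n = as.list(setNames(as.integer(report$n), names(report$n))),
         structure_terms = report$combined_structure$selected_terms,
         structure_flow_terms = report$combined_full$selected_terms),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
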