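# The end-to-end pipeline: video -> mosaic -> detection -> flow ->
# per-digit metrics -> per-subject averages -> cohort report, with per-digit
# fault isolation so one failed digit never aborts a cohort run.

#' Pipeline configuration
#'
#' Collects every tunable of the stage chain, validated at construction.
#'
#' @param pixel_scale_um,frame_rate_hz imaging geometry defaults (used when
#'   a video does not carry its own).
#' @param scales_um ridge-filter scales (target vessel widths, um).
#' @param min_score,min_separation_um,distal_band_um apex detector settings.
#' @param max_limb_um path-tracing limb limit (um).
#' @param flow_window optical-flow aggregation window (px).
#' @param search_radius_px mosaic registration search half-width.
#' @param alpha significance level for the cohort report.
#' @param seed RNG seed recorded for provenance.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_scale_um = 1, frame_rate_hz = 120,
                            scales_um = c(8, 12, 16), min_score = 0.4,
                            min_separation_um = 50, distal_band_um = 40,
                            max_limb_um = 100, flow_window = 15,
                            search_radius_px = 10, alpha = 0.05, seed = 1) {
  check_pos(pixel_scale_um, "pixel_scale_um")
  check_pos(frame_rate_hz, "frame_rate_hz")
  check_pos(scales_um, "scales_um")
  check_pos(min_separation_um, "min_separation_um")
  check_pos(distal_band_um, "distal_band_um")
  check_pos(max_limb_um, "max_limb_um")
  check_pos(flow_window, "flow_window")
  check_pos(search_radius_px, "search_radius_px")
  if (alpha <= 0 || alpha >= 1) {
    nf_error("nailfold_invalid_parameter", "alpha must be in (0, 1)")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full measurement chain on one digit
#'
#' Mosaics the video, detects and traces every distal-row capillary,
#' measures widths, estimates per-capillary flow, and summarises the six
#' image-level parameters. Per-capillary failures (untraceable path,
#' unmeasurable widths, too few visible frames for flow) are recorded as
#' warnings and the remaining capillaries are kept.
#'
#' @param video a [video_sequence()].
#' @param config a [pipeline_config()].
#' @param digit_id identifier recorded in the result.
#' @return a `digit_result`: `failed`, `metrics` (a `nailfold_metrics` or
#'   NULL), `mosaic`, `paths`, `flows`, `capillaries`, `apices`, `warnings`.
#' @export
run_digit <- function(video, config = pipeline_config(), digit_id = "digit") {
  warnings <- character(0)
  result <- function(failed, metrics = NULL, mosaic = NULL, paths = NULL,
                     flows = NULL, capillaries = NULL, apices = NULL,
                     reason = NULL) {
    structure(list(digit_id = digit_id, failed = failed, reason = reason,
                   metrics = metrics, mosaic = mosaic, paths = paths,
                   flows = flows, capillaries = capillaries, apices = apices,
                   warnings = warnings), class = "digit_result")
  }
  out <- tryCatch({
    mosaic <- compose_mosaic(video, search_radius = config$search_radius_px)
    warnings <- c(warnings, mosaic$registration_warnings)
    ridge <- ridge_map(mosaic$image, config$scales_um,
                       video$pixel_scale_um %||% config$pixel_scale_um)
    apices <- detect_apices(ridge, min_score = config$min_score,
                            min_separation_um = config$min_separation_um,
                            distal_band_um = config$distal_band_um)
    if (nrow(apices) == 0) {
      return(result(TRUE, mosaic = mosaic, apices = apices,
                    reason = "no capillary apices detected"))
    }
    paths <- list(); flows <- list(); caps <- list()
    for (k in seq_len(nrow(apices))) {
      pk <- tryCatch({
        p <- trace_path(ridge, c(apices$x[k], apices$y[k]),
                        max_limb_um = config$max_limb_um)
        measure_widths(mosaic, p)
      }, nailfold_error = function(e) {
        warnings <<- c(warnings,
                       sprintf("%s capillary %d: %s", digit_id, k,
                               conditionMessage(e)))
        NULL
      })
      if (is.null(pk)) next
      fk <- tryCatch(
        capillary_velocity(video, pk, window = config$flow_window,
                           capillary_id = k),
        nailfold_error = function(e) {
          warnings <<- c(warnings,
                         sprintf("%s capillary %d flow: %s", digit_id, k,
                                 conditionMessage(e)))
          NULL
        })
      ck <- tryCatch(summarize_capillary(pk, fk, capillary_id = k),
                     nailfold_error = function(e) {
                       warnings <<- c(warnings,
                                      sprintf("%s capillary %d: %s", digit_id,
                                              k, conditionMessage(e)))
                       NULL
                     })
      if (is.null(ck)) next
      paths[[length(paths) + 1]] <- pk
      if (!is.null(fk)) flows[[length(flows) + 1]] <- fk
      caps[[length(caps) + 1]] <- ck
    }
    if (length(caps) == 0) {
      return(result(TRUE, mosaic = mosaic, apices = apices,
                    reason = "no measurable capillary"))
    }
    scale <- mosaic$pixel_scale_um
    metrics <- summarize_nailfold(
      caps,
      apices_x_um = vapply(caps, function(cm) cm$apex_xy_um[1], 0),
      digit_id = digit_id
    )
    result(FALSE, metrics = metrics, mosaic = mosaic, paths = paths,
           flows = flows, capillaries = caps, apices = apices)
  }, nailfold_error = function(e) {
    result(TRUE, reason = conditionMessage(e))
  })
  out
}

#' Run the pipeline over a cohort and report
#'
#' `manifest` has one row per digit with columns `subject_id`, `group`,
#' `digit_id` and a `video` list-column of [video_sequence()]s (as produced
#' by [phantom_cohort()], or assembled from [read_video_frames()]). Digits
#' are processed independently; a subject with zero successful digits is
#' excluded from the cohort table but kept in the run manifest.
#'
#' @param manifest data.frame as described above.
#' @param config a [pipeline_config()].
#' @return list with `table` (cohort data.frame), `report`
#'   (a [cohort_report()], NULL when fewer than 2 groups survive),
#'   `subjects`, `digit_results`, and `manifest` (per-digit status).
#' @export
run_cohort <- function(manifest, config = pipeline_config()) {
  stopifnot(all(c("subject_id", "group", "digit_id", "video") %in%
                  names(manifest)))
  digit_results <- lapply(seq_len(nrow(manifest)), function(i) {
    run_digit(manifest$video[[i]], config,
              digit_id = sprintf("%s/%s", manifest$subject_id[i],
                                 manifest$digit_id[i]))
  })
  status <- data.frame(
    subject_id = manifest$subject_id,
    digit_id = manifest$digit_id,
    failed = vapply(digit_results, `[[`, TRUE, "failed"),
    n_warnings = vapply(digit_results, function(d) length(d$warnings), 0L),
    stringsAsFactors = FALSE
  )
  subjects <- list()
  for (sid in unique(manifest$subject_id)) {
    rows <- which(manifest$subject_id == sid)
    mets <- Filter(Negate(is.null),
                   lapply(digit_results[rows], `[[`, "metrics"))
    if (length(mets) == 0) next
    subjects[[sid]] <- summarize_subject(mets, sid,
                                         manifest$group[rows[1]])
  }
  tab <- if (length(subjects)) cohort_table(unname(subjects)) else NULL
  report <- NULL
  if (!is.null(tab) && length(unique(tab$group)) >= 2 &&
      all(table(tab$group) >= 2)) {
    report <- cohort_report(tab, alpha = config$alpha)
  }
  list(table = tab, report = report, subjects = subjects,
       digit_results = digit_results, manifest = status)
}

#' Simulate an imaged phantom cohort
#'
#' Builds a digit manifest for [run_cohort()]: for each subject a
#' group-dependent phantom (SSc digits have wider, more tortuous, more
#' deranged, more sparsely spaced capillaries with slower flow than HC/PRP)
#' is generated and rendered to a video sequence per digit. Sized for small
#' demonstration frames; spacing is compressed relative to a full nailfold
#' so several capillaries fit the reduced frame.
#'
#' @param n_per_group subjects per group.
#' @param digits_per_subject rendered digits per subject.
#' @param n_capillaries capillaries per digit.
#' @param frame_shape frame `c(height, width)` px, or NULL (default) to
#'   auto-size each digit's frames around its generated capillaries.
#' @param n_frames frames per video.
#' @param noise_sd frame noise SD.
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, `group`, `digit_id`, list-columns
#'   `video` and `truth`.
#' @export
phantom_cohort <- function(n_per_group = 2, digits_per_subject = 2,
                           n_capillaries = 3, frame_shape = NULL,
                           n_frames = 8, noise_sd = 0.01, seed = 1) {
  prof <- list(
    HC  = list(width = 11.8, vel = 0.311, tort = 0.15, der = 0.18,
               spacing = 110),
    PRP = list(width = 12.7, vel = 0.383, tort = 0.15, der = 0.18,
               spacing = 105),
    SSc = list(width = 15.0, vel = 0.235, tort = 0.35, der = 0.45,
               spacing = 130)
  )
  rows <- list()
  si <- 0
  for (gr in names(prof)) {
    for (s in seq_len(n_per_group)) {
      si <- si + 1
      sid <- sprintf("P%02d", si)
      for (d in seq_len(digits_per_subject)) {
        dseed <- seed + 1000L * si + d
        pg <- prof[[gr]]
        jit <- with_seed(dseed, list(w = rnorm(1, 0, 0.6),
                                     v = rnorm(1, 0, 0.02)))
        spec <- phantom_spec(
          n_capillaries = n_capillaries,
          spacing_um = pg$spacing,
          width_um = max(6, pg$width + jit$w),
          velocity_mm_s = max(0.05, pg$vel + jit$v),
          tortuosity = pg$tort,
          derangement_spread = pg$der,
          frame_shape = frame_shape,
          apex_y_um = 90,
          n_frames = n_frames,
          noise_sd = noise_sd,
          seed = dseed + 7L
        )
        truth <- phantom_truth(spec)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, group = gr, digit_id = sprintf("d%d", d),
          stringsAsFactors = FALSE
        )
        rows[[length(rows)]]$video <- list(render_video(spec, truth))
        rows[[length(rows)]]$truth <- list(truth)
      }
    }
  }
  do.call(rbind, rows)
}
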