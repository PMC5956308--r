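# Circular statistics for axial data and the capillary / nailfold / subject
# summary chain producing the six per-nailfold parameters.

#' Dispersion of axial orientation data
#'
#' Mean resultant length of angle-doubled unit vectors,
#' \eqn{R = |\mathrm{mean}(e^{2i\theta})|}. Orientations are axial
#' (defined modulo \eqn{\pi}); doubling maps them to the full circle so that
#' \eqn{\theta} and \eqn{\theta + \pi} are identical. The score is 1 when all
#' orientations coincide and 0 for a perfectly balanced axial spread. It is
#' used both per capillary (the *shape score*, low for tortuous vessels) and
#' per nailfold on the capillaries' principal orientations (the *derangement
#' score*, low when capillaries point every which way).
#'
#' @param orientations numeric vector of orientations in radians (mod pi).
#' @return a single number in \[0, 1\].
#' @examples
#' circular_dispersion(rep(1.2, 10))       # 1
#' circular_dispersion(c(0, pi / 2))       # 0: axially antipodal
#' circular_dispersion(c(0, 0, pi / 2))    # 1/3
#' @export
circular_dispersion <- function(orientations) {
  if (length(orientations) == 0 || !is.numeric(orientations) ||
      !all(is.finite(orientations))) {
    nf_error("nailfold_invalid_input",
             "`orientations` must be a non-empty finite numeric vector")
  }
  Mod(mean(exp(2i * orientations)))
}

#' Axial circular mean of orientations
#'
#' Half the argument of the mean angle-doubled unit vector, reduced to
#' \[0, pi). This is the principal orientation consistent with
#' [circular_dispersion()]; an arithmetic mean of raw angles is ill-defined
#' for axial data.
#'
#' @inheritParams circular_dispersion
#' @return orientation in \[0, pi).
#' @export
axial_mean_orientation <- function(orientations) {
  if (length(orientations) == 0 || !all(is.finite(orientations))) {
    nf_error("nailfold_invalid_input",
             "`orientations` must be a non-empty finite numeric vector")
  }
  (Arg(mean(exp(2i * orientations))) / 2) %% pi
}

#' Summarise one capillary path
#'
#' Collapses a traced path to per-capillary metrics: mean width over the
#' measurable points, principal orientation (axial circular mean of the path
#' orientations) and shape score (dispersion of the path orientations).
#'
#' @param path a `capillary_path` (see [trace_path()] / [make_capillary_path()]).
#' @param flow optional `capillary_flow` from [capillary_velocity()].
#' @param capillary_id identifier copied into the result.
#' @return a `capillary_metrics` list with fields `capillary_id`,
#'   `mean_width_um`, `principal_orientation`, `shape_score`,
#'   `mean_velocity_mm_s` (NA when `flow` is absent) and `apex_xy_um`.
#' @export
summarize_capillary <- function(path, flow = NULL, capillary_id = 1L) {
  pts <- path$points
  meas <- if (is.null(pts$measurable)) rep(TRUE, nrow(pts)) else pts$measurable
  w <- pts$width_um[meas & is.finite(pts$width_um)]
  if (length(w) < 2) {
    nf_error("nailfold_summary_error",
             sprintf("capillary %s: fewer than 2 measurable width points",
                     capillary_id))
  }
  scale <- path$pixel_scale_um %||% 1
  apex_um <- if (identical(path$units, "px")) path$apex_xy * scale else path$apex_xy
  structure(list(
    capillary_id = capillary_id,
    mean_width_um = mean(w),
    principal_orientation = axial_mean_orientation(pts$orientation),
    shape_score = circular_dispersion(pts$orientation),
    mean_velocity_mm_s = if (is.null(flow)) NA_real_ else flow$mean_velocity_mm_s,
    apex_xy_um = apex_um
  ), class = "capillary_metrics")
}

#' Summarise one nailfold (digit) image
#'
#' Computes the six image-level parameters from the per-capillary metrics:
#' (a) capillary density, apices per millimetre measured from the left-most
#' to the right-most apex (`n / span`); (b) mean width; (c) max width;
#' (d) shape score, the mean of per-capillary shape scores; (e) derangement
#' score, the dispersion of the capillaries' principal orientations;
#' (f) mean flow velocity over capillaries with a valid flow estimate.
#'
#' @param capillaries list of `capillary_metrics`.
#' @param apices_x_um apex x-coordinates in micrometres (defaults to those
#'   stored in `capillaries`).
#' @param digit_id identifier copied into the result.
#' @return a `nailfold_metrics` list with the six parameters, the capillary
#'   count, and a `density_defined` flag (FALSE when fewer than two apices
#'   give no span; the density is then NA and is excluded from
#'   participant-level averaging of density only).
#' @export
summarize_nailfold <- function(capillaries, apices_x_um = NULL,
                               digit_id = "digit") {
  n <- length(capillaries)
  if (n < 1) {
    nf_error("nailfold_invalid_input", "no capillaries to summarise")
  }
  if (is.null(apices_x_um)) {
    apices_x_um <- vapply(capillaries, function(cm) cm$apex_xy_um[1], 0)
  }
  widths <- vapply(capillaries, `[[`, 0, "mean_width_um")
  shapes <- vapply(capillaries, `[[`, 0, "shape_score")
  oris <- vapply(capillaries, `[[`, 0, "principal_orientation")
  flows <- vapply(capillaries, `[[`, 0, "mean_velocity_mm_s")
  density_defined <- n >= 2 && diff(range(apices_x_um)) > 0
  density <- if (density_defined) {
    n / (diff(range(apices_x_um)) / 1000)
  } else {
    NA_real_
  }
  structure(list(
    digit_id = digit_id,
    n_capillaries = n,
    density = density,
    density_defined = density_defined,
    mean_width = mean(widths),
    max_width = max(widths),
    shape = mean(shapes),
    derangement = circular_dispersion(oris),
    flow = if (any(is.finite(flows))) mean(flows[is.finite(flows)]) else NA_real_
  ), class = "nailfold_metrics")
}

#' Aggregate per-digit metrics to one subject
#'
#' Unweighted mean of each parameter over the digits where it is defined;
#' a digit missing flow (or with undefined density) still contributes its
#' other parameters.
#'
#' @param digits list of `nailfold_metrics`.
#' @param subject_id,group subject identifier and group label
#'   (`"HC"`, `"PRP"` or `"SSc"`).
#' @return a `subject_record` with `participant_params`, a named vector of
#'   the six parameters.
#' @export
summarize_subject <- function(digits, subject_id, group) {
  if (length(digits) < 1) {
    nf_error("nailfold_invalid_input", "at least one digit is required")
  }
  params <- vapply(NF_PARAMS, function(p) {
    v <- vapply(digits, function(d) d[[p]] %||% NA_real_, 0)
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  structure(list(
    subject_id = subject_id,
    group = match.arg(group, NF_GROUPS),
    per_digit = digits,
    participant_params = params
  ), class = "subject_record")
}

#' Assemble subject records into a cohort table
#'
#' @param subjects list of `subject_record`s.
#' @return data.frame with columns `subject_id`, `group` and the six
#'   parameter columns (`density`, `mean_width`, `max_width`, `shape`,
#'   `derangement`, `flow`), one row per subject.
#' @export
cohort_table <- function(subjects) {
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) {
    nf_error("nailfold_invalid_input", "duplicated subject_id in cohort")
  }
  df <- data.frame(
    subject_id = ids,
    group = vapply(subjects, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
  for (p in NF_PARAMS) {
    df[[p]] <- vapply(subjects, function(s) s$participant_params[[p]], 0)
  }
  df
}
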