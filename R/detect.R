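# Apex detection, ridge-following path tracing, and perpendicular-profile
# width measurement.

shift_dx <- function(m) {
  nc <- ncol(m)
  0.5 * (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))])
}

shift_dy <- function(m) {
  nr <- nrow(m)
  0.5 * (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ])
}

#' Detect capillary apices
#'
#' An apex is a turning point of the vessel path: a location where the ridge
#' response is high and the ridge orientation field curves rapidly. The
#' detector builds the smoothed doubled-angle orientation field, scores each
#' masked ridge pixel by response x orientation-field curvature, keeps local
#' maxima above `min_score` (relative to the strongest candidate), merges
#' candidates closer than `min_separation_um` keeping the higher score (ties
#' keep the leftmost), refines each apex to the topmost strong-ridge pixel of
#' its turn, restricts to the distal row (a band of half-height
#' `distal_band_um` below the topmost apex), and returns the apices sorted
#' left to right.
#'
#' @param ridge a [ridge_map()].
#' @param min_score relative apexness threshold in \[0, 1\].
#' @param min_separation_um merge radius (um).
#' @param distal_band_um distal-row band half-height (um).
#' @param ridge_frac response mask threshold, relative to the max response.
#' @return data.frame with columns `x`, `y` (0-based px) and `score`,
#'   sorted by increasing `x`; zero rows when nothing is detected.
#' @export
detect_apices <- function(ridge, min_score = 0.4, min_separation_um = 50,
                          distal_band_um = 40, ridge_frac = 0.25) {
  stopifnot(inherits(ridge, "nailfold_ridge"))
  s <- ridge$pixel_scale_um
  R <- ridge$response
  empty <- data.frame(x = numeric(0), y = numeric(0), score = numeric(0))
  rmax <- max(R)
  if (rmax <= 0) return(empty)
  Rn <- R / rmax
  th <- ridge$orientation
  g <- gaussian_kernel2(2 / s)
  Us <- conv2(Rn * cos(2 * th), g)
  Vs <- conv2(Rn * sin(2 * th), g)
  Rs <- conv2(Rn, g)
  ub <- Us / (Rs + 1e-4)
  vb <- Vs / (Rs + 1e-4)
  kappa <- sqrt(shift_dx(ub)^2 + shift_dy(ub)^2 +
                shift_dx(vb)^2 + shift_dy(vb)^2)
  # a turn is interior to the path: the ridge must continue on both sides
  # along the local tangent, which distinguishes it from a limb end (where
  # the orientation field also curves sharply as the response dies)
  d <- max(4, 0.5 * max(ridge$scales_um) / s)
  gx <- matrix(0:(ncol(Rn) - 1), nrow(Rn), ncol(Rn), byrow = TRUE)
  gy <- matrix(0:(nrow(Rn) - 1), nrow(Rn), ncol(Rn))
  ahead <- interp_bilinear(Rn, gx + d * cos(th), gy + d * sin(th))
  behind <- interp_bilinear(Rn, gx - d * cos(th), gy - d * sin(th))
  cont <- pmin(ahead, behind)
  cont[!is.finite(cont)] <- 0
  cont <- matrix(cont, nrow(Rn), ncol(Rn))
  apexness <- conv2(Rn * kappa * cont, g)
  apexness[Rn < ridge_frac] <- 0
  # keep away from image borders where derivatives are unreliable
  b <- 3L
  apexness[c(seq_len(b), nrow(apexness) - seq_len(b) + 1), ] <- 0
  apexness[, c(seq_len(b), ncol(apexness) - seq_len(b) + 1)] <- 0
  amax <- max(apexness)
  if (amax <= 0) return(empty)
  apexness <- apexness / amax

  cand <- which(apexness >= min_score, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cx <- cand[, 2] - 1; cy <- cand[, 1] - 1
  sc <- apexness[cand]
  ord <- order(-sc, cx, cy)
  cx <- cx[ord]; cy <- cy[ord]; sc <- sc[ord]
  min_sep_px <- min_separation_um / s
  keep_x <- keep_y <- keep_s <- numeric(0)
  for (k in seq_along(cx)) {
    if (length(keep_x) == 0 ||
        all((keep_x - cx[k])^2 + (keep_y - cy[k])^2 >= min_sep_px^2)) {
      keep_x <- c(keep_x, cx[k]); keep_y <- c(keep_y, cy[k])
      keep_s <- c(keep_s, sc[k])
    }
  }

  # Refine each candidate to the topmost strong-ridge pixel of its turn.
  rad <- max(12, 1.5 * max(ridge$scales_um)) / s
  for (k in seq_along(keep_x)) {
    x0 <- max(0, round(keep_x[k] - rad)); x1 <- min(ncol(R) - 1, round(keep_x[k] + rad))
    y0 <- max(0, round(keep_y[k] - rad)); y1 <- min(nrow(R) - 1, round(keep_y[k] + rad))
    sub <- Rn[(y0:y1) + 1, (x0:x1) + 1, drop = FALSE]
    strong <- which(sub >= 0.6 * max(sub), arr.ind = TRUE)
    top <- strong[strong[, 1] <= min(strong[, 1]) + 1, , drop = FALSE]
    keep_y[k] <- y0 + mean(top[, 1]) - 1
    keep_x[k] <- x0 + mean(top[, 2]) - 1
  }
  # refinement can collapse neighbouring candidates onto one turn: re-merge
  ord <- order(-keep_s, keep_x, keep_y)
  keep_x <- keep_x[ord]; keep_y <- keep_y[ord]; keep_s <- keep_s[ord]
  fx <- fy <- fs <- numeric(0)
  for (k in seq_along(keep_x)) {
    if (length(fx) == 0 ||
        all((fx - keep_x[k])^2 + (fy - keep_y[k])^2 >= min_sep_px^2)) {
      fx <- c(fx, keep_x[k]); fy <- c(fy, keep_y[k]); fs <- c(fs, keep_s[k])
    }
  }
  # distal row: keep apices within a band below the topmost apex
  band <- fy <= min(fy) + distal_band_um / s
  fx <- fx[band]; fy <- fy[band]; fs <- fs[band]
  ord <- order(fx)
  data.frame(x = fx[ord], y = fy[ord], score = fs[ord])
}

ridge_orientation_at <- function(ridge, x, y) {
  u <- interp_bilinear(cos(2 * ridge$orientation) * ridge$response, x, y)
  v <- interp_bilinear(sin(2 * ridge$orientation) * ridge$response, x, y)
  (0.5 * atan2(v, u)) %% pi
}

#' Trace a capillary path from its apex
#'
#' Bidirectional steepest-ridge following: starting at the apex, steps of
#' `step_um` arc length are taken along the local ridge orientation (sign
#' chosen for continuity), each step re-centred onto the ridge crest by a
#' parabolic fit of the response across the path. Each branch stops at
#' `max_limb_um` arc length from the apex, at the image border, or when the
#' response drops below `stop_frac` of the apex response.
#'
#' @param ridge a [ridge_map()].
#' @param apex `c(x, y)` in 0-based px (e.g. one row of [detect_apices()]).
#' @param max_limb_um maximum limb arc length from the apex (um).
#' @param stop_frac response stop fraction relative to the apex response.
#' @param step_um arc-length step (um).
#' @return a `capillary_path` with `units = "px"`: ordered `points`
#'   (`x`, `y`, `orientation`, `width_um` = NA until [measure_widths()],
#'   `arc_from_apex` in um), `apex_xy`, `apex_index`, `limb_arc_lengths`
#'   (um), `detection_score`.
#' @export
trace_path <- function(ridge, apex, max_limb_um = 100, stop_frac = 0.25,
                       step_um = 1) {
  stopifnot(inherits(ridge, "nailfold_ridge"))
  s <- ridge$pixel_scale_um
  R <- ridge$response
  r0 <- interp_bilinear(R, apex[1], apex[2])
  if (!is.finite(r0) || r0 < 0.05 * max(R)) {
    nf_error("nailfold_trace_error",
             sprintf("apex (%.1f, %.1f) is not on a ridge", apex[1], apex[2]))
  }
  step_px <- step_um / s
  th0 <- ridge_orientation_at(ridge, apex[1], apex[2])

  branch <- function(sign0) {
    d <- sign0 * c(cos(th0), sin(th0))
    p <- apex
    arc <- 0
    xs <- ys <- os <- as_ <- numeric(0)
    while (arc < max_limb_um - 1e-9) {
      th <- ridge_orientation_at(ridge, p[1], p[2])
      if (!is.finite(th)) break
      dd <- c(cos(th), sin(th))
      if (sum(dd * d) < 0) dd <- -dd
      pn <- p + step_px * dd
      pp <- c(-dd[2], dd[1])
      off <- seq(-1.5, 1.5, by = 0.5)
      prof <- interp_bilinear(R, pn[1] + off * pp[1], pn[2] + off * pp[2])
      if (all(is.finite(prof))) {
        i <- which.max(prof)
        delta <- off[i]
        if (i > 1 && i < length(prof)) {
          delta <- delta + 0.5 * parabolic_peak(prof[i - 1], prof[i],
                                                prof[i + 1])
        }
        pn <- pn + delta * pp
      }
      rv <- interp_bilinear(R, pn[1], pn[2])
      if (!is.finite(rv) || rv < stop_frac * r0) break
      arc <- arc + sqrt(sum((pn - p)^2)) * s
      d <- (pn - p) / sqrt(sum((pn - p)^2))
      p <- pn
      xs <- c(xs, p[1]); ys <- c(ys, p[2])
      os <- c(os, ridge_orientation_at(ridge, p[1], p[2]))
      as_ <- c(as_, arc)
    }
    list(x = xs, y = ys, ori = os, arc = as_)
  }
  b1 <- branch(-1)
  b2 <- branch(1)
  n1 <- length(b1$x)
  pts <- data.frame(
    x = c(rev(b1$x), apex[1], b2$x),
    y = c(rev(b1$y), apex[2], b2$y),
    orientation = c(rev(b1$ori), th0, b2$ori),
    width_um = NA_real_,
    arc_from_apex = c(-rev(b1$arc), 0, b2$arc)
  )
  structure(list(
    points = pts,
    apex_xy = c(apex[1], apex[2]),
    apex_index = n1 + 1L,
    limb_arc_lengths = c(arterial = if (n1) max(b1$arc) else 0,
                         venous = if (length(b2$arc)) max(b2$arc) else 0),
    detection_score = r0,
    units = "px",
    pixel_scale_um = s
  ), class = "capillary_path")
}

#' Measure per-point capillary width
#'
#' At each path point the intensity profile is sampled perpendicular to the
#' local orientation; the width is the full width at half the profile depth
#' (depth = background minus the profile minimum, background estimated as a
#' high quantile of the profile), converted to micrometres. This matches the
#' phantom renderer's width definition. Points whose profile is truncated by
#' the image border, or where no half-depth crossing exists, are flagged
#' non-measurable and excluded from summaries.
#'
#' @param mosaic a `nailfold_mosaic` or a plain image matrix.
#' @param path a `capillary_path` in px units (from [trace_path()]).
#' @param pixel_scale_um used when `mosaic` is a plain matrix.
#' @param profile_halfwidth_um half-length of the sampled profile (um).
#' @return the path with `points$width_um` filled and `points$measurable`
#'   set. Raises `nailfold_width_error` when more than half the points are
#'   non-measurable.
#' @export
measure_widths <- function(mosaic, path, pixel_scale_um = NULL,
                           profile_halfwidth_um = 40) {
  img <- if (inherits(mosaic, "nailfold_mosaic")) mosaic$image else mosaic
  s <- if (inherits(mosaic, "nailfold_mosaic")) mosaic$pixel_scale_um
       else pixel_scale_um %||% path$pixel_scale_um %||% 1
  pts <- path$points
  hw <- profile_halfwidth_um / s
  off <- seq(-hw, hw, by = 0.25)
  n <- nrow(pts)
  widths <- rep(NA_real_, n)
  meas <- rep(FALSE, n)
  ctr_i <- which(abs(off) <= hw / 2)
  for (k in seq_len(n)) {
    thk <- pts$orientation[k]
    ppx <- -sin(thk); ppy <- cos(thk)
    prof <- interp_bilinear(img, pts$x[k] + off * ppx, pts$y[k] + off * ppy)
    if (anyNA(prof)) next
    prof <- as.numeric(stats::filter(prof, rep(1 / 3, 3), sides = 2))
    prof[1] <- prof[2]; prof[length(prof)] <- prof[length(prof) - 1]
    bg <- quantile(prof, 0.95, names = FALSE)
    imin <- ctr_i[which.min(prof[ctr_i])]
    depth <- bg - prof[imin]
    if (depth < 0.02) next
    half <- prof[imin] + depth / 2
    il <- imin
    while (il > 1 && prof[il] < half) il <- il - 1
    ir <- imin
    while (ir < length(prof) && prof[ir] < half) ir <- ir + 1
    if (prof[il] < half || prof[ir] < half) next
    fl <- (half - prof[il]) / (prof[il + 1] - prof[il])
    oL <- off[il] + fl * 0.25
    fr <- (half - prof[ir - 1]) / (prof[ir] - prof[ir - 1])
    oR <- off[ir - 1] + fr * 0.25
    widths[k] <- (oR - oL) * s
    meas[k] <- TRUE
  }
  if (mean(meas) < 0.5) {
    nf_error("nailfold_width_error",
             "more than half of the path points are non-measurable")
  }
  path$points$width_um <- widths
  path$points$measurable <- meas
  path
}
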