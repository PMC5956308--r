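# Multiscale second-derivative ridge filtering: the vessel detector that
# drives apex detection and path tracing.

#' Multiscale ridge (vesselness) map
#'
#' Convolves the mosaic with Gaussian second-derivative kernels at each
#' scale, takes the larger Hessian eigenvalue (positive across a dark tube),
#' gamma-normalises by sigma^2 and keeps the per-pixel maximum over scales.
#' The ridge orientation is the eigenvector direction of the smaller
#' eigenvalue, i.e. the along-vessel direction, reduced mod pi.
#'
#' @param image 2D grayscale matrix (a mosaic image; rows = y), or a
#'   `nailfold_mosaic`.
#' @param scales_um target vessel widths to respond to (um).
#' @param pixel_scale_um micrometres per pixel (taken from the mosaic if one
#'   is supplied).
#' @return a `nailfold_ridge`: `response` (>= 0), `orientation`
#'   (radians in \[0, pi)), `scale_map` (best-responding width per px, um),
#'   `scales_um`, `pixel_scale_um`.
#' @export
ridge_map <- function(image, scales_um = c(8, 12, 16), pixel_scale_um = 1) {
  if (inherits(image, "nailfold_mosaic")) {
    pixel_scale_um <- image$pixel_scale_um
    image <- image$image
  }
  check_pos(scales_um, "scales_um")
  check_pos(pixel_scale_um, "pixel_scale_um")
  best <- matrix(0, nrow(image), ncol(image))
  ori <- matrix(0, nrow(image), ncol(image))
  smap <- matrix(scales_um[1], nrow(image), ncol(image))
  for (w in scales_um) {
    sigma <- w * FWHM_TO_SIGMA / pixel_scale_um
    k <- hessian_kernels(sigma)
    hxx <- conv2(image, k$xx)
    hyy <- conv2(image, k$yy)
    hxy <- conv2(image, k$xy)
    disc <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
    l1 <- 0.5 * ((hxx + hyy) + disc)
    resp <- sigma^2 * pmax(l1, 0)
    th <- (0.5 * atan2(2 * hxy, hxx - hyy) + pi / 2) %% pi
    upd <- resp > best
    best[upd] <- resp[upd]
    ori[upd] <- th[upd]
    smap[upd] <- w
  }
  structure(list(response = best, orientation = ori, scale_map = smap,
                 scales_um = scales_um, pixel_scale_um = pixel_scale_um),
            class = "nailfold_ridge")
}
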