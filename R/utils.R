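# Internal helpers: conditions, seeded evaluation, image primitives.

`%||%` <- function(a, b) if (is.null(a)) b else a

nf_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "nailfold_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

check_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    (if (allow_zero) all(x >= 0) else all(x > 0))
  if (!ok) {
    nf_error("nailfold_invalid_parameter",
             sprintf("`%s` must be %s", name,
                     if (allow_zero) "finite and >= 0" else "finite and > 0"))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 2D convolution with replicated borders (FFT-based).
conv2 <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

gaussian_kernel1 <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g / sum(g)
}

gaussian_kernel2 <- function(sigma) {
  g <- gaussian_kernel1(sigma)
  outer(g, g)
}

# Gaussian second-derivative (Hessian) kernels; rows index y, columns x.
hessian_kernels <- function(sigma) {
  r <- max(2L, ceiling(3.5 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- (-x / sigma^2) * g
  g2 <- (x^2 / sigma^2 - 1) / sigma^2 * g
  list(xx = outer(g, g2), yy = outer(g2, g), xy = outer(g1, g1))
}

# Bilinear interpolation at 0-based (x, y); NA outside the image.
interp_bilinear <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 0 & y >= 0 & x <= nc - 1 & y <= nr - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- cbind(y0 + 1, x0 + 1)
  v00 <- img[i0]
  v01 <- img[cbind(y0 + 1, x0 + 2)]
  v10 <- img[cbind(y0 + 2, x0 + 1)]
  v11 <- img[cbind(y0 + 2, x0 + 2)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

# Sum over a (2r+1)^2 window centred at each pixel, truncated at the borders.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  hi_r <- pmin(seq_len(nr) + r, nr); lo_r <- pmax(seq_len(nr) - r - 1, 0)
  hi_c <- pmin(seq_len(nc) + r, nc); lo_c <- pmax(seq_len(nc) - r - 1, 0)
  S[hi_r + 1, hi_c + 1] - S[lo_r + 1, hi_c + 1] -
    S[hi_r + 1, lo_c + 1] + S[lo_r + 1, lo_c + 1]
}

box_count <- function(nr, nc, r) {
  box_sum(matrix(1, nr, nc), r)
}

downsample2 <- function(m) {
  nr <- 2 * (nrow(m) %/% 2); nc <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  0.25 * (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
          m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)])
}

# Nearest-neighbour upsampling to an exact target size.
upsample_to <- function(m, nr, nc) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(nr) / nr * nrow(m))))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(nc) / nc * ncol(m))))
  m[ri, ci, drop = FALSE]
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
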