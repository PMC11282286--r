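# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one top-level seed through named
#' substreams (traces, noise, texture, layer, ...), so that a whole experiment
#' is reproducible from a single integer while its parts stay statistically
#' independent.
#'
#' @param seed master integer seed.
#' @param name character stream name.
#' @param index optional integer (e.g. source index) further separating streams.
#' @return an integer seed in [0, 2^31 - 1).
#' @keywords internal
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 2654435 + h * 97 + index * 7919) %% 2147483647)
}

#' Evaluate an expression with a local RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Pixel-center coordinate grids for a square image. The fiber axis sits at the
# image center; x increases with column index, y increases with row index, and
# azimuth is measured counterclockwise from +x.
pixel_grid <- function(image_size, half_width) {
  px <- (seq_len(image_size) - (image_size + 1) / 2) * (2 * half_width / image_size)
  list(
    x = matrix(px, image_size, image_size, byrow = TRUE),
    y = matrix(px, image_size, image_size, byrow = FALSE)
  )
}

# Separable Gaussian blur via explicit band matrices (replicate-free: kernel
# renormalized at the borders so constants are preserved).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K[abs(row(K) - col(K)) > half] <- 0
  K <- K / rowSums(K)
  K %*% img %*% t(K)
}

# Bilinear sampling of img at fractional (row, col) positions; outside the
# image the nearest border value is used.
bilinear_sample <- function(img, rr, cc) {
  n <- nrow(img); m <- ncol(img)
  rr <- as.vector(pmin(pmax(rr, 1), n))
  cc <- as.vector(pmin(pmax(cc, 1), m))
  r0 <- pmin(floor(rr), n - 1L); c0 <- pmin(floor(cc), m - 1L)
  fr <- rr - r0; fc <- cc - c0
  v <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  matrix(v, n, m)
}

# Azimuthal symmetry score of an image about its center: Pearson correlation
# between the image and its azimuthally averaged (radially symmetric) version.
# 1 for a perfectly symmetric pattern, lower as azimuthal structure appears.
azimuthal_symmetry_score <- function(img) {
  n <- nrow(img)
  g <- pixel_grid(n, half_width = 1)
  r <- sqrt(g$x^2 + g$y^2)
  rb <- round(r * n / 2)
  mu <- tapply(as.vector(img), as.vector(rb), mean)
  sym <- matrix(mu[as.character(rb)], n, n)
  suppressWarnings(cc <- stats::cor(as.vector(img), as.vector(sym)))
  if (is.na(cc)) 1 else cc
}

# Pearson correlation that maps degenerate (constant) inputs to 0 with a
# warning instead of NA.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant trace encountered; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}
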