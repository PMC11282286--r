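#' Distal source position
#'
#' Position of a point-like fluorescent source (bead or soma) at the distal
#' fiber facet, in polar coordinates about the fiber axis.
#'
#' @param d radial offset from the fiber axis, micrometers (>= 0).
#' @param azimuth azimuthal angle in radians, counterclockwise from +x.
#' @param diameter source diameter in micrometers (default 10, bead-like).
#' @return an object of class `source_position`.
#' @export
source_position <- function(d, azimuth = 0, diameter = 10) {
  stopifnot(d >= 0, diameter > 0)
  structure(list(d = d, azimuth = azimuth, diameter = diameter),
            class = "source_position")
}

new_fingerprint <- function(image, ring_radius, out_of_fov = FALSE) {
  stopifnot(all(image >= 0), ring_radius >= 0)
  structure(list(image = image, ring_radius = ring_radius,
                 out_of_fov = out_of_fov),
            class = "fingerprint_pattern")
}

#' @export
print.fingerprint_pattern <- function(x, ...) {
  cat(sprintf("fingerprint %dx%d, ring radius %.1f px%s\n",
              nrow(x$image), ncol(x$image), x$ring_radius,
              if (x$out_of_fov) " (out of FoV)" else ""))
  invisible(x)
}

# Intensity-weighted mean radius (in pixels from image center); descriptor of
# how far out the bright ring sits.
measured_ring_radius <- function(image) {
  n <- nrow(image)
  g <- pixel_grid(n, half_width = n / 2)
  r <- sqrt(g$x^2 + g$y^2)
  s <- sum(image)
  if (s <= 0) return(0)
  sum(image * r) / s
}

#' Physical fingerprint of a point source through a step-index fiber
#'
#' Forward model for the scattering fingerprint: the point source excites
#' each guided LP mode in proportion to the mode field at the source
#' position; every mode then accumulates its own propagation phase
#' `beta(lambda) * L` over the fiber length, and the proximal-facet intensity
#' is averaged incoherently over wavelengths across the emission band
#' (fluorescence is incoherent; the averaging washes out fine speckle and
#' leaves the smooth spiral-ring structure). Sources farther from the axis
#' excite higher-order modes whose power concentrates near the core edge, so
#' the bright ring radius grows with the source offset d.
#'
#' @param fiber a [fiber_spec()].
#' @param pos a [source_position()].
#' @param image_size output image side length in pixels.
#' @param n_wavelengths number of equally spaced wavelength samples across
#'   the fiber bandwidth (default 11).
#' @param seed integer seed for the fiber's static per-mode phase disorder
#'   (a given seed is one physical fiber; use one seed per experiment).
#' @param phase_disorder standard deviation (radians) of the static random
#'   phase added to each mode group, emulating index inhomogeneity of a real
#'   fiber. 0 gives the ideal fiber.
#' @param modes optional precomputed [solve_lp_modes()] result for `fiber`,
#'   to amortize the mode solve across many sources.
#' @return a `fingerprint_pattern` with the proximal intensity image (peak
#'   normalized to the coupled power), the measured ring-radius descriptor,
#'   and an out-of-FoV flag for sources beyond 1.1x the core radius.
#' @export
fingerprint_physical <- function(fiber, pos, image_size = 48,
                                 n_wavelengths = 11, seed = 0,
                                 phase_disorder = 0.3, modes = NULL) {
  stopifnot(n_wavelengths >= 1, image_size >= 16)
  if (is.null(modes)) modes <- solve_lp_modes(fiber)
  a <- fiber$core_radius
  out_of_fov <- pos$d > 1.1 * a

  half <- 1.3 * a
  g <- pixel_grid(image_size, half)
  r <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x)

  radius <- attr(modes, "radius")
  profiles <- attr(modes, "profiles")
  nm <- nrow(modes)

  # static fiber disorder: one phase per LP(l, m) group (shared by the cos /
  # sin orientation pair, so the ideal cylindrical symmetry of the ensemble
  # is preserved and rotating the source rotates the pattern)
  dphi <- with_seed(substream_seed(seed, "mode_phase"),
                    stats::rnorm(nm, 0, phase_disorder))

  # mode field at the source radius (linear interpolation of the profile)
  src_amp <- vapply(seq_len(nm), function(i) {
    stats::approx(radius, profiles[, i], xout = min(pos$d, max(radius)),
                  rule = 2)$y
  }, numeric(1))

  # wavelength samples across the band; the core parameter u is held fixed
  # (its dispersion across a 30 nm band is negligible next to beta * L)
  lams <- if (n_wavelengths == 1) fiber$center_wavelength else
    seq(fiber$center_wavelength - fiber$bandwidth / 2,
        fiber$center_wavelength + fiber$bandwidth / 2,
        length.out = n_wavelengths)

  n1 <- fiber$refractive_index_core
  L_um <- fiber$length_mm * 1e3

  # transverse profiles on the pixel grid, evaluated once
  prof_px <- vapply(seq_len(nm), function(i) {
    stats::approx(radius, profiles[, i], xout = pmin(r, max(radius)),
                  rule = 2)$y
  }, numeric(image_size^2))
  lmat <- modes$l

  intensity <- matrix(0, image_size, image_size)
  for (lam in lams) {
    k <- 2 * pi / lam
    beta <- sqrt(pmax((k * n1)^2 - (modes$u / a)^2, 0))
    ph <- (beta * L_um + dphi) %% (2 * pi)
    coef <- complex(modulus = 1, argument = ph)
    # cos and sin orientations: coupling = profile(d) * {cos, sin}(l * az)
    cc <- src_amp * cos(lmat * pos$azimuth) * coef
    cs <- src_amp * sin(lmat * pos$azimuth) * coef
    field <- matrix(0 + 0i, image_size, image_size)
    # accumulate per azimuthal order to reuse cos(l*phi)/sin(l*phi)
    for (lv in unique(lmat)) {
      sel <- which(lmat == lv)
      amp_c <- matrix(prof_px[, sel, drop = FALSE] %*% cc[sel],
                      image_size, image_size)
      field <- field + amp_c * cos(lv * phi)
      if (lv > 0) {
        amp_s <- matrix(prof_px[, sel, drop = FALSE] %*% cs[sel],
                        image_size, image_size)
        field <- field + amp_s * sin(lv * phi)
      }
    }
    intensity <- intensity + Mod(field)^2
  }
  intensity <- intensity / n_wavelengths
  new_fingerprint(intensity, measured_ring_radius(intensity), out_of_fov)
}

#' Phenomenological spiral-ring fingerprint
#'
#' Fast generative model of the short-fiber scattering fingerprint that
#' reproduces its documented geometry without solving modes: (i) a bright
#' ring whose radius rho is a monotone nondecreasing map of the source
#' offset d (rho = 0 at d = 0, a central blob); (ii) a central bright
#' doublet aligned with the source azimuth; (iii) spiral-arm modulation; and
#' (iv) a seeded multiplicative speckle texture unique to each source, which
#' is what makes fingerprints of equidistant sources distinguishable.
#' Sources beyond ~1.1x the core radius are attenuated by a smooth roll-off
#' (they couple progressively less light into the core).
#'
#' @param pos a [source_position()].
#' @param image_size output side length in pixels (>= 32).
#' @param texture_seed integer seed for the per-source speckle texture.
#' @param core_radius distal core radius in micrometers used to scale d
#'   (default 12.5, the scaled fiber).
#' @return a `fingerprint_pattern`; its `ring_radius` field is the model
#'   parameter rho(d) in pixels.
#' @export
fingerprint_phenomenological <- function(pos, image_size = 48,
                                         texture_seed = 0,
                                         core_radius = 12.5) {
  stopifnot(image_size >= 32)
  a <- core_radius
  rel <- pos$d / a                      # 0 at axis, 1 at core edge
  out_of_fov <- rel > 1.1

  r_core_px <- image_size / 2 / 1.3     # core edge in pixels
  rho <- r_core_px * 0.9 * min(rel, 1.25)

  g <- pixel_grid(image_size, image_size / 2)
  r <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x)

  sigma_ring <- 0.09 * image_size
  ring <- exp(-(r - rho)^2 / (2 * sigma_ring^2))

  # central doublet along the source azimuth
  rd <- 0.07 * image_size
  wd <- 0.035 * image_size
  cx <- rd * cos(pos$azimuth); cy <- rd * sin(pos$azimuth)
  doublet <- exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * wd^2)) +
    exp(-((g$x + cx)^2 + (g$y + cy)^2) / (2 * wd^2))

  # spiral-arm modulation winding off the azimuth
  n_arm <- 2
  k_sp <- 2.5 / r_core_px * (0.5 + rel)
  spiral <- 1 + 0.35 * cos(n_arm * (phi - pos$azimuth) - k_sp * n_arm * r)

  base <- (ring + 1.2 * doublet) * spiral

  # seeded multiplicative speckle texture, smooth at ~5% of the image scale
  z <- with_seed(substream_seed(texture_seed, "texture"),
                 matrix(stats::rnorm(image_size^2), image_size, image_size))
  z <- gaussian_blur(z, sigma = 0.035 * image_size)
  tex <- exp(1.1 * z / stats::sd(z))
  tex <- tex / mean(tex)

  aperture <- exp(-(r / (1.08 * r_core_px))^8)
  rolloff <- 1 / (1 + exp((rel - 1.15) / 0.03))

  img <- base * tex * aperture * rolloff
  img[img < 0] <- 0
  new_fingerprint(img, rho, out_of_fov)
}

#' Apply a thin scattering layer to a fingerprint
#'
#' Emulates a scattering film (e.g. a ~120 um plastic-paraffin layer, a
#' stand-in for a comparable depth of brain tissue) between the sources and
#' the fiber: a seeded smooth random distortion field warps the pattern,
#' its contrast is reduced, and a diffuse pedestal is added. At strength 0
#' the input is returned unchanged; increasing strength increasingly breaks
#' the residual azimuthal symmetry of on-axis fingerprints.
#'
#' @param pattern a `fingerprint_pattern` (or plain nonnegative matrix).
#' @param layer_seed integer seed identifying the physical layer; the same
#'   seed gives the same distortion, so one layer is shared by all sources
#'   of an experiment.
#' @param strength nonnegative scattering strength (default 1, the
#'   calibrated film).
#' @return a `fingerprint_pattern` of the same size.
#' @export
apply_scattering_layer <- function(pattern, layer_seed = 0, strength = 1) {
  stopifnot(strength >= 0)
  img <- if (inherits(pattern, "fingerprint_pattern")) pattern$image else pattern
  if (strength == 0) {
    return(if (inherits(pattern, "fingerprint_pattern")) pattern
           else new_fingerprint(img, measured_ring_radius(img)))
  }
  n <- nrow(img)
  corr_px <- 0.05 * 2 * (n / 2 / 1.3)   # correlation length: 5% of core diameter
  amp <- strength * 0.05 * n
  disp <- with_seed(substream_seed(layer_seed, "layer"), {
    dx <- gaussian_blur(matrix(stats::rnorm(n^2), n, n), corr_px)
    dy <- gaussian_blur(matrix(stats::rnorm(n^2), n, n), corr_px)
    list(dx = dx / stats::sd(dx), dy = dy / stats::sd(dy))
  })
  rr <- matrix(seq_len(n), n, n) + amp * disp$dy
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) + amp * disp$dx
  warped <- bilinear_sample(img, rr, cc)

  mixfrac <- 0.3 * min(strength, 1)
  pedestal <- gaussian_blur(warped, sigma = 0.15 * n)
  out <- (1 - mixfrac) * warped + mixfrac * pedestal
  out[out < 0] <- 0
  oofv <- if (inherits(pattern, "fingerprint_pattern")) pattern$out_of_fov else FALSE
  new_fingerprint(out, measured_ring_radius(out), oofv)
}
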