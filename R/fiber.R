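#' Step-index multimode fiber specification
#'
#' Describes the geometry and optics of the short step-index multimode fiber
#' that relays fluorescence from the sample to the camera. The hardware fiber
#' (NA 0.39, 200 um core, 8 mm long) guides on the order of 1e4 modes, far
#' beyond desk-scale simulation; the default spec is therefore a scaled-down
#' fiber (12.5 um core radius, NA 0.22, V ~ 33, ~270 guided modes counting
#' orientation pairs) that preserves the spiral-ring fingerprint morphology.
#'
#' @param numerical_aperture fiber NA, in (0, 1).
#' @param core_radius core radius in micrometers.
#' @param length_mm fiber length in millimeters.
#' @param center_wavelength emission center wavelength in micrometers
#'   (default 0.518, green fluorescent bead emission).
#' @param bandwidth emission bandwidth in micrometers used for incoherent
#'   wavelength averaging.
#' @param refractive_index_core core refractive index.
#' @return an object of class `fiber_spec`.
#' @examples
#' f <- fiber_spec()
#' fiber_v_number(f)
#' @export
fiber_spec <- function(numerical_aperture = 0.22,
                       core_radius = 12.5,
                       length_mm = 8,
                       center_wavelength = 0.518,
                       bandwidth = 0.030,
                       refractive_index_core = 1.46) {
  stopifnot(
    numerical_aperture > 0, numerical_aperture < 1,
    core_radius > 0, length_mm > 0,
    center_wavelength > 0, bandwidth >= 0,
    refractive_index_core > 1
  )
  structure(
    list(
      numerical_aperture = numerical_aperture,
      core_radius = core_radius,
      length_mm = length_mm,
      center_wavelength = center_wavelength,
      bandwidth = bandwidth,
      refractive_index_core = refractive_index_core
    ),
    class = "fiber_spec"
  )
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf(
    "Step-index fiber: NA %.2f, core radius %.1f um, length %.1f mm, V = %.1f\n",
    x$numerical_aperture, x$core_radius, x$length_mm, fiber_v_number(x)
  ))
  invisible(x)
}

#' Normalized frequency (V-number) of a step-index fiber
#'
#' V = 2 * pi * a * NA / lambda. The V-number sets the guided mode count
#' (approximately V^2 / 4 modes per polarization, counting both orientations
#' of each azimuthal order).
#'
#' @param fiber a [fiber_spec()].
#' @param wavelength wavelength in micrometers; defaults to the fiber's
#'   center wavelength.
#' @return the dimensionless V-number.
#' @export
fiber_v_number <- function(fiber, wavelength = fiber$center_wavelength) {
  2 * pi * fiber$core_radius * fiber$numerical_aperture / wavelength
}

# Zeros of J_l on (0, upper) by sign-change scan + uniroot refinement.
bessel_j_zeros <- function(l, upper, n_grid = 4096) {
  u <- seq(1e-9, upper, length.out = n_grid)
  f <- besselJ(u, l)
  s <- which(f[-1] * f[-length(f)] < 0)
  vapply(s, function(i) {
    stats::uniroot(function(z) besselJ(z, l), c(u[i], u[i + 1]),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Solve the guided LP modes of a step-index fiber
#'
#' Finds every linearly polarized (LP) mode guided by the fiber under the
#' weakly guiding approximation, by solving the LP dispersion relation
#' `u J_{l+1}(u) / J_l(u) = w K_{l+1}(w) / K_l(w)` with `u^2 + w^2 = V^2`
#' for each azimuthal order l. Between consecutive zeros of J_l there is at
#' most one root, which brackets the search.
#'
#' @param fiber a [fiber_spec()].
#' @param v_ceiling maximum admissible V-number (the mode count grows like
#'   V^2/4; above the ceiling the simulation is no longer desk-scale and an
#'   error asks for a scaled-down fiber).
#' @param n_radial_samples number of radius samples for the stored radial
#'   profile of each mode.
#' @return a data frame of class `lp_mode_set` with one row per LP(l, m)
#'   mode: azimuthal order `l`, radial order `m`, core parameter `u`,
#'   cladding parameter `w`, normalized propagation parameter
#'   `b = 1 - (u/V)^2`, plus attributes `radius` (sample radii, um) and
#'   `profiles` (matrix of radial profiles, one column per mode, normalized
#'   to unit peak).
#' @examples
#' modes <- solve_lp_modes(fiber_spec(core_radius = 2, numerical_aperture = 0.08,
#'                                    center_wavelength = 0.518))
#' nrow(modes)  # few-mode fiber
#' @export
solve_lp_modes <- function(fiber, v_ceiling = 40, n_radial_samples = 256) {
  V <- fiber_v_number(fiber)
  if (!is.finite(V) || V <= 0) {
    stop("degenerate fiber: V-number must be positive")
  }
  if (V > v_ceiling) {
    stop(sprintf(
      paste0("V = %.1f exceeds the desk-scale ceiling (%.0f); ",
             "scale the fiber down (smaller core radius or NA) or raise ",
             "`v_ceiling` explicitly"), V, v_ceiling))
  }
  a <- fiber$core_radius
  rows <- list()
  l <- 0L
  repeat {
    # dispersion mismatch; poles of the J-ratio are avoided by bracketing
    # between consecutive zeros of J_l
    disp <- function(u) {
      w <- sqrt(pmax(V^2 - u^2, 1e-300))
      u * besselJ(u, l + 1) / besselJ(u, l) -
        w * besselK(w, l + 1) / besselK(w, l)
    }
    jz <- bessel_j_zeros(l, V)
    brackets <- unique(c(1e-9, jz[jz < V], V - 1e-9))
    roots <- c()
    if (length(brackets) >= 2) {
      for (i in seq_len(length(brackets) - 1)) {
        lo <- brackets[i] + 1e-9
        hi <- brackets[i + 1] - 1e-9
        if (hi <= lo) next
        flo <- disp(lo); fhi <- disp(hi)
        if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0) {
          roots <- c(roots, stats::uniroot(disp, c(lo, hi), tol = 1e-10)$root)
        }
      }
    }
    if (length(roots) == 0) {
      if (l == 0L) break  # no guided modes at all cannot happen for V > 0
      break
    }
    for (m in seq_along(roots)) {
      rows[[length(rows) + 1]] <- data.frame(
        l = l, m = m, u = roots[m],
        w = sqrt(V^2 - roots[m]^2),
        b = 1 - (roots[m] / V)^2
      )
    }
    l <- l + 1L
  }
  modes <- do.call(rbind, rows)
  modes <- modes[order(-modes$b), , drop = FALSE]
  rownames(modes) <- NULL

  radius <- seq(0, 1.3 * a, length.out = n_radial_samples)
  profiles <- vapply(seq_len(nrow(modes)), function(i) {
    lp_radial_profile(radius, modes$l[i], modes$u[i], modes$w[i], a)
  }, numeric(n_radial_samples))
  attr(modes, "radius") <- radius
  attr(modes, "profiles") <- profiles
  attr(modes, "fiber") <- fiber
  attr(modes, "V") <- V
  class(modes) <- c("lp_mode_set", "data.frame")
  modes
}

# Transverse radial profile of an LP(l, m) mode, continuous at the core
# boundary and normalized to unit maximum magnitude.
lp_radial_profile <- function(r, l, u, w, a) {
  inside <- r <= a
  prof <- numeric(length(r))
  ja <- besselJ(u, l)
  ka <- besselK(w, l)
  prof[inside] <- besselJ(u * r[inside] / a, l)
  prof[!inside] <- ja / ka * besselK(w * r[!inside] / a, l)
  prof / max(abs(prof))
}

#' Core-output intensity and per-bead excitation power
#'
#' Converts an optical power measured at the distal fiber facet into an
#' excitation intensity over the core area and into the power intercepted by
#' a fluorescent bead of given diameter.
#'
#' @param fiber a [fiber_spec()] (only the core radius is used).
#' @param power_at_distal_uW power at the distal facet in microwatts.
#' @param bead_diameter bead diameter in micrometers (default 10).
#' @return a list with `core_area_mm2`, `intensity_mW_mm2`, and
#'   `power_per_bead_mW`.
#' @examples
#' # 9.5 uW over a 200 um core -> ~0.30 mW/mm^2 and ~2.4e-5 mW per 10 um bead
#' fiber_geometry_summary(fiber_spec(core_radius = 100), 9.5)
#' @export
fiber_geometry_summary <- function(fiber, power_at_distal_uW,
                                   bead_diameter = 10) {
  if (fiber$core_radius <= 0) stop("core radius must be positive")
  if (power_at_distal_uW < 0) stop("power must be nonnegative")
  core_area_mm2 <- pi * (fiber$core_radius * 1e-3)^2
  intensity <- (power_at_distal_uW * 1e-3) / core_area_mm2     # mW / mm^2
  bead_area_mm2 <- pi * (bead_diameter / 2 * 1e-3)^2
  list(
    core_area_mm2 = core_area_mm2,
    intensity_mW_mm2 = intensity,
    power_per_bead_mW = intensity * bead_area_mm2
  )
}
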