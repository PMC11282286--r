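fib <- fiber_spec()
mod <- solve_lp_modes(fib)

test_that("on-axis physical fingerprint is azimuthally symmetric", {
  fp <- fingerprint_physical(fib, source_position(0), modes = mod)
  expect_true(all(fp$image >= 0))
  # relative azimuthal variance: compare image to its azimuthal average
  n <- nrow(fp$image)
  sym <- fiberdemix:::azimuthal_symmetry_score(fp$image)
  expect_gt(sym, 0.975)
})

test_that("physical ring radius grows with source offset", {
  d_grid <- seq(0, 0.9, by = 0.1) * fib$core_radius
  rr <- vapply(d_grid, function(d) {
    fingerprint_physical(fib, source_position(d), modes = mod)$ring_radius
  }, numeric(1))
  expect_true(all(diff(rr) >= -1e-9))
  # spec'd comparison at proportionally scaled 20 vs 60 um of a 100 um core
  expect_lt(rr[3], rr[7])
})

test_that("rotating the source rotates the physical fingerprint", {
  d <- 0.4 * fib$core_radius
  fp0 <- fingerprint_physical(fib, source_position(d, 0), modes = mod)
  # 180-degree rotation maps pixel (i, j) to (n+1-i, n+1-j) exactly on the
  # pixel-centered grid, so no interpolation error enters the comparison
  fp1 <- fingerprint_physical(fib, source_position(d, pi), modes = mod)
  n <- nrow(fp1$image)
  back <- fp1$image[n:1, n:1]
  expect_gt(cor(as.vector(fp0$image), as.vector(back)), 0.99)
})

test_that("far out-of-FoV physical source couples almost nothing", {
  fp <- fingerprint_physical(fib, source_position(1.25 * fib$core_radius),
                             modes = mod)
  expect_true(fp$out_of_fov)
  fp_in <- fingerprint_physical(fib, source_position(0.4 * fib$core_radius),
                                modes = mod)
  expect_lt(max(fp$image), 0.05 * max(fp_in$image))
})

test_that("phenomenological ring parameter is monotone and zero on axis", {
  rel <- seq(0, 0.9, by = 0.1)
  rho <- vapply(rel * 12.5, function(d) {
    fingerprint_phenomenological(source_position(d))$ring_radius
  }, numeric(1))
  expect_equal(rho[1], 0)
  expect_true(all(diff(rho) >= 0))
})

test_that("same-position sources with different textures are distinguishable", {
  a <- fingerprint_phenomenological(source_position(6, 1), texture_seed = 1)
  b <- fingerprint_phenomenological(source_position(6, 1), texture_seed = 2)
  expect_lt(cor(as.vector(a$image), as.vector(b$image)), 0.8)
  # determinism
  a2 <- fingerprint_phenomenological(source_position(6, 1), texture_seed = 1)
  expect_identical(a$image, a2$image)
})

test_that("central doublet aligns with the source azimuth", {
  # intensity at the two doublet sites along the azimuth beats the
  # intensity at the same radius rotated 90 degrees away
  az <- pi / 3
  n <- 64
  fp <- fingerprint_phenomenological(source_position(5, az), image_size = n)
  rd <- 0.07 * n
  at <- function(ang) {
    i <- round((n + 1) / 2 + rd * sin(ang))
    j <- round((n + 1) / 2 + rd * cos(ang))
    fp$image[i, j]
  }
  on_axis <- at(az) + at(az + pi)
  off_axis <- at(az + pi / 2) + at(az - pi / 2)
  expect_gt(on_axis, off_axis)
})

test_that("scattering layer: identity at zero, deterministic, symmetry-breaking", {
  fp <- fingerprint_phenomenological(source_position(0), texture_seed = 5)
  same <- apply_scattering_layer(fp, layer_seed = 1, strength = 0)
  expect_identical(same$image, fp$image)
  s1a <- apply_scattering_layer(fp, layer_seed = 7, strength = 1)
  s1b <- apply_scattering_layer(fp, layer_seed = 7, strength = 1)
  expect_identical(s1a$image, s1b$image)
  # symmetry breaking is assessed on the smooth on-axis physical pattern
  # (the phenomenological texture already carries azimuthal structure)
  smooth <- fingerprint_physical(fib, source_position(0), modes = mod)
  sym <- function(img) fiberdemix:::azimuthal_symmetry_score(img)
  s0 <- sym(smooth$image)
  s1 <- sym(apply_scattering_layer(smooth, layer_seed = 7, strength = 1)$image)
  s2 <- sym(apply_scattering_layer(smooth, layer_seed = 7, strength = 2)$image)
  expect_lt(s1, s0)
  expect_lt(s2, s1)
})
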