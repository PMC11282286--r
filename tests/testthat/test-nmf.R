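test_that("reshape flattens frames row-major and round-trips exactly", {
  arr <- array(0, c(2, 2, 2))
  arr[, , 1] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  arr[, , 2] <- matrix(c(5, 6, 7, 8), 2, 2, byrow = TRUE)
  v <- video_stack(arr)
  m <- reshape_video(v)
  expect_equal(m[, 1], c(1, 2, 3, 4))
  expect_equal(m[, 2], c(5, 6, 7, 8))
  expect_identical(unshape_matrix(m, 2, 2), arr)
  # single-frame edge case
  v1 <- video_stack(arr[, , 1, drop = FALSE])
  expect_equal(dim(reshape_video(v1)), c(4L, 1L))
})

test_that("pixel binning takes block means and preserves scale", {
  f <- matrix(1, 4, 4)
  v <- video_stack(array(f, c(4, 4, 1)))
  b <- bin_pixels(v, 2)
  expect_equal(b$frames[, , 1], matrix(1, 2, 2))
  f2 <- matrix(0, 4, 4); f2[1:2, 1:2] <- c(1, 3, 2, 4)
  b2 <- bin_pixels(video_stack(array(f2, c(4, 4, 1))), 2)
  expect_equal(b2$frames[1, 1, 1], 2.5)
  expect_identical(bin_pixels(v, 1), v)
  expect_error(bin_pixels(v, 0), ">= 1")
  # non-dividing factor crops with a message
  v5 <- video_stack(array(1, c(5, 5, 1)))
  expect_message(b5 <- bin_pixels(v5, 2), "cropping")
  expect_equal(dim(b5$frames), c(2, 2, 1))
})

test_that("nndsvd reconstructs a rank-1 matrix to machine precision", {
  M <- outer(c(1, 2), c(3, 4))
  f <- nndsvd_init(M, 1)
  expect_equal(f$W %*% f$H, M, tolerance = 1e-12)
  # oracle: leading singular triplet of the same matrix
  sv <- svd(M)
  expect_equal(abs(sv$u[, 1] * sqrt(sv$d[1])), f$W[, 1], tolerance = 1e-12)
})

test_that("nndsvd output is nonnegative and deterministic", {
  set.seed(1)
  M <- matrix(runif(30 * 20), 30, 20)
  f1 <- nndsvd_init(M, 4)
  f2 <- nndsvd_init(M, 4)
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
  expect_identical(f1, f2)
  expect_error(nndsvd_init(M - 1, 2), "nonnegative")
  expect_error(nndsvd_init(M, 25), "rank")
})

test_that("coordinate descent recovers an exactly factorizable matrix", {
  fx <- make_factorizable(40, 30, 2, seed = 5)
  res <- nmf_fit(fx$M, nmf_config(2, tol = 0, max_iter = 500))
  rel <- norm(fx$M - res$W %*% res$H, "F") / norm(fx$M, "F")
  expect_lt(rel, 1e-4)
  expect_true(all(res$W >= 0) && all(res$H >= 0))
})

test_that("multiplicative-update loss is monotonically non-increasing", {
  set.seed(2)
  M <- matrix(abs(rnorm(50 * 60)), 50, 60)
  res <- nmf_fit(M, nmf_config(5, solver = "mu", max_iter = 300, tol = 0))
  expect_true(all(diff(res$loss_history) <= 1e-8 * res$loss_history[1]))
  expect_true(all(is.finite(res$loss_history)))
})

test_that("coordinate-descent and multiplicative solvers agree within 1%", {
  # multiplicative updates cannot reopen entries that start at zero, so the
  # cross-solver comparison runs both from the same random initialization
  fx <- make_factorizable(30, 40, 3, seed = 9)
  set.seed(9)
  M <- fx$M + 0.05 * mean(fx$M) * matrix(abs(rnorm(30 * 40)), 30, 40)
  cd <- nmf_fit(M, nmf_config(3, init = "random", seed = 0,
                              tol = 0, max_iter = 500))
  mu <- nmf_fit(M, nmf_config(3, init = "random", seed = 0, solver = "mu",
                              tol = 0, max_iter = 10000))
  lcd <- tail(cd$loss_history, 1)
  lmu <- tail(mu$loss_history, 1)
  expect_lt(abs(lcd - lmu) / lcd, 0.01)
})

test_that("invalid NMF inputs are rejected", {
  M <- matrix(1, 4, 4)
  expect_error(nmf_fit(M, nmf_config(5)), "rank")
  Mna <- M; Mna[1, 1] <- NaN
  expect_error(nmf_fit(Mna, nmf_config(2)), "NaN")
  expect_error(nmf_fit(M - 2, nmf_config(2)), "nonnegative")
  expect_error(nmf_config(2, alpha_W = 0.1), "alpha")
})

test_that("demixing is bit-reproducible for fixed config and input", {
  sc <- make_scene(2, seed = 4, n_frames = 100)
  r1 <- demix_video(sc$video, nmf_config(3))
  r2 <- demix_video(sc$video, nmf_config(3))
  expect_identical(r1$W, r2$W)
  expect_identical(r1$temporal, r2$temporal)
})

test_that("rank-1 demixing of a single noiseless source recovers its trace", {
  sc <- make_scene(1, seed = 8, n_frames = 120)
  v <- render_video(sc$sources, camera_model("custom"), noiseless = TRUE)
  res <- demix_video(v, nmf_config(1))
  expect_gt(cor(res$temporal[1, ], sc$sources$traces[[1]]), 0.999)
  # spatial normalization: max of each component is 1, product unchanged
  expect_equal(max(res$spatial[[1]]), 1)
  m <- reshape_video(v)
  expect_lt(norm(m - res$W %*% res$H, "F") / norm(m, "F"), 1e-3)
})

test_that("three-source demixing recovers all traces on clean data", {
  sc <- make_scene(3, seed = 6, n_frames = 300)
  res <- demix_video(sc$video, nmf_config(3))
  rep <- evaluate_demix(res, sc$sources)
  expect_true(all(rep$assignment$pairs$correlation > 0.95))
})

test_that("binned demixing matches unbinned traces", {
  sc <- make_scene(3, seed = 12, n_frames = 300)
  r1 <- demix_video(sc$video, nmf_config(3))
  r2 <- demix_video(sc$video, nmf_config(3), bin_factor = 2)
  for (i in 1:3) {
    best <- max(abs(cor(r1$temporal[i, ], t(r2$temporal))))
    expect_gt(best, 0.95)
  }
})
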