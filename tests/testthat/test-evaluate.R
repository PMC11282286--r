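test_that("pearson table reproduces hand-computed correlations", {
  expect_equal(pearson_table(list(c(1, 2, 3)), list(c(1, 2, 3)))[1, 1], 1)
  expect_equal(pearson_table(list(c(0, 1, 2)), list(c(0, 2, 4)))[1, 1], 1)
  expect_equal(pearson_table(list(c(1, 2, 3, 4)), list(c(2, 1, 4, 3)))[1, 1],
               0.6, tolerance = 1e-12)
  expect_error(pearson_table(list(1:4 / 1), list(1:5 / 1)), "length")
  expect_warning(r <- pearson_table(list(rep(1, 4)), list(1:4 / 1)),
                 "constant")
  expect_equal(r[1, 1], 0)
})

test_that("greedy assignment takes global maxima with (row, col) tie-break", {
  t1 <- pearson_dummy(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2))
  a1 <- assign_and_sort(t1)
  expect_equal(a1$pairs$gt, c(1L, 2L))
  expect_equal(a1$pairs$component, c(1L, 2L))
  expect_equal(a1$pairs$correlation, c(0.9, 0.8))
  # tie on 0.9: lowest (row, col) wins, GT2 falls back to 0.1
  t2 <- pearson_dummy(matrix(c(0.9, 0.9, 0.85, 0.1), 2, 2))
  a2 <- assign_and_sort(t2)
  expect_equal(a2$pairs$gt[1], 1L)
  expect_equal(a2$pairs$component[1], 1L)
  expect_equal(a2$pairs$correlation[2], 0.1)
})

test_that("assignment inverts a component permutation on separated data", {
  sc <- make_scene(4, seed = 21, n_frames = 300)
  res <- demix_video(sc$video, nmf_config(4))
  perm <- c(3, 1, 4, 2)
  res2 <- res
  res2$temporal <- res$temporal[perm, ]
  res2$spatial <- res$spatial[perm]
  rep1 <- evaluate_demix(res, sc$sources)
  rep2 <- evaluate_demix(res2, sc$sources)
  # same GT order, permuted component labels
  expect_equal(rep1$assignment$pairs$gt, rep2$assignment$pairs$gt)
  expect_equal(match(rep1$assignment$pairs$component, perm),
               rep2$assignment$pairs$component)
  expect_equal(rep1$assignment$pairs$correlation,
               rep2$assignment$pairs$correlation, tolerance = 1e-12)
})

test_that("diagonal summary: mean and population standard deviation", {
  d <- pearson_dummy(diag(c(0.9, 0.8, 0.7)))
  s <- diagonal_summary(d)
  expect_equal(s$delta_avg, 0.8)
  expect_equal(s$sigma_delta, sqrt(mean(c(0.1, 0, -0.1)^2)), tolerance = 1e-12)
  expect_equal(round(s$sigma_delta, 4), 0.0816)
  s1 <- diagonal_summary(d, subset = 1)
  expect_equal(s1$sigma_delta, 0)
  expect_error(diagonal_summary(d, subset = integer()), "nonempty")
})

test_that("cross-talk follows |nu - gamma| with the literal-prose mean", {
  nu <- pearson_dummy(matrix(c(1, 0.2, 0.3, 1), 2, 2))
  ga <- pearson_dummy(matrix(c(1, 0.1, 0.1, 1), 2, 2))
  cs <- crosstalk_summary(nu, ga)
  expect_equal(sort(cs$ae_matrix[!is.na(cs$ae_matrix)]), c(0.1, 0.2))
  expect_equal(cs$zeta_avg, 0.15)
  # identical tables give zero cross-talk
  cs0 <- crosstalk_summary(nu, nu)
  expect_equal(cs0$zeta_avg, 0)
  expect_equal(cs0$sigma_zeta, 0)
  # printed-prefactor variant: sum / (2 (N_s - 1)) with N_s = 2
  csp <- crosstalk_summary(nu, ga, prefactor = "half_ns_minus_1")
  expect_equal(csp$zeta_avg, (0.2 + 0.1) / 2)
  expect_error(crosstalk_summary(nu, ga, subset = 1), "at least 2")
  expect_error(crosstalk_summary(nu, pearson_dummy(diag(3))), "shape")
})

test_that("zeta is invariant to simultaneous relabeling of both tables", {
  set.seed(3)
  nu <- matrix(runif(16, -1, 1), 4, 4)
  ga <- matrix(runif(16, -1, 1), 4, 4)
  p <- c(3, 1, 4, 2)
  c1 <- crosstalk_summary(pearson_dummy(nu), pearson_dummy(ga))
  c2 <- crosstalk_summary(pearson_dummy(nu[p, p]), pearson_dummy(ga[p, p]))
  expect_equal(c1$zeta_avg, c2$zeta_avg, tolerance = 1e-12)
  expect_equal(c1$sigma_zeta, c2$sigma_zeta, tolerance = 1e-12)
})

test_that("fingerprint match is scale invariant and exact on identity", {
  sc <- make_scene(2, seed = 14, n_frames = 60)
  imgs <- lapply(sc$sources$fingerprints, `[[`, "image")
  asg <- structure(list(pairs = data.frame(gt = 1:2, component = 1:2,
                                           correlation = c(1, 1))),
                   class = "assignment")
  same <- fingerprint_match(sc$sources$fingerprints, imgs, asg)
  expect_equal(same, c(1, 1), tolerance = 1e-12)
  doubled <- fingerprint_match(sc$sources$fingerprints,
                               lapply(imgs, function(x) 2 * x), asg)
  expect_equal(doubled, c(1, 1), tolerance = 1e-12)
  expect_error(fingerprint_match(sc$sources$fingerprints,
                                 list(matrix(1, 4, 4), matrix(1, 4, 4)), asg),
               "size")
})

test_that("ensemble trace equals the fingerprint-weighted trace sum", {
  sc <- make_scene(2, seed = 19, n_frames = 80)
  v <- render_video(sc$sources, camera_model("custom"), noiseless = TRUE)
  et <- ensemble_trace(v)
  wsum <- vapply(sc$sources$fingerprints, function(f) sum(f$image), numeric(1))
  expected <- wsum[1] * sc$sources$traces[[1]] + wsum[2] * sc$sources$traces[[2]]
  expect_equal(et$trace, expected, tolerance = 1e-9)
  z <- ensemble_trace(video_stack(array(0, c(4, 4, 5))))
  expect_equal(z$trace, rep(0, 5))
})

test_that("percent-scale reporting is the fraction report times 100", {
  sc <- make_scene(3, seed = 22, n_frames = 200)
  res <- demix_video(sc$video, nmf_config(3))
  rf <- evaluate_demix(res, sc$sources, scale = "fraction")
  rp <- evaluate_demix(res, sc$sources, scale = "percent")
  # identical underlying statistics; only the printed units differ
  expect_identical(rf$diagonal$per_source_diagonals,
                   rp$diagonal$per_source_diagonals)
  out <- paste(capture.output(print(rp)), collapse = " ")
  expect_match(out, sprintf("%.1f%%", 100 * rf$diagonal$delta_avg),
               fixed = TRUE)
})
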