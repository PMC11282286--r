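test_that("unknown presets are rejected with the available list", {
  expect_error(generate_experiment("nope", 0), "six_bead")
})

test_that("six_bead preset is deterministic given the seed", {
  e1 <- generate_experiment("six_bead", seed = 5, n_frames = 60,
                            image_size = 32)
  e2 <- generate_experiment("six_bead", seed = 5, n_frames = 60,
                            image_size = 32)
  expect_identical(e1$video$frames, e2$video$frames)
  e3 <- generate_experiment("six_bead", seed = 6, n_frames = 60,
                            image_size = 32)
  expect_false(identical(e1$video$frames, e3$video$frames))
  expect_length(e1$sources$traces, 6)
  expect_true(all(e1$sources$roles == "target"))
  # one source near the core edge
  rel <- vapply(e1$sources$positions, function(p) p$d, numeric(1)) /
    e1$config$fiber$core_radius
  expect_true(any(rel > 0.9))
})

test_that("dominant-neuropil preset has 11 shared-trace sources at ~6x power", {
  e <- generate_experiment("dominant_neuropil_21", seed = 2, n_frames = 400,
                           image_size = 32)
  expect_length(e$sources$traces, 21)
  np <- which(e$sources$roles == "neuropil")
  expect_length(np, 11)
  shared <- e$sources$traces[np]
  for (h in shared[-1]) expect_identical(h, shared[[1]])
  wsum <- vapply(e$sources$fingerprints, function(f) sum(f$image), numeric(1))
  tg <- setdiff(seq_len(21), np)
  r <- sum(vapply(np, function(i) wsum[i] * mean(e$sources$traces[[i]]),
                  numeric(1))) /
    sum(vapply(tg, function(i) wsum[i] * mean(e$sources$traces[[i]]),
               numeric(1)))
  expect_gte(r, 5)
  expect_lte(r, 7)
})

test_that("dense presets carry 26 sources with one neuropil and edge failures", {
  e <- generate_experiment("dense_26_neuropil", seed = 1, n_frames = 80,
                           image_size = 32)
  expect_length(e$sources$traces, 26)
  expect_equal(sum(e$sources$roles == "neuropil"), 1)
  oofv <- vapply(e$sources$fingerprints, `[[`, logical(1), "out_of_fov")
  expect_true(any(oofv))
  # the scattering-layer variant shares geometry but different fingerprints
  ep <- generate_experiment("dense_26_parafilm", seed = 1, n_frames = 80,
                            image_size = 32)
  expect_equal(ep$config$scatter_strength, 1)
  expect_false(identical(e$sources$fingerprints[[1]]$image,
                         ep$sources$fingerprints[[1]]$image))
})

test_that("single-source scan steps the ring radius monotonically", {
  e <- generate_experiment("single_source_scan", seed = 3, n_frames = 100,
                           image_size = 32)
  rho <- vapply(e$sources$fingerprints, `[[`, numeric(1), "ring_radius")
  expect_true(all(diff(rho) >= 0))
})

test_that("background experiment calibrates the ensemble max ratio", {
  e <- generate_background_experiment(2.0, seed = 4, n_frames = 300,
                                      image_size = 32)
  wsum <- vapply(e$sources$fingerprints, function(f) sum(f$image), numeric(1))
  n <- length(wsum)
  tgt <- Reduce(`+`, Map(function(w, h) w * h, wsum[-n],
                         e$sources$traces[-n]))
  bg <- wsum[n] * e$sources$traces[[n]]
  expect_equal(max(bg) / max(tgt), 2.0, tolerance = 1e-9)
})

test_that("preset videos have no saturated pixels at calibrated exposure", {
  e <- generate_experiment("six_bead", seed = 9, n_frames = 100,
                           image_size = 32)
  expect_false(any(e$video$saturation_mask))
})
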