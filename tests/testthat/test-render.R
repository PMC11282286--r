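test_that("noiseless rendering is exactly linear in the sources", {
  sc <- make_scene(3, seed = 7, n_frames = 50)
  v <- render_video(sc$sources, camera_model("custom"), noiseless = TRUE)
  wsum <- vapply(sc$sources$fingerprints, function(f) sum(f$image), numeric(1))
  expected <- Reduce(`+`, Map(function(w, h) w * h, wsum, sc$sources$traces))
  expect_equal(apply(v$frames, 3, sum), expected, tolerance = 1e-9)

  # additivity: video(A union B) = video(A) + video(B) frame-wise
  sA <- source_set(sc$sources$fingerprints[1:2], sc$sources$traces[1:2],
                   sc$sources$positions[1:2], sc$sources$roles[1:2])
  sB <- source_set(sc$sources$fingerprints[3], sc$sources$traces[3],
                   sc$sources$positions[3], sc$sources$roles[3])
  vA <- render_video(sA, camera_model("custom"), noiseless = TRUE)
  vB <- render_video(sB, camera_model("custom"), noiseless = TRUE)
  expect_equal(v$frames, vA$frames + vB$frames, tolerance = 1e-12)
})

test_that("saturation mask flags exactly the clipped pixels", {
  sc <- make_scene(2, seed = 3, n_frames = 20)
  cam <- camera_model("miniscope", gain = 1e6, shot_noise = FALSE,
                      read_noise_sd = 0)
  v <- render_video(sc$sources, cam, noise_seed = 1)
  expect_true(any(v$saturation_mask))
  expect_true(all(v$frames[v$saturation_mask] == 255))
  expect_true(all(v$frames[!v$saturation_mask] < 255))
  # an unclipped render has an empty mask
  cam2 <- camera_model("sCMOS", gain = 1, shot_noise = FALSE,
                       read_noise_sd = 0)
  v2 <- render_video(sc$sources, cam2, noise_seed = 1)
  expect_false(any(v2$saturation_mask))
})

test_that("shot noise is unbiased around the expected counts", {
  img <- matrix(0, 8, 8); img[3:6, 3:6] <- 1
  fp <- fiberdemix:::new_fingerprint(img, 0)
  src <- source_set(list(fp), list(rep(1, 1000)),
                    list(source_position(0)), "target")
  cam <- camera_model("sCMOS", gain = 500, read_noise_sd = 0)
  v <- render_video(src, cam, noise_seed = 9)
  px <- v$frames[4, 4, ]
  se <- sd(px) / sqrt(length(px))
  expect_lt(abs(mean(px) - 500), 3 * se)
})

test_that("mismatched shapes and lengths are rejected", {
  f1 <- fiberdemix:::new_fingerprint(matrix(1, 4, 4), 0)
  f2 <- fiberdemix:::new_fingerprint(matrix(1, 5, 5), 0)
  p <- source_position(0)
  expect_error(source_set(list(f1, f2), list(1:3 / 3, 1:3 / 3),
                          list(p, p), c("target", "target")),
               "image size")
  expect_error(source_set(list(f1, f1), list(1:3 / 3, 1:4 / 4),
                          list(p, p), c("target", "target")),
               "length")
  expect_error(source_set(list(f1), list(c(-1, 1)), list(p), "target"),
               "nonnegative")
})
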