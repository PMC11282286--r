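# Small seeded scenes used across tests. All fixtures are built in code;
# sizes are kept small so the whole suite stays fast.

# n_src sources at spread radii with seeded azimuths and unique textures,
# sparse seeded calcium traces, rendered through the sCMOS camera model.
make_scene <- function(n_src, seed, n_frames = 300, image_size = 32,
                       n_spikes = 8, camera = camera_model("sCMOS")) {
  set.seed(seed)
  az <- runif(n_src, 0, 2 * pi)
  pos <- lapply(seq_len(n_src), function(i) {
    source_position(1.5 + i * 9 / n_src, az[i])
  })
  fps <- lapply(seq_len(n_src), function(i) {
    fingerprint_phenomenological(pos[[i]], image_size = image_size,
                                 texture_seed = seed * 100 + i)
  })
  trs <- lapply(seq_len(n_src), function(i) {
    set.seed(seed * 1000 + i)
    generate_calcium_trace(trace_spec(
      "target", n_frames = n_frames, frame_rate = 10,
      spike_times = sort(sample.int(n_frames, n_spikes)),
      decay_tau = 1.0))
  })
  src <- source_set(fps, trs, pos, rep("target", n_src))
  list(sources = src,
       video = render_video(src, camera, noise_seed = seed))
}

# wrap a plain matrix as a correlation_table (for hand-built fixtures)
pearson_dummy <- function(m) {
  rownames(m) <- paste0("GT", seq_len(nrow(m)))
  colnames(m) <- paste0("C", seq_len(ncol(m)))
  structure(m, scale = "fraction", class = c("correlation_table", "matrix"))
}

# exactly factorizable nonnegative matrix with known rank
make_factorizable <- function(m, n, rank, seed) {
  set.seed(seed)
  W <- matrix(abs(rnorm(m * rank)), m, rank)
  H <- matrix(abs(rnorm(rank * n)), rank, n)
  list(M = W %*% H, W = W, H = H)
}
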