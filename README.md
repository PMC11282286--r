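# fiberdemix

Single-source activity demixing for fiber photometry through **short
multimode fibers (MMFs)**.

Classical fiber photometry collects bulk fluorescence through an implanted
fiber onto one detector, so the activity of individual neurons is lost in
the ensemble signal. A short (few millimeters) multimode fiber changes the
game: each fluorescent source at the distal facet produces a structured,
position-specific **scattering fingerprint** at the proximal facet. A camera
video of the superimposed fingerprints is then a linear mixture

```
M[pixel, t] = sum_i  w_i[pixel] * h_i(t)
```

of per-source spatial fingerprints `w_i >= 0` and time traces `h_i(t) >= 0`,
which **unconstrained non-negative matrix factorization (NMF)** can separate
by minimizing `0.5 * ||M - W H||_F^2` over `W, H >= 0` — applied directly to
the raw video matrix, with deterministic NNDSVD initialization and a
coordinate-descent solver, no regularization, no spatial or temporal priors.

The package provides, in four modules:

* **Synthetic data** — a complete forward model to generate test beds with
  known ground truth: guided LP-mode solving for a scaled step-index fiber
  and a physical fingerprint model; a fast phenomenological spiral-ring
  fingerprint model; sparse calcium-transient and non-sparse neuropil trace
  generators; a scattering-layer model; camera digitization (16-bit sCMOS /
  8-bit miniscope presets) with shot/read noise and saturation tracking;
  and scenario presets (`six_bead`, `dense_26_neuropil`,
  `dense_26_parafilm`, `dominant_neuropil_21`, `single_source_scan`).
* **Demixing** — `nndsvd_init()`, `nmf_fit()` (coordinate descent, plus a
  multiplicative-update solver with a monotone-loss guarantee as an internal
  cross-check), `demix_video()`, optional pixel binning, and `rank_scan()`
  for counting sources by the plateau of unique components across ranks.
* **Evaluation** — Pearson correlation tables between ground-truth and
  demixed traces (and between ground-truth traces themselves), greedy
  descending assignment, the diagonal recovery summary
  (`delta_avg ± sigma_delta`), and the cross-talk summary
  `zeta_avg = mean |nu_ij - gamma_ij|, i != j` that measures mixing error
  beyond the intrinsic correlation of the ground-truth traces.
* **I/O + CLI** — multi-page TIFF videos, CSV traces/tables, JSON
  configs/manifests, and a `fiberdemix` command-line wrapper
  (`simulate`, `demix`, `evaluate`, `rank-scan`, `full-run`).

## Worked example

```r
library(fiberdemix)

# six target beads, one near the core edge; 1500 frames at 10 Hz, 16-bit
# sCMOS camera with shot noise
exp <- generate_experiment("six_bead", seed = 0)

# unconstrained NMF on the raw video, rank 9, NNDSVD + coordinate descent
res <- demix_video(exp$video, nmf_config(rank = 9))

# compare to ground truth over the five best-recovered sources
rep <- evaluate_demix(res, exp$sources, subset = 5, scale = "percent")
print(rep)
#> evaluation over 6 sources, 6 assigned
#>   delta_avg = 99.9% (sigma 0.2%) over 5 sources
#>   zeta_avg  = 1.23% (sigma 2.06%)
```

`delta_avg` is the mean Pearson correlation between each ground-truth trace
and its assigned demixed trace; `zeta_avg` is the mean absolute difference
between off-diagonal demixed-vs-truth and truth-vs-truth correlations — the
residual cross-talk. On this clean synthetic scene the demixing is nearly
exact; the bench-scale analogue of this experiment reports
`delta_avg = 85.4%` and `zeta_avg = 7.06%`.

Counting sources without ground truth:

```r
scan <- rank_scan(exp$video, 1:9)
scan$estimated_source_count   # 6
```

From the shell:

```sh
Rscript inst/cli/fiberdemix full-run --preset six_bead --seed 0 --rank 9 --out out/
```

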