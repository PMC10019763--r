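#!/usr/bin/env Rscript
# Build the canonical synthetic scene suite that the downstream analyses
# use: comet (+1/2) and trefoil (-1/2) textures with truth tables, a
# +/-1/2 pair, a stationary-defect movie (head-side texture advecting
# toward the core), a focal-adhesion panel and a nuclei point set with a
# density hotspot at the defect head.

library(nematicdefects)

out <- file.path("results", "scenes")
params <- make_synthetic_suite(out, seed = 1, pixel_size = 1.5)

truth <- read.csv(file.path(out, "comet_truth.csv"))
cat(sprintf(
  "Scene suite written to %s (seed %d, %.3g um/px)\n", out, params$seed,
  params$pixel_size
))
cat(sprintf(
  "Comet truth: +%.1f defect at (%.1f, %.1f) um, tail along %.1f deg\n",
  truth$charge, truth$x_um, truth$y_um, truth$axis_rad * 180 / pi
))
cat(sprintf(
  "Stationary movie: %d frames, dt = %.2f h, head flow v0 = %g um/h\n",
  params$n_frames, params$frame_interval, params$v0
))
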