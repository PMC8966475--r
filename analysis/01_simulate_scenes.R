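#!/usr/bin/env Rscript
# Generate one synthetic scene of every modality the pipeline consumes and
# write them to disk (TIFF + ground-truth sidecars). Later scripts read
# these files back, so the whole workflow exercises the same I/O path real
# microscopy data would take.

suppressPackageStartupMessages(library(synapseflow))
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260917L

# IRM-like spreading movies for two conditions with equal spreading rate
# (the published contrast: spreading rate comparable, plateau area larger
# under three-signal activation)
for (cond in c("2SI", "3SI")) {
  a0 <- if (cond == "2SI") 260 else 320
  g <- generate_spreading_movie(A0_um2 = a0, alpha = 0.02, seed = seed)
  write_stack(g$stack, file.path(out, paste0("irm_", cond, ".tif")))
  write_truth_sidecar(g$truth[c("A0_um2", "alpha", "t_contact", "seed")],
                      file.path(out, paste0("irm_", cond)))
  seed <- seed + 1L
}

# speckle movies: faster actin flow for the 2SI-like condition (the study's
# direction of effect), plus a centripetal scene for directionality
for (cond in c("2SI", "3SI")) {
  v <- if (cond == "2SI") 2.6 else 2.0
  g <- generate_speckle_movie(size_px = 64, n_frames = 30, flow = "uniform",
                              speed_um_min = v, direction_deg = 25,
                              seed = seed)
  write_stack(g$stack, file.path(out, paste0("actin_", cond, ".tif")),
              dtype = "float32")
  write_truth_sidecar(g$truth[c("flow", "speed_um_min", "seed")],
                      file.path(out, paste0("actin_", cond)))
  seed <- seed + 1L
}
g <- generate_speckle_movie(size_px = 64, n_frames = 30, flow = "radial_in",
                            speed_um_min = 1.5, seed = seed)
write_stack(g$stack, file.path(out, "actin_inward.tif"), dtype = "float32")
write_truth_sidecar(g$truth[c("flow", "speed_um_min", "seed")],
                    file.path(out, "actin_inward"))
seed <- seed + 1L

# granule scene + motion-model track sets (tracking works on tables here;
# the rendered-movie detection path is exercised in the test suite)
gg <- generate_granule_scene(seed = seed)
write_tiff(gg$frame, file.path(out, "lamp1_frame.tif"), dtype = "float32")
write_truth_sidecar(list(granules = gg$truth, seed = seed),
                    file.path(out, "lamp1"))
seed <- seed + 1L

for (model in c("brownian", "directed", "confined")) {
  # directed transport rides microtubule motors (~0.5 um/s) on top of a
  # small diffusive component
  sim <- simulate_tracks(n_tracks = 120, n_points = 100,
                         frame_interval = 0.1, model = model, D = 0.05,
                         speed_um_s = 0.5, box_um = 1, seed = seed)
  write_tracks_csv(sim$tracks, file.path(out, paste0("tracks_", model,
                                                     ".csv")))
  seed <- seed + 1L
}

# TFM bead pair on a ~1 kPa gel
gel <- gel_properties(1000, 0.5)
sc <- generate_tfm_scene(seed = seed, gel = gel)
write_tiff(sc$reference, file.path(out, "beads_reference.tif"),
           dtype = "float32")
write_tiff(sc$deformed, file.path(out, "beads_deformed.tif"),
           dtype = "float32")
write_truth_sidecar(list(force_nN = sc$truth$force_nN,
                         peak_disp_px = sc$truth$peak_disp_px,
                         seed = seed), file.path(out, "beads"))

cat("Scenes written to", out, ":", length(list.files(out)), "files\n")
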