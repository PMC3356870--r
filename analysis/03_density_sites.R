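#!/usr/bin/env Rscript
# Fixed-lab-frame water density, hydration sites and RMSD stability.
#
# A 300-frame trajectory with two planted hydration sites (100 % and 90 %
# scripted presence) tumbles rigidly every frame; each frame is RMS-fitted
# back to frame 1 on the protein backbone, so the density grid stays fixed
# in the lab frame while the molecule moves. Sites are extracted by greedy
# peak-picking and the full bundled report is written alongside the
# OpenDX density map.
suppressPackageStartupMessages(library(hydrosite))

seed <- 42
out_dir <- "results/density"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ws <- list(water_script(1.0, distance = 2.6, jitter_sigma = 0.2),
           water_script(0.9, distance = 4.2, jitter_sigma = 0.2))
gen <- make_trajectory(trajectory_spec(n_frames = 300, water_scripts = ws,
                                       ring_radius = 8.5,
                                       seed = seed, rigid_tumbling = TRUE))
report <- hydration_report(gen$trajectory, "LIG",
                           grid_extent = 60, grid_spacing = 0.5)
write_hydration_report(report, out_dir)

cat(sprintf("density grid: %d counts + %d overflow over %d frames\n",
            sum(report$grid$counts), report$grid$overflow,
            report$grid$n_frames))
cat(sprintf("hydration sites (>=25%% occupancy): %d\n", nrow(report$sites)))
print(report$sites, row.names = FALSE)
for (k in seq_along(ws)) {
  truth <- gen$ground_truth$waters[[k]]
  err <- sqrt(sum((as.numeric(report$sites[k, c("x", "y", "z")]) -
                     as.numeric(truth$sites[1, ]))^2))
  cat(sprintf("site %d: scripted occupancy %.2f%%, position error %.2f A\n",
              k, truth$occupancy, err))
}
cat(sprintf("backbone RMSD after fitting: mean %.2f A, max %.2f A\n",
            mean(report$rmsd_backbone$rmsd), max(report$rmsd_backbone$rmsd)))
if (!is.null(report$rmsd_active_site)) {
  cat(sprintf("active-site (5 A region) RMSD: mean %.2f A\n",
              mean(report$rmsd_active_site$rmsd)))
}
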