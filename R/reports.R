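#' Bundled hydration report for one trajectory
#'
#' Runs the full hydration workflow on a trajectory: solvation-shell series,
#' contact-occupancy table, fixed-frame density grid with hydration sites,
#' and backbone RMSD traces for the whole protein and for the 5-angstrom
#' active-site region around the ligand (region fixed at frame 1).
#'
#' @param traj a `pdb_trajectory`.
#' @param ligand_resname ligand residue name.
#' @param r1,r2 solvation-shell radii, angstrom.
#' @param dist_cutoff occupancy distance criterion, angstrom.
#' @param grid_extent density-grid edge, angstrom.
#' @param grid_spacing voxel edge, angstrom.
#' @param min_occupancy hydration-site threshold, percent.
#' @param site_radius hydration-site radius, angstrom.
#' @return A `hydration_report` list: `shells`, `occupancy`, `sites`, `grid`,
#'   `rmsd_backbone`, `rmsd_active_site`, `params`.
#' @export
hydration_report <- function(traj, ligand_resname, r1 = 3.4, r2 = 5.0,
                             dist_cutoff = 5.0, grid_extent = 100,
                             grid_spacing = 0.5, min_occupancy = 25,
                             site_radius = 1.0) {
  topo <- traj$topology
  lig <- select_atoms(topo, "ligand", resname = ligand_resname)
  bb <- select_atoms(topo, "backbone")
  shells <- shell_counts(traj, lig, r1 = r1, r2 = r2)
  occupancy <- hbond_occupancy(traj, lig, dist_cutoff = dist_cutoff)
  fit_sel <- if (length(bb)) bb else lig
  grid <- build_density_grid(traj, fit_sel, extent = grid_extent,
                             spacing = grid_spacing)
  sites <- extract_hydration_sites(grid, min_occupancy = min_occupancy,
                                   site_radius = site_radius)
  rmsd_bb <- if (length(bb)) trajectory_rmsd(traj, bb) else NULL
  frame1 <- frame_structure(traj, 1L)
  region <- select_atoms(frame1, "within", radius = 5.0, of = lig)
  region_bb <- intersect(region, bb)
  rmsd_site <- if (length(region_bb) >= 3L && length(bb)) {
    trajectory_rmsd(traj, bb, region_bb)
  } else {
    NULL
  }
  structure(
    list(shells = shells, occupancy = occupancy, sites = sites, grid = grid,
         rmsd_backbone = rmsd_bb, rmsd_active_site = rmsd_site,
         params = list(ligand = ligand_resname, r1 = r1, r2 = r2,
                       dist_cutoff = dist_cutoff, grid_extent = grid_extent,
                       grid_spacing = grid_spacing,
                       min_occupancy = min_occupancy,
                       site_radius = site_radius)),
    class = "hydration_report"
  )
}

#' @export
print.hydration_report <- function(x, ...) {
  cat(sprintf(
    "<hydration_report> ligand %s: shells %.2f/%.2f, %d contact pairs, %d sites\n",
    x$params$ligand, x$shells$mean_first, x$shells$mean_second,
    nrow(x$occupancy), nrow(x$sites)))
  invisible(x)
}

#' Write a hydration report to plain-text files
#'
#' Emits `shells.csv` (per-frame counts), `occupancy.tsv` (donor, acceptor,
#' occupancy to two decimals, mean distance — the trajectory-table shape),
#' `sites.json`, `rmsd.csv` and `density.dx` under `dir`.
#'
#' @param report a `hydration_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hydration_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$shells),
                   file.path(dir, "shells.csv"), row.names = FALSE)
  occ <- report$occupancy
  occ_out <- data.frame(donor = occ$donor, acceptor = occ$acceptor,
                        occupancy_pct = sprintf("%.2f", occ$occupancy),
                        distance_A = sprintf("%.3f", occ$mean_distance),
                        stringsAsFactors = FALSE)
  utils::write.table(occ_out, file.path(dir, "occupancy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$sites, file.path(dir, "sites.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  rmsd <- report$rmsd_backbone
  if (!is.null(rmsd)) {
    rmsd$rmsd_active_site <- if (!is.null(report$rmsd_active_site)) {
      report$rmsd_active_site$rmsd
    } else {
      NA_real_
    }
    utils::write.csv(rmsd, file.path(dir, "rmsd.csv"), row.names = FALSE)
  }
  write_dx(report$grid, file.path(dir, "density.dx"))
  invisible(dir)
}

#' Write a family contact table as TSV
#'
#' @param report output of [crystal_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crystal_report <- function(report, path) {
  out <- report
  out$distance_A <- sprintf("%.3f", out$distance_A)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
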