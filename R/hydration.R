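#' Trajectory hydration analysis
#'
#' Per-frame solvation-shell populations around a ligand, contact /
#' hydrogen-bond occupancies over a trajectory, and water residence times at
#' a fixed site.
#'
#' @name trajectory-hydration
NULL

# Indices of water oxygen atoms in a topology.
#' @noRd
water_oxygens <- function(topology) {
  which(topology$atoms$water & topology$atoms$element == "O")
}

#' Solvation-shell water counts per frame
#'
#' Counts waters whose oxygen lies within the first shell (minimum distance
#' to any ligand atom at most `r1`, default 3.4 angstrom) and the second
#' shell (distance in `(r1, r2]`, default `r2 = 5`) at every frame. With
#' `mode = "com"` distances are taken to the ligand centre of mass instead of
#' the nearest ligand atom.
#'
#' @param traj a `pdb_trajectory`.
#' @param ligand ligand atom selection on the topology.
#' @param r1,r2 shell radii, angstrom, `r1 < r2`.
#' @param mode `"atom"` (minimum heavy-atom distance, default) or `"com"`.
#' @return A `shell_series` list: `first`, `second` (per-frame integer
#'   counts), `mean_first`, `mean_second`, `r1`, `r2`, `time_ps`.
#' @export
shell_counts <- function(traj, ligand, r1 = 3.4, r2 = 5.0,
                         mode = c("atom", "com")) {
  stopifnot(inherits(traj, "pdb_trajectory"), r1 > 0, r1 < r2)
  mode <- match.arg(mode)
  if (!length(ligand)) stop("empty ligand selection")
  wo <- water_oxygens(traj$topology)
  nf <- n_frames(traj)
  first <- integer(nf)
  second <- integer(nf)
  for (f in seq_len(nf)) {
    if (!length(wo)) break
    wxyz <- coords_of(traj, f, wo)
    ref <- coords_of(traj, f, ligand)
    if (mode == "com") ref <- matrix(colMeans(ref), 1L)
    md <- min_dist_to(wxyz, ref)
    first[f] <- sum(md <= r1)
    second[f] <- sum(md > r1 & md <= r2)
  }
  structure(
    list(first = first, second = second,
         mean_first = mean(first), mean_second = mean(second),
         r1 = r1, r2 = r2,
         time_ps = (seq_len(nf) - 1L) * traj$frame_interval),
    class = "shell_series"
  )
}

#' @export
print.shell_series <- function(x, ...) {
  cat(sprintf(
    "<shell_series> %d frames; mean first shell (<=%.1f A) %.2f, second (%.1f-%.1f A) %.2f\n",
    length(x$first), x$r1, x$mean_first, x$r1, x$r2, x$mean_second))
  invisible(x)
}

#' @export
as.data.frame.shell_series <- function(x, ...) {
  data.frame(frame = seq_along(x$first), time_ps = x$time_ps,
             first_shell = x$first, second_shell = x$second)
}

#' Solute-water contact and hydrogen-bond occupancy
#'
#' For every (solute atom, water oxygen) pair seen within `dist_cutoff` in at
#' least one frame, reports the occupancy: the percentage of frames in which
#' the distance criterion — and, when `use_angle = TRUE`, a
#' donor-H...acceptor angle of at least `angle_cutoff` degrees for some
#' hydrogen bonded to the solute atom — is satisfied. The default is
#' distance-only at 5 angstrom, i.e. a contact occupancy; the strict
#' hydrogen-bond mode needs hydrogens in the topology. Mean distance is
#' averaged over satisfying frames. Records are sorted by descending
#' occupancy.
#'
#' @param traj a `pdb_trajectory`.
#' @param solute solute atom selection (e.g. the ligand).
#' @param waters water-oxygen selection; default all water oxygens.
#' @param dist_cutoff distance criterion, angstrom.
#' @param angle_cutoff angle criterion, degrees (strict mode).
#' @param use_angle enable the angle criterion.
#' @return Data frame with `donor`, `acceptor`, `occupancy` (percent),
#'   `mean_distance` (angstrom), `n_frames_present`.
#' @export
hbond_occupancy <- function(traj, solute, waters = NULL, dist_cutoff = 5.0,
                            angle_cutoff = 120, use_angle = FALSE) {
  stopifnot(inherits(traj, "pdb_trajectory"), dist_cutoff > 0)
  at <- traj$topology$atoms
  solute <- as.integer(solute)
  if (!length(solute)) stop("empty solute selection")
  wo <- if (is.null(waters)) water_oxygens(traj$topology) else as.integer(waters)
  nf <- n_frames(traj)
  empty <- data.frame(donor = character(0), acceptor = character(0),
                      occupancy = numeric(0), mean_distance = numeric(0),
                      n_frames_present = integer(0), stringsAsFactors = FALSE)
  if (!length(wo)) return(empty)

  hyd <- NULL
  if (use_angle) {
    h_idx <- which(at$element == "H")
    if (!length(h_idx)) {
      stop("missing hydrogens: the angle criterion needs explicit H atoms")
    }
    # map each solute heavy atom to its covalent hydrogens (frame-1 geometry)
    d_h <- dist_xyz(coords_of(traj, 1L, solute), coords_of(traj, 1L, h_idx))
    same_res <- outer(residue_key(at, solute), residue_key(at, h_idx), "==")
    hyd <- lapply(seq_along(solute), function(i) {
      h_idx[d_h[i, ] <= 1.25 & same_res[i, ]]
    })
  }

  counts <- matrix(0L, length(solute), length(wo))
  dsums <- matrix(0, length(solute), length(wo))
  for (f in seq_len(nf)) {
    d <- dist_xyz(coords_of(traj, f, solute), coords_of(traj, f, wo))
    ok <- d <= dist_cutoff
    if (use_angle && any(ok)) {
      wxyz <- coords_of(traj, f, wo)
      sxyz <- coords_of(traj, f, solute)
      for (i in which(rowSums(ok) > 0L)) {
        hs <- hyd[[i]]
        if (!length(hs)) { ok[i, ] <- FALSE; next }
        hxyz <- coords_of(traj, f, hs)
        for (j in which(ok[i, ])) {
          # donor-H...acceptor angle at H, maximised over donor hydrogens
          v1 <- -sweep(hxyz, 2L, sxyz[i, ])                       # H -> donor
          v2 <- matrix(wxyz[j, ], nrow(hxyz), 3L, byrow = TRUE) - hxyz  # H -> acceptor
          cosang <- rowSums(v1 * v2) /
            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          ok[i, j] <- any(ang >= angle_cutoff)
        }
      }
    }
    counts <- counts + ok
    dsums <- dsums + d * ok
  }
  hit <- which(counts > 0L, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- solute[hit[, 1L]]
  j <- wo[hit[, 2L]]
  n_present <- counts[hit]
  out <- data.frame(
    donor = atom_ref(at$resname[i], at$resid[i], at$name[i], at$water[i]),
    acceptor = atom_ref(at$resname[j], at$resid[j], at$name[j], at$water[j]),
    occupancy = 100 * n_present / nf,
    mean_distance = dsums[hit] / n_present,
    n_frames_present = n_present, stringsAsFactors = FALSE
  )
  out <- out[order(-out$occupancy, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximal presence runs with gap bridging: runs of 1s separated by zero-runs
# of length <= gap_tolerance are merged; run length counts bridged gaps.
#' @noRd
presence_runs <- function(bits, gap_tolerance = 0L) {
  bits <- as.integer(bits != 0)
  if (!any(bits == 1L)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_present = integer(0)))
  }
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  one <- which(r$values == 1L)
  runs <- data.frame(start = starts[one], end = ends[one],
                     n_present = r$lengths[one])
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= gap_tolerance) {
        merged$end[nrow(merged)] <- runs$end[k]
        merged$n_present[nrow(merged)] <-
          merged$n_present[nrow(merged)] + runs$n_present[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  merged$length <- merged$end - merged$start + 1L
  merged[, c("start", "end", "length", "n_present")]
}

#' Residence time of a water at a fixed site
#'
#' Builds the per-frame presence bitstring (water oxygen within `site_radius`
#' of `site_center`) and summarises it: the longest visit (allowing internal
#' absences of up to `gap_tolerance` frames; the reported run length includes
#' bridged gaps), the number of visits, and the total occupancy. Site
#' coordinates are interpreted in the trajectory's own frame — fit the
#' trajectory first if the solute tumbles.
#'
#' @param traj a `pdb_trajectory`.
#' @param water_resid residue number of the water (with `chain` when
#'   ambiguous).
#' @param site_center site position, length-3, angstrom.
#' @param site_radius presence radius, angstrom (default 1.4).
#' @param gap_tolerance maximum bridged absence, frames.
#' @param chain optional chain id of the water.
#' @return A `residence_report` list: `water_id`, `presence` (logical
#'   per-frame), `n_visits`, `longest_run_frames`, `longest_run_ps`,
#'   `total_occupancy` (percent), `runs` (data frame).
#' @export
residence_time <- function(traj, water_resid, site_center, site_radius = 1.4,
                           gap_tolerance = 0L, chain = NULL) {
  stopifnot(inherits(traj, "pdb_trajectory"), site_radius > 0)
  at <- traj$topology$atoms
  idx <- which(at$water & at$element == "O" & at$resid == water_resid &
                 (if (is.null(chain)) TRUE else at$chain == chain))
  if (!length(idx)) stop(sprintf("unknown water residue %s", water_resid))
  idx <- idx[1L]
  nf <- n_frames(traj)
  wxyz <- t(traj$coords[idx, , ])  # nf x 3
  d <- sqrt(rowSums(sweep(wxyz, 2L, as.numeric(site_center))^2))
  presence <- d <= site_radius
  runs <- presence_runs(presence, gap_tolerance)
  longest <- if (nrow(runs)) max(runs$length) else 0L
  structure(
    list(water_id = paste0(at$resname[idx], at$resid[idx]),
         presence = presence, n_visits = nrow(runs),
         longest_run_frames = longest,
         longest_run_ps = longest * traj$frame_interval,
         total_occupancy = 100 * sum(presence) / nf,
         runs = runs),
    class = "residence_report"
  )
}

#' @export
print.residence_report <- function(x, ...) {
  cat(sprintf(
    "<residence_report> %s: %d visits, longest %d frames (%g ps), occupancy %.2f%%\n",
    x$water_id, x$n_visits, x$longest_run_frames, x$longest_run_ps,
    x$total_occupancy))
  invisible(x)
}
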