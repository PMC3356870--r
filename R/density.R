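#' Water density grids and hydration sites
#'
#' Every frame is rigid-fitted to frame 1 on the solute, so the lab frame —
#' and the voxel grid in it — never moves while the molecule tumbles; water
#' oxygens then accumulate into fixed voxels, and localized high-density
#' peaks are extracted as hydration sites.
#'
#' @name density-grid
NULL

#' Build a fixed-lab-frame water density grid
#'
#' Fits each frame to frame 1 on `fit_selection` (Kabsch), centres a cubic
#' grid of edge `extent` on the frame-1 centroid of the fit selection, and
#' counts one increment per water oxygen per frame into its containing
#' voxel. Waters outside the grid are tallied as overflow, so
#' `sum(counts) + overflow == n_frames * n_waters` always holds.
#'
#' @param traj a `pdb_trajectory`.
#' @param fit_selection solute atoms used for the per-frame rigid fit.
#' @param extent grid edge length, angstrom (default 100); must be an
#'   integral multiple of `spacing`.
#' @param spacing voxel edge, angstrom (default 0.5).
#' @param center optional grid centre; default frame-1 fit-selection
#'   centroid.
#' @return A `density_grid` list: `origin`, `spacing`, `dims`, `counts`
#'   (integer array), `n_frames`, `overflow`, plus the fitted water-oxygen
#'   coordinates (`water_xyz`, `n_waters x 3 x n_frames`), water ids, and
#'   fitted polar heavy-atom coordinates used for site statistics.
#' @export
build_density_grid <- function(traj, fit_selection, extent = 100,
                               spacing = 0.5, center = NULL) {
  stopifnot(inherits(traj, "pdb_trajectory"), spacing > 0, extent > 0)
  nvox <- extent / spacing
  if (abs(nvox - round(nvox)) > 1e-9) {
    stop("extent must be an integral multiple of spacing")
  }
  nvox <- as.integer(round(nvox))
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames")
  if (!length(fit_selection)) stop("empty fit selection")
  at <- traj$topology$atoms
  wo <- water_oxygens(traj$topology)
  polar <- which(!at$water & at$element %in% POLAR_ELEMENTS)

  ref <- coords_of(traj, 1L, fit_selection)
  center <- as.numeric(center %||% colMeans(ref))
  origin <- center - extent / 2
  solute_span <- max(abs(sweep(ref, 2L, center)))
  if (solute_span > extent / 2) {
    warning("grid extent does not contain the frame-1 solute")
  }

  dims <- rep(nvox, 3L)
  counts <- integer(prod(dims))
  overflow <- 0L
  water_xyz <- array(NA_real_, c(length(wo), 3L, nf))
  polar_xyz <- array(NA_real_, c(length(polar), 3L, nf))
  for (f in seq_len(nf)) {
    fit <- kabsch(coords_of(traj, f, fit_selection), ref)
    if (length(wo)) {
      w <- apply_superposition(fit, coords_of(traj, f, wo))
      water_xyz[, , f] <- w
      ijk <- floor(sweep(w, 2L, origin) / spacing)
      inside <- rowSums(ijk >= 0 & ijk < nvox) == 3L
      overflow <- overflow + sum(!inside)
      if (any(inside)) {
        lin <- 1L + ijk[inside, 1L] + nvox * (ijk[inside, 2L] +
                                                nvox * ijk[inside, 3L])
        tab <- table(lin)
        counts[as.integer(names(tab))] <-
          counts[as.integer(names(tab))] + as.integer(tab)
      }
    }
    if (length(polar)) {
      polar_xyz[, , f] <- apply_superposition(fit, coords_of(traj, f, polar))
    }
  }
  dim(counts) <- dims
  structure(
    list(origin = origin, spacing = spacing, dims = dims, counts = counts,
         n_frames = nf, overflow = overflow,
         water_xyz = water_xyz,
         water_ids = paste0(at$resname[wo], at$resid[wo]),
         polar_xyz = polar_xyz),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %dx%dx%d voxels @ %.2f A, %d frames, %d counts (+%d overflow)\n",
    x$dims[1L], x$dims[2L], x$dims[3L], x$spacing, x$n_frames,
    sum(x$counts), x$overflow))
  invisible(x)
}

# Centre coordinates of a linear voxel index.
#' @noRd
voxel_center <- function(grid, lin) {
  lin0 <- lin - 1L
  i <- lin0 %% grid$dims[1L]
  j <- (lin0 %/% grid$dims[1L]) %% grid$dims[2L]
  k <- lin0 %/% (grid$dims[1L] * grid$dims[2L])
  grid$origin + (c(i, j, k) + 0.5) * grid$spacing
}

#' Extract hydration sites from a density grid
#'
#' Greedy peak picking: the highest-count voxel seeds a site at its centre;
#' the site's occupancy is the percentage of frames with at least one water
#' oxygen within `site_radius`; voxels within `site_radius` of the site are
#' cleared and the search repeats while the seeded occupancy stays at or
#' above `min_occupancy`. For every site the mean number of neighbouring
#' waters within 3.5 and 5 angstrom of the occupying water, and its mean
#' distance-criterion hydrogen-bond count (polar heavy atoms within 3.5
#' angstrom), are averaged over occupied frames.
#'
#' @param grid a `density_grid` from [build_density_grid()].
#' @param min_occupancy minimum site occupancy, percent (default 25).
#' @param site_radius site radius, angstrom (default 1.0).
#' @return Data frame with `x`, `y`, `z`, `occupancy`, `mean_neighbors_3p5`,
#'   `mean_neighbors_5`, `mean_hbonds`, `peak_count`, one row per site in
#'   extraction order.
#' @export
extract_hydration_sites <- function(grid, min_occupancy = 25,
                                    site_radius = 1.0) {
  stopifnot(inherits(grid, "density_grid"), site_radius > 0)
  counts <- grid$counts
  nf <- grid$n_frames
  nw <- dim(grid$water_xyz)[1L]
  sites <- list()
  while (TRUE) {
    m <- which.max(counts)
    if (counts[m] <= 0L) break
    pos <- voxel_center(grid, m)
    # per-frame occupancy and statistics at this site
    occ_frames <- logical(nf)
    nb35 <- numeric(nf)
    nb5 <- numeric(nf)
    nhb <- numeric(nf)
    for (f in seq_len(nf)) {
      w <- grid$water_xyz[, , f, drop = FALSE]
      dim(w) <- c(nw, 3L)
      d <- sqrt(rowSums(sweep(w, 2L, pos)^2))
      hit <- which(d <= site_radius)
      if (!length(hit)) next
      occ_frames[f] <- TRUE
      occ_w <- hit[which.min(d[hit])]
      dd <- sqrt(rowSums(sweep(w, 2L, w[occ_w, ])^2))
      dd <- dd[-occ_w]
      nb35[f] <- sum(dd <= 3.5)
      nb5[f] <- sum(dd <= 5.0)
      np <- dim(grid$polar_xyz)[1L]
      hb_polar <- 0L
      if (np > 0L) {
        p <- grid$polar_xyz[, , f, drop = FALSE]
        dim(p) <- c(np, 3L)
        hb_polar <- sum(sqrt(rowSums(sweep(p, 2L, w[occ_w, ])^2)) <= 3.5)
      }
      nhb[f] <- hb_polar + sum(dd <= 3.5)
    }
    occupancy <- 100 * sum(occ_frames) / nf
    if (occupancy < min_occupancy) break
    present <- which(occ_frames)
    sites[[length(sites) + 1L]] <- data.frame(
      x = pos[1L], y = pos[2L], z = pos[3L], occupancy = occupancy,
      mean_neighbors_3p5 = mean(nb35[present]),
      mean_neighbors_5 = mean(nb5[present]),
      mean_hbonds = mean(nhb[present]),
      peak_count = as.integer(counts[m])
    )
    # clear the site's voxels
    rad_vox <- ceiling(site_radius / grid$spacing)
    ijk0 <- floor((pos - grid$origin) / grid$spacing)
    rng <- lapply(1:3, function(a) {
      max(0L, ijk0[a] - rad_vox):min(grid$dims[a] - 1L, ijk0[a] + rad_vox)
    })
    box <- as.matrix(expand.grid(i = rng[[1L]], j = rng[[2L]], k = rng[[3L]]))
    ctr <- sweep((box + 0.5) * grid$spacing, 2L, as.numeric(pos - grid$origin))
    near <- sqrt(rowSums(ctr^2)) <= site_radius
    lin <- 1L + box[near, 1L] + grid$dims[1L] *
      (box[near, 2L] + grid$dims[2L] * box[near, 3L])
    counts[lin] <- 0L
  }
  if (!length(sites)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      occupancy = numeric(0), mean_neighbors_3p5 = numeric(0),
                      mean_neighbors_5 = numeric(0), mean_hbonds = numeric(0),
                      peak_count = integer(0)))
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}

#' Write a density grid as an OpenDX scalar field
#'
#' Plain-text OpenDX format readable by PyMOL, Chimera and VMD.
#'
#' @param grid a `density_grid`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(d))
  ), con)
  # OpenDX expects x fastest-varying last: emit in x-major order
  vals <- aperm(grid$counts, c(3L, 2L, 1L))
  vals <- as.numeric(vals)
  pad <- (3L - length(vals) %% 3L) %% 3L
  rows <- matrix(c(vals, rep(NA_real_, pad)), ncol = 3L, byrow = TRUE)
  lines <- apply(rows, 1L, function(r) {
    paste(formatC(r[!is.na(r)], format = "g"), collapse = " ")
  })
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
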