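#' Synthetic crystal families and hydration trajectories
#'
#' Seeded generators that plant known hydration structure — conserved water
#' sites, bridging contacts, displaced apo waters, scripted per-frame water
#' presence — into coarse protein-ligand models, standing in for downloaded
#' crystal structures and explicit-solvent MD runs. The "protein" is a
#' C-alpha-plus-backbone scaffold ring around a central ligand: geometry
#' sufficient for every distance-based operation, with no force field or
#' chemistry. All randomness flows from the single seed in the spec;
#' identical specs give byte-identical output.
#'
#' @name synthetic-data
NULL

# Scaffold protein: n residues (N, CA, C, O) on a rippled ring around the
# origin. Non-planar so superposition is never degenerate.
#' @noRd
scaffold_atoms <- function(n_residues, ring_radius = 12, chain = "A") {
  theta <- 2 * pi * (seq_len(n_residues) - 1L) / n_residues
  ca <- cbind(ring_radius * cos(theta), ring_radius * sin(theta),
              2.0 * sin(3 * theta))
  # local residue frame follows the ring: x -> radial, y -> tangential
  offs <- rbind(N = c(0.6, 0.5, 0.8), CA = c(0, 0, 0), C = c(0.6, 0.9, -0.6),
                O = c(1.7, 1.2, -0.8))
  rows <- lapply(seq_len(n_residues), function(i) {
    rot <- matrix(c(cos(theta[i]), sin(theta[i]), 0,
                    -sin(theta[i]), cos(theta[i]), 0,
                    0, 0, 1), 3L, 3L)
    xyz <- sweep(tcrossprod(offs, rot), 2L, -ca[i, ])
    data.frame(
      name = rownames(offs),
      resname = "GLY",
      chain = chain,
      resid = i,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      element = c("N", "C", "C", "O"),
      record = "ATOM", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @noRd
finish_atoms <- function(atoms, water_names = DEFAULT_WATER_NAMES) {
  atoms$serial <- seq_len(nrow(atoms))
  atoms$occ <- 1
  atoms$bfactor <- 0
  atoms$water <- toupper(atoms$resname) %in% toupper(water_names)
  atoms[, c("serial", "name", "resname", "chain", "resid", "x", "y", "z",
            "occ", "bfactor", "element", "record", "water")]
}

#' @noRd
water_rows <- function(resid, pos, resname = "HOH", chain = "W",
                       with_h = FALSE) {
  rows <- data.frame(name = "O", resname = resname, chain = chain,
                     resid = resid, x = pos[1L], y = pos[2L], z = pos[3L],
                     element = "O", record = "HETATM",
                     stringsAsFactors = FALSE)
  if (with_h) {
    h <- rbind(pos + c(0.76, 0.59, 0), pos + c(-0.76, 0.59, 0))
    rows <- rbind(rows, data.frame(
      name = c("H1", "H2"), resname = resname, chain = chain, resid = resid,
      x = h[, 1L], y = h[, 2L], z = h[, 3L], element = "H",
      record = "HETATM", stringsAsFactors = FALSE))
  }
  rows
}

#' Specification of a synthetic crystal family
#'
#' Describes a family of near-identical protein-ligand crystals sharing a
#' scaffold, with conserved water sites planted near the ligand at stated
#' presence fractions, guaranteed bridging contacts (one ligand and one
#' protein polar partner per site water, placed at `contact_distance` from
#' the realised water position in every structure that has it), far-off
#' distractor waters, and an apo variant whose ordered waters sit where the
#' ligand binds.
#'
#' @param n_structures number of holo family members.
#' @param n_residues scaffold residues.
#' @param ligand_resname ligand residue name.
#' @param site_fractions presence fraction of each conserved site, in (0, 1];
#'   site s appears in the first `round(fraction * n_structures)` members.
#' @param jitter_sigma Gaussian positional jitter of site waters, angstrom.
#' @param contact_distance planted hydrogen-bond length, angstrom.
#' @param protein_jitter_sigma per-atom scaffold jitter, angstrom.
#' @param n_distractors far-from-site waters per structure.
#' @param n_displaced apo ordered waters overlapping the ligand volume.
#' @param rigid_motion apply a random rigid transform per structure.
#' @param seed integer seed.
#' @return A `crystal_family_spec` list.
#' @export
crystal_family_spec <- function(n_structures = 10, n_residues = 40,
                                ligand_resname = "LIG",
                                site_fractions = c(1.0, 0.8, 0.5),
                                jitter_sigma = 0.3, contact_distance = 2.8,
                                protein_jitter_sigma = 0.05,
                                n_distractors = 6, n_displaced = 9,
                                rigid_motion = TRUE, seed = 42) {
  stopifnot(n_structures >= 1, all(site_fractions > 0 & site_fractions <= 1),
            jitter_sigma >= 0, contact_distance > 0, n_displaced <= 9)
  structure(as.list(environment()), class = "crystal_family_spec")
}

#' Generate a synthetic crystal family with planted ground truth
#'
#' @param spec a [crystal_family_spec()].
#' @return List with `structures` (holo `pdb_structure` list), `apo` (the
#'   ligand-free reference) and `ground_truth` (planted sites with their
#'   member structures and water residue numbers, planted bridging contacts,
#'   displaced-water count, seed echo).
#' @export
make_crystal_family <- function(spec) {
  stopifnot(inherits(spec, "crystal_family_spec"))
  with_private_seed(spec$seed, {
    n <- spec$n_structures
    prot <- scaffold_atoms(spec$n_residues)

    # ligand: 6-atom ring (2 angstrom neighbour spacing so jittered contact
    # partners never clash), polar anchors at three alternating positions
    phi <- 2 * pi * (0:5) / 6
    lig_xyz <- cbind(2.0 * cos(phi), 2.0 * sin(phi), 0.3 * sin(2 * phi))
    lig_elem <- rep("C", 6L)
    anchors <- c(1L, 3L, 5L)
    lig_elem[anchors] <- c("O", "N", "O")
    lig_name <- paste0(lig_elem, seq_len(6L))
    lig <- data.frame(name = lig_name, resname = spec$ligand_resname,
                      chain = "A", resid = 900L,
                      x = lig_xyz[, 1L], y = lig_xyz[, 2L], z = lig_xyz[, 3L],
                      element = lig_elem, record = "HETATM",
                      stringsAsFactors = FALSE)

    n_sites <- length(spec$site_fractions)
    if (n_sites > length(anchors)) {
      stop("at most 3 conserved sites are supported by the default ligand")
    }
    out_dir <- function(v) v / sqrt(sum(v^2))
    site_pos <- t(vapply(seq_len(n_sites), function(s) {
      a <- lig_xyz[anchors[s], ]
      a + out_dir(c(a[1L], a[2L], 0)) * spec$contact_distance
    }, numeric(3L)))
    members <- lapply(spec$site_fractions,
                      function(f) seq_len(round(f * n)))

    labels <- sprintf("SYN%02d", seq_len(n))
    truth_sites <- vector("list", n_sites)
    contacts <- list()
    structures <- vector("list", n)

    for (i in seq_len(n)) {
      prot_i <- prot
      jig <- matrix(stats::rnorm(3L * nrow(prot), 0, spec$protein_jitter_sigma),
                    ncol = 3L)
      prot_i[, c("x", "y", "z")] <- prot_i[, c("x", "y", "z")] + jig
      lig_i <- lig
      extra <- list()
      wat <- list()
      for (s in seq_len(n_sites)) {
        present <- i %in% members[[s]]
        w <- site_pos[s, ] + stats::rnorm(3L, 0, spec$jitter_sigma)
        anchor_dir <- out_dir(lig_xyz[anchors[s], ] - site_pos[s, ])
        prot_dir <- out_dir(c(-anchor_dir[2L], anchor_dir[1L], 0.4))
        if (present) {
          resid_w <- 2000L + 100L * s + i
          wat[[length(wat) + 1L]] <- water_rows(resid_w, w)
          # reposition the planted partners so each contact is exact
          lig_i[anchors[s], c("x", "y", "z")] <-
            w + anchor_dir * spec$contact_distance
          pp <- w + prot_dir * spec$contact_distance
          truth_sites[[s]] <- rbind(truth_sites[[s]], data.frame(
            label = labels[i], resid = resid_w, stringsAsFactors = FALSE))
          contacts[[length(contacts) + 1L]] <- data.frame(
            label = labels[i], water_resid = resid_w,
            ligand_atom = lig_name[anchors[s]], protein_atom = "OD1",
            distance = spec$contact_distance, stringsAsFactors = FALSE)
        } else {
          pp <- site_pos[s, ] + prot_dir * spec$contact_distance
        }
        extra[[length(extra) + 1L]] <- data.frame(
          name = "OD1", resname = "ASP", chain = "A",
          resid = 100L + s, x = pp[1L], y = pp[2L], z = pp[3L],
          element = "O", record = "ATOM", stringsAsFactors = FALSE)
      }
      for (k in seq_len(spec$n_distractors)) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        pos <- u * stats::runif(1L, 16, 20)
        wat[[length(wat) + 1L]] <- water_rows(3000L + k, pos)
      }
      atoms <- finish_atoms(rbind(prot_i, do.call(rbind, extra), lig_i,
                                  do.call(rbind, wat)))
      st <- new_structure(atoms, label = labels[i])
      if (spec$rigid_motion) {
        rot <- random_rotation()
        trans <- stats::runif(3L, -8, 8)
        xyz <- tcrossprod(coords_of(st), rot) +
          matrix(trans, nrow(atoms), 3L, byrow = TRUE)
        st$atoms$x <- xyz[, 1L]
        st$atoms$y <- xyz[, 2L]
        st$atoms$z <- xyz[, 3L]
      }
      check <- dist_xyz(coords_of(st), coords_of(st))
      diag(check) <- Inf
      if (min(check) < 0.5) {
        bad <- which(check == min(check), arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "generation error: planted atoms closer than 0.5 angstrom (%s%d@%s / %s%d@%s, %.2f A)",
          atoms$resname[bad[1L]], atoms$resid[bad[1L]], atoms$name[bad[1L]],
          atoms$resname[bad[2L]], atoms$resid[bad[2L]], atoms$name[bad[2L]],
          min(check)))
      }
      structures[[i]] <- st
    }

    # apo: scaffold + ordered waters (site positions and ligand-overlapping
    # displaced waters), no ligand
    apo_wat <- list()
    for (s in seq_len(n_sites)) {
      apo_wat[[length(apo_wat) + 1L]] <-
        water_rows(2000L + 100L * s, site_pos[s, ])
    }
    # candidate ordered-water positions inside the ligand volume: the six
    # atom positions plus three ring-chord midpoints, all within the
    # displacement radius of a never-repositioned ligand carbon
    mid <- (lig_xyz[c(1L, 3L, 5L), ] + lig_xyz[c(2L, 4L, 6L), ]) / 2
    disp_pos <- sweep(rbind(lig_xyz, mid), 2L, c(0, 0, -0.2))
    disp_resid <- integer(0)
    for (k in seq_len(spec$n_displaced)) {
      disp_resid <- c(disp_resid, 4000L + k)
      apo_wat[[length(apo_wat) + 1L]] <- water_rows(4000L + k, disp_pos[k, ])
    }
    apo <- new_structure(
      finish_atoms(rbind(prot, do.call(rbind, apo_wat))), label = "APO")

    ground_truth <- list(
      seed = spec$seed,
      ligand_resname = spec$ligand_resname,
      sites = lapply(seq_len(n_sites), function(s) list(
        position = as.numeric(site_pos[s, ]),
        fraction = spec$site_fractions[s],
        multiplicity = length(members[[s]]),
        members = truth_sites[[s]]
      )),
      contacts = do.call(rbind, contacts),
      displaced = list(count = spec$n_displaced, resids = disp_resid)
    )
    list(structures = structures, apo = apo, ground_truth = ground_truth)
  })
}

#' One scripted water of a synthetic trajectory
#'
#' A scripted water occupies a fixed site (with Gaussian jitter) in scheduled
#' frames and diffuses in the bulk region otherwise. The site is either
#' given explicitly (`site`), or placed perpendicular to the ligand chain at
#' a stated minimum ligand distance (`distance`) by the generator. Schedules
#' are deterministic by default so scripted fractions are realised exactly:
#' `"block"` puts the present frames first, `"even"` spreads them uniformly,
#' `"bernoulli"` draws them independently.
#'
#' @param fraction fraction of frames present, in [0, 1].
#' @param distance target minimum distance to the ligand, angstrom.
#' @param site explicit site position (overrides `distance`).
#' @param schedule explicit 0/1 per-frame schedule (overrides `fraction`).
#' @param jitter_sigma positional jitter when present, angstrom.
#' @param mode schedule layout for `fraction`.
#' @return A `water_script` list.
#' @export
water_script <- function(fraction = 1, distance = NULL, site = NULL,
                         schedule = NULL, jitter_sigma = 0.15,
                         mode = c("block", "even", "bernoulli")) {
  stopifnot(fraction >= 0, fraction <= 1, jitter_sigma >= 0)
  mode <- match.arg(mode)
  structure(list(fraction = fraction, distance = distance, site = site,
                 schedule = schedule, jitter_sigma = jitter_sigma,
                 mode = mode, sites = NULL),
            class = "water_script")
}

#' Specification of a synthetic hydration trajectory
#'
#' The solute is a scaffold protein ring around an elongated ligand chain
#' along x (atoms spaced 0.8 angstrom), so a water placed perpendicular to
#' the chain at distance d has minimum ligand distance exactly d. Scripted
#' waters follow their [water_script()]; bulk waters random-walk inside a
#' spherical shell 10-25 angstrom from the ligand, which keeps them outside
#' both solvation shells. With `rigid_tumbling` the whole system is given a
#' random rigid motion every frame (drawn after all placement randomness, so
#' the planted ground truth is identical with tumbling on or off).
#'
#' @param n_frames number of frames.
#' @param frame_interval frame spacing, ps (default 2).
#' @param n_residues scaffold residues.
#' @param ring_radius scaffold ring radius, angstrom; smaller rings bring
#'   backbone atoms into the 5 angstrom active-site region of the ligand.
#' @param ligand_resname ligand residue name.
#' @param ligand_atoms ligand atom names along the chain (elements inferred).
#' @param water_scripts list of [water_script()].
#' @param n_bulk_waters diffusing bulk waters.
#' @param bulk_sigma bulk random-walk step, angstrom per frame.
#' @param protein_jitter_sigma per-frame scaffold thermal jitter, angstrom.
#' @param with_hydrogens add H1/H2 to every water.
#' @param rigid_tumbling random rigid motion of the whole frame.
#' @param seed integer seed.
#' @return A `trajectory_spec` list.
#' @export
trajectory_spec <- function(n_frames = 500, frame_interval = 2,
                            n_residues = 30, ring_radius = 12,
                            ligand_resname = "LIG",
                            ligand_atoms = c("C1", "N2", "C3", "O4", "C5", "N6"),
                            water_scripts = list(),
                            n_bulk_waters = 10, bulk_sigma = 0.5,
                            protein_jitter_sigma = 0.25,
                            with_hydrogens = TRUE, rigid_tumbling = FALSE,
                            seed = 1) {
  if (n_frames < 1) stop("trajectory spec needs n_frames >= 1")
  stopifnot(frame_interval > 0, bulk_sigma >= 0, protein_jitter_sigma >= 0)
  for (ws in water_scripts) {
    if (!inherits(ws, "water_script")) stop("water_scripts must be water_script objects")
    if (!is.null(ws$schedule) && length(ws$schedule) != n_frames &&
        is.null(dim(ws$schedule))) {
      stop("schedule length does not match n_frames")
    }
  }
  structure(as.list(environment()), class = "trajectory_spec")
}

# Resolve one script's site matrix and integer per-frame schedule
# (0 = bulk, j = sites[j, ]).
#' @noRd
resolve_script <- function(ws, k, lig_xyz, n_frames) {
  if (is.null(ws$sites)) {
    if (!is.null(ws$site)) {
      ws$sites <- matrix(as.numeric(ws$site), 1L)
    } else if (!is.null(ws$distance)) {
      anchor <- lig_xyz[1L + (k - 1L) %% nrow(lig_xyz), ]
      phi <- (k - 1L) * 2.399963   # golden angle spreads waters apart
      ws$sites <- matrix(anchor +
                           ws$distance * c(0, cos(phi), sin(phi)), 1L)
    } else {
      stop("water_script needs a site, a distance, or a sites matrix")
    }
  }
  if (is.null(ws$schedule)) {
    n1 <- round(ws$fraction * n_frames)
    ws$schedule <- switch(ws$mode,
      block = rep(c(1L, 0L), c(n1, n_frames - n1)),
      even = as.integer(floor(seq_len(n_frames) * ws$fraction) -
                          floor((seq_len(n_frames) - 1L) * ws$fraction) > 0),
      bernoulli = stats::rbinom(n_frames, 1L, ws$fraction)
    )
  }
  ws$schedule <- as.integer(ws$schedule)
  if (length(ws$schedule) != n_frames) stop("schedule length mismatch")
  if (any(ws$schedule < 0L | ws$schedule > nrow(ws$sites))) {
    stop("schedule indexes a site that does not exist")
  }
  ws
}

#' Generate a synthetic hydration trajectory with planted ground truth
#'
#' @param spec a [trajectory_spec()].
#' @return List with `trajectory` (a `pdb_trajectory`) and `ground_truth`:
#'   per scripted water its residue number, site(s), integer schedule and
#'   realised occupancy; an independently recounted per-frame first/second
#'   shell series; and the seed echo.
#' @export
make_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_private_seed(spec$seed, {
    nf <- spec$n_frames
    prot <- scaffold_atoms(spec$n_residues, ring_radius = spec$ring_radius)
    lig_xyz <- cbind(0.8 * (seq_along(spec$ligand_atoms) - 1L), 0, 0)
    lig <- data.frame(
      name = spec$ligand_atoms, resname = spec$ligand_resname, chain = "A",
      resid = 900L, x = lig_xyz[, 1L], y = lig_xyz[, 2L], z = lig_xyz[, 3L],
      element = infer_element(spec$ligand_atoms), record = "HETATM",
      stringsAsFactors = FALSE)
    lig_center <- colMeans(lig_xyz)

    scripts <- spec$water_scripts
    scripts <- lapply(seq_along(scripts), function(k) {
      resolve_script(scripts[[k]], k, lig_xyz, nf)
    })
    n_script <- length(scripts)
    n_bulk <- spec$n_bulk_waters
    n_wat <- n_script + n_bulk

    # initial bulk positions for every water (scripted waters park here when
    # absent), then continuous random walks, reflected into the 10-25 A shell
    bulk_pos <- array(NA_real_, c(n_wat, 3L, nf))
    for (w in seq_len(n_wat)) {
      u <- stats::rnorm(3L)
      p <- lig_center + u / sqrt(sum(u^2)) * stats::runif(1L, 12, 22)
      for (f in seq_len(nf)) {
        if (f > 1L) p <- p + stats::rnorm(3L, 0, spec$bulk_sigma)
        r <- sqrt(sum((p - lig_center)^2))
        if (r < 10 || r > 25) {
          p <- lig_center + (p - lig_center) * (min(max(r, 10), 25) / r)
        }
        bulk_pos[w, , f] <- p
      }
    }
    # realised scripted positions
    script_pos <- array(NA_real_, c(max(n_script, 1L), 3L, nf))
    for (k in seq_len(n_script)) {
      ws <- scripts[[k]]
      for (f in seq_len(nf)) {
        s <- ws$schedule[f]
        script_pos[k, , f] <- if (s > 0L) {
          ws$sites[s, ] + stats::rnorm(3L, 0, ws$jitter_sigma)
        } else {
          bulk_pos[k, , f]
        }
      }
    }
    prot_jit <- array(stats::rnorm(nrow(prot) * 3L * nf, 0,
                                   spec$protein_jitter_sigma),
                      c(nrow(prot), 3L, nf))

    wat_rows <- do.call(rbind, c(
      lapply(seq_len(n_script), function(k) {
        water_rows(500L + k, script_pos[k, , 1L], resname = "WAT",
                   with_h = spec$with_hydrogens)
      }),
      lapply(seq_len(n_bulk), function(k) {
        water_rows(600L + k, bulk_pos[n_script + k, , 1L], resname = "WAT",
                   with_h = spec$with_hydrogens)
      })
    ))
    atoms <- finish_atoms(rbind(prot, lig, wat_rows))
    topo <- new_structure(atoms, label = "synthetic-trajectory")

    np <- nrow(prot)
    nl <- nrow(lig)
    apw <- if (spec$with_hydrogens) 3L else 1L
    h_off <- rbind(c(0.76, 0.59, 0), c(-0.76, 0.59, 0))
    n_atoms <- nrow(atoms)
    coords <- array(NA_real_, c(n_atoms, 3L, nf))
    coords[seq_len(np), , ] <-
      array(as.matrix(prot[, c("x", "y", "z")]), c(np, 3L, nf)) + prot_jit
    coords[np + seq_len(nl), , ] <- array(lig_xyz, c(nl, 3L, nf))
    o_pos <- array(NA_real_, c(n_wat, 3L, nf))
    if (n_script > 0L) o_pos[seq_len(n_script), , ] <-
      script_pos[seq_len(n_script), , , drop = FALSE]
    if (n_bulk > 0L) o_pos[n_script + seq_len(n_bulk), , ] <-
      bulk_pos[n_script + seq_len(n_bulk), , , drop = FALSE]
    o_rows <- np + nl + apw * (seq_len(n_wat) - 1L) + 1L
    coords[o_rows, , ] <- o_pos
    if (spec$with_hydrogens) {
      for (h in 1:2) {
        coords[o_rows + h, , ] <- o_pos +
          array(rep(h_off[h, ], each = n_wat), c(n_wat, 3L, nf))
      }
    }

    # ground truth before any tumbling: presence schedules and an
    # independent brute-force shell recount from the emitted oxygen positions
    first <- integer(nf)
    second <- integer(nf)
    for (f in seq_len(nf)) {
      lxyz <- coords[np + seq_len(nl), , f, drop = FALSE]
      dim(lxyz) <- c(nl, 3L)
      for (w in seq_len(n_wat)) {
        o <- coords[o_rows[w], , f]
        dmin <- sqrt(min(rowSums(sweep(lxyz, 2L, o)^2)))
        if (dmin <= 3.4) first[f] <- first[f] + 1L
        else if (dmin <= 5.0) second[f] <- second[f] + 1L
      }
    }

    # frame 1 stays untransformed: it defines the lab frame that per-frame
    # fitting (RMS fit to the first frame) recovers
    if (spec$rigid_tumbling && nf > 1L) {
      for (f in 2:nf) {
        rot <- random_rotation()
        trans <- stats::runif(3L, -5, 5)
        coords[, , f] <- tcrossprod(coords[, , f], rot) +
          matrix(trans, nrow(atoms), 3L, byrow = TRUE)
      }
    }

    ground_truth <- list(
      seed = spec$seed,
      waters = lapply(seq_len(n_script), function(k) list(
        resid = 500L + k,
        sites = scripts[[k]]$sites,
        schedule = scripts[[k]]$schedule,
        occupancy = 100 * sum(scripts[[k]]$schedule > 0L) / nf
      )),
      shells = list(first = first, second = second,
                    mean_first = mean(first), mean_second = mean(second))
    )
    list(trajectory = new_trajectory(topo, coords, spec$frame_interval),
         ground_truth = ground_truth)
  })
}

#' Trajectory spec with scripted mean solvation-shell populations
#'
#' Builds a [trajectory_spec()] whose scripted waters realise the requested
#' mean first- and second-shell counts exactly: `floor(mean)` waters present
#' in every frame plus one water present for the fractional remainder, at
#' guaranteed in-shell distances (2.6 and 4.2 angstrom, safely inside the
#' 3.4 / (3.4, 5] bands at the default jitter).
#'
#' @param first_mean,second_mean target mean shell populations.
#' @param n_frames frames.
#' @param jitter_sigma site jitter, angstrom.
#' @param seed integer seed.
#' @param ... passed to [trajectory_spec()].
#' @return A `trajectory_spec`.
#' @export
shell_spec <- function(first_mean, second_mean, n_frames = 500,
                       jitter_sigma = 0.15, seed = 1, ...) {
  build <- function(target, dist) {
    full <- floor(target)
    frac <- target - full
    ws <- lapply(seq_len(full), function(i) {
      water_script(fraction = 1, distance = dist, jitter_sigma = jitter_sigma)
    })
    if (frac > 1e-9) {
      ws <- c(ws, list(water_script(fraction = frac, distance = dist,
                                    jitter_sigma = jitter_sigma)))
    }
    ws
  }
  trajectory_spec(
    n_frames = n_frames,
    water_scripts = c(build(first_mean, 2.6), build(second_mean, 4.2)),
    seed = seed, ...
  )
}

#' Trajectory spec with a scripted per-atom contact-occupancy table
#'
#' One water visits a ladder of positions beside an elongated five-atom
#' ligand chain so that its 5-angstrom contact with atom j holds for exactly
#' `round(rates_pct[j] / 100 * n_frames)` frames, arranged as decaying
#' blocks (the contact to the chain end is lost first as the water steps
#' away). Rates must be non-increasing. Recomputing contact occupancies
#' from the emitted frames recovers the rates exactly (at the resolution of
#' one frame).
#'
#' @param rates_pct five occupancy percentages, non-increasing.
#' @param n_frames frames; rates are realised to the nearest 1/n_frames.
#' @param atom_names ligand atom names, nearest-to-water first.
#' @param jitter_sigma water jitter, angstrom (small: the position ladder has
#'   about 0.3 angstrom of distance margin per rung).
#' @param seed integer seed.
#' @param ... passed to [trajectory_spec()].
#' @return A `trajectory_spec`.
#' @export
contact_table_spec <- function(rates_pct = c(98.82, 97.55, 95.27, 91.91, 89.64),
                               n_frames = 10000,
                               atom_names = c("C9", "O10", "C11", "C19", "O6I"),
                               jitter_sigma = 0.03, seed = 1, ...) {
  stopifnot(length(rates_pct) == 5L, length(atom_names) == 5L,
            all(diff(rates_pct) <= 0), all(rates_pct >= 0 & rates_pct <= 100))
  k <- round(rates_pct / 100 * n_frames)
  # frames in "class j" satisfy atoms 1..j; class counts from the rate ladder
  class_n <- c(n_frames - k[1L], k[1L] - k[2L], k[2L] - k[3L], k[3L] - k[4L],
               k[4L] - k[5L], k[5L])
  schedule <- rep(c(5L, 4L, 3L, 2L, 1L, 0L),
                  c(class_n[6L], class_n[5L], class_n[4L], class_n[3L],
                    class_n[2L], class_n[1L]))
  # ladder positions: atoms at x = 0, 0.8, ..., 3.2; position a in the
  # ladder satisfies atom k iff (a + x_k)^2 + 3^2 <= 25, i.e. a <= 4 - x_k
  a <- c(3.6, 2.8, 2.0, 1.2, 0.4)      # class 1..5 offsets
  sites <- cbind(-a, 3.0, 0)
  ws <- water_script(jitter_sigma = jitter_sigma)
  ws$sites <- sites
  ws$schedule <- schedule
  trajectory_spec(n_frames = n_frames, ligand_atoms = atom_names,
                  water_scripts = list(ws), seed = seed, ...)
}
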