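#' Crystal-water analysis
#'
#' Distance-criterion hydrogen bonds between heavy polar atoms (crystal
#' structures usually lack hydrogens, so the criterion is a donor/acceptor
#' heavy-atom distance of at most 3 angstrom), active-site water extraction,
#' bridging-water classification, conserved-water clustering across a
#' superposed family, and apo-versus-holo displaced-water counting.
#'
#' @name crystal-water
NULL

#' Distance-criterion hydrogen bonds between two atom groups
#'
#' Reports every pair of polar heavy atoms (N, O, F, S) with one atom in each
#' group and inter-atomic distance at most `cutoff`. No angle term is used:
#' this is the crystallographic criterion, applied to structures without
#' hydrogens. The result is symmetric in the two groups.
#'
#' @param struct a `pdb_structure`.
#' @param group_a,group_b disjoint atom selections.
#' @param cutoff maximum heavy-atom distance, angstrom (default 3.0).
#' @return Data frame with `atom_a`, `atom_b` (RES@NAME references), `idx_a`,
#'   `idx_b` (atom indices) and `distance` (angstrom), ordered by
#'   `(idx_a, idx_b)`.
#' @export
detect_hbonds_crystal <- function(struct, group_a, group_b, cutoff = 3.0) {
  stopifnot(inherits(struct, "pdb_structure"), cutoff > 0)
  if (length(intersect(group_a, group_b))) {
    stop("hydrogen-bond groups must be disjoint")
  }
  at <- struct$atoms
  polar <- which(at$element %in% POLAR_ELEMENTS)
  ia <- intersect(as.integer(group_a), polar)
  ib <- intersect(as.integer(group_b), polar)
  empty <- data.frame(atom_a = character(0), atom_b = character(0),
                      idx_a = integer(0), idx_b = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(empty)
  d <- dist_xyz(coords_of(struct, sel = ia), coords_of(struct, sel = ib))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- ia[hit[, 1L]]
  j <- ib[hit[, 2L]]
  out <- data.frame(
    atom_a = atom_ref(at$resname[i], at$resid[i], at$name[i], at$water[i]),
    atom_b = atom_ref(at$resname[j], at$resid[j], at$name[j], at$water[j]),
    idx_a = i, idx_b = j, distance = d[hit],
    stringsAsFactors = FALSE
  )
  out[order(out$idx_a, out$idx_b), , drop = FALSE]
}

#' Waters in the active site around a ligand
#'
#' A water belongs to the active site when its oxygen lies within `radius`
#' (default 5 angstrom) of any ligand atom.
#'
#' @param struct a `pdb_structure`.
#' @param ligand ligand atom selection (see [select_atoms()]).
#' @param radius cutoff, angstrom.
#' @return Data frame of water residues (`resname`, `resid`, `chain`,
#'   `water_id`, `min_distance`), sorted by residue number.
#' @export
find_active_site_waters <- function(struct, ligand, radius = 5.0) {
  stopifnot(radius > 0)
  if (!length(ligand)) stop("empty selection: no ligand atoms")
  at <- struct$atoms
  wo <- which(at$water & at$element == "O")
  if (!length(wo)) {
    return(data.frame(resname = character(0), resid = integer(0),
                      chain = character(0), water_id = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  }
  md <- min_dist_to(coords_of(struct, sel = wo), coords_of(struct, sel = ligand))
  keep <- wo[md <= radius]
  out <- data.frame(
    resname = at$resname[keep], resid = at$resid[keep], chain = at$chain[keep],
    water_id = paste0(at$resname[keep], at$resid[keep]),
    min_distance = md[md <= radius], stringsAsFactors = FALSE
  )
  out[order(out$resid), , drop = FALSE]
}

#' Classify bridging waters
#'
#' A water bridges the complex when it makes at least one distance-criterion
#' hydrogen bond to the ligand and at least one to protein atoms
#' simultaneously. With `chain_waters = TRUE`, a contact may also be mediated
#' by one intervening hydrogen-bonded water (a two-water bridge); the default
#' is direct contact only.
#'
#' @param struct a `pdb_structure` containing protein, ligand and waters.
#' @param ligand ligand atom selection.
#' @param cutoff hydrogen-bond distance cutoff, angstrom.
#' @param chain_waters allow one-water-mediated bridges.
#' @return Data frame with one row per bridging water: `water_id`, `resid`,
#'   `chain`, `n_ligand_contacts`, `n_protein_contacts`, `chained` (whether
#'   the bridge needed an intervening water). The attribute `"contacts"`
#'   carries all underlying water-ligand and water-protein hydrogen bonds.
#' @export
classify_bridging <- function(struct, ligand, cutoff = 3.0,
                              chain_waters = FALSE) {
  at <- struct$atoms
  water_o <- which(at$water & at$element == "O")
  protein <- setdiff(which(at$record == "ATOM"), as.integer(ligand))
  empty <- data.frame(water_id = character(0), resid = integer(0),
                      chain = character(0), n_ligand_contacts = integer(0),
                      n_protein_contacts = integer(0), chained = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(water_o)) return(empty)
  hb_lig <- detect_hbonds_crystal(struct, water_o, ligand, cutoff)
  hb_pro <- detect_hbonds_crystal(struct, water_o, protein, cutoff)
  lig_n <- tabulate(match(hb_lig$idx_a, water_o), length(water_o))
  pro_n <- tabulate(match(hb_pro$idx_a, water_o), length(water_o))
  has_lig <- lig_n > 0L
  has_pro <- pro_n > 0L
  chained <- rep(FALSE, length(water_o))
  if (chain_waters && length(water_o) > 1L) {
    d_ww <- dist_xyz(coords_of(struct, sel = water_o),
                     coords_of(struct, sel = water_o))
    ww <- d_ww <= cutoff & d_ww > 0
    lig_via <- has_lig | (ww %*% has_lig > 0)
    pro_via <- has_pro | (ww %*% has_pro > 0)
    chained <- (lig_via & pro_via) & !(has_lig & has_pro)
    has_lig <- as.logical(lig_via)
    has_pro <- as.logical(pro_via)
  }
  keep <- which(has_lig & has_pro)
  if (!length(keep)) return(empty)
  i <- water_o[keep]
  ord <- order(at$resid[i], at$chain[i])
  keep <- keep[ord]
  i <- i[ord]
  out <- data.frame(
    water_id = paste0(at$resname[i], at$resid[i]),
    resid = at$resid[i], chain = at$chain[i],
    n_ligand_contacts = lig_n[keep], n_protein_contacts = pro_n[keep],
    chained = chained[keep], stringsAsFactors = FALSE
  )
  attr(out, "contacts") <- list(ligand = hb_lig, protein = hb_pro)
  out
}

#' Cluster conserved waters across a superposed family
#'
#' Greedy single-linkage clustering with a per-structure cap: the water whose
#' `match_radius` neighbourhood spans the most structures seeds a cluster;
#' each structure contributes at most its nearest in-radius water; the
#' centroid is refined once and members re-gathered around it; assigned
#' waters are removed and the procedure repeats. Clusters are reported in
#' decreasing multiplicity, ties broken by ascending centroid distance to the
#' ligand (when given), then by centroid coordinates.
#'
#' @param aligned list of `pdb_structure` already superposed onto a common
#'   reference (e.g. the `accepted` output of [rmsd_filter()]).
#' @param region_of optional `n x 3` coordinate matrix (e.g. the reference
#'   ligand); only waters within `region_radius` of it are clustered and it
#'   is used for tie-breaking.
#' @param region_radius region cutoff, angstrom (default 5).
#' @param match_radius maximum member-to-centroid distance, angstrom.
#' @return List of clusters, each a list with `centroid`, `multiplicity` and
#'   `members` (data frame: `label`, `water_id`, `resid`, `x`, `y`, `z`,
#'   `dist_to_centroid`).
#' @export
cluster_conserved_waters <- function(aligned, region_of = NULL,
                                     region_radius = 5.0, match_radius = 1.2) {
  stopifnot(match_radius > 0)
  pool <- do.call(rbind, lapply(aligned, function(st) {
    at <- st$atoms
    wo <- which(at$water & at$element == "O")
    if (!length(wo)) return(NULL)
    data.frame(label = st$label, water_id = paste0(at$resname[wo], at$resid[wo]),
               resid = at$resid[wo], x = at$x[wo], y = at$y[wo], z = at$z[wo],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || !nrow(pool)) return(list())
  if (!is.null(region_of)) {
    md <- min_dist_to(as.matrix(pool[, c("x", "y", "z")]), region_of)
    pool <- pool[md <= region_radius, , drop = FALSE]
  }
  if (!nrow(pool)) return(list())
  # Deterministic candidate order: (label, resid).
  pool <- pool[order(pool$label, pool$resid), , drop = FALSE]
  xyz <- as.matrix(pool[, c("x", "y", "z")])
  free <- rep(TRUE, nrow(pool))
  clusters <- list()
  gather <- function(center, active) {
    d <- as.numeric(dist_xyz(matrix(center, 1L), xyz[active, , drop = FALSE]))
    cand <- data.frame(row = which(active)[d <= match_radius],
                       d = d[d <= match_radius])
    if (!nrow(cand)) return(integer(0))
    cand$label <- pool$label[cand$row]
    cand <- cand[order(cand$label, cand$d), , drop = FALSE]
    cand$row[!duplicated(cand$label)]
  }
  while (any(free)) {
    span <- integer(nrow(pool))
    fi <- which(free)
    for (s in fi) {
      span[s] <- length(unique(pool$label[gather(xyz[s, ], free)]))
    }
    seed <- fi[which.max(span[fi])]
    members <- gather(xyz[seed, ], free)
    # one centroid refinement pass
    centroid <- colMeans(xyz[members, , drop = FALSE])
    members <- gather(centroid, free)
    centroid <- colMeans(xyz[members, , drop = FALSE])
    dmem <- as.numeric(dist_xyz(matrix(centroid, 1L),
                                xyz[members, , drop = FALSE]))
    keep <- dmem <= match_radius
    members <- members[keep]
    dmem <- dmem[keep]
    if (!length(members)) { # isolated outlier: singleton cluster
      members <- seed
      centroid <- xyz[seed, ]
      dmem <- 0
    }
    free[members] <- FALSE
    mdf <- pool[members, , drop = FALSE]
    mdf$dist_to_centroid <- dmem
    rownames(mdf) <- NULL
    clusters[[length(clusters) + 1L]] <-
      list(centroid = as.numeric(centroid), multiplicity = length(members),
           members = mdf)
  }
  mult <- vapply(clusters, function(cl) cl$multiplicity, integer(1L))
  tie <- if (!is.null(region_of)) {
    vapply(clusters, function(cl) min_dist_to(matrix(cl$centroid, 1L),
                                              region_of), numeric(1L))
  } else {
    vapply(clusters, function(cl) cl$centroid[1L] * 1e6 +
             cl$centroid[2L] * 1e3 + cl$centroid[3L], numeric(1L))
  }
  clusters[order(-mult, tie)]
}

#' Count apo waters displaced by a ligand
#'
#' Counts ordered waters of the apo structure whose oxygen falls within
#' `overlap_radius` (default 1.4 angstrom, roughly the water-oxygen van der
#' Waals radius) of any ligand atom of the superposed holo structure — the
#' waters the bound ligand expels from the site.
#'
#' @param apo the apo `pdb_structure` (reference frame).
#' @param holo_aligned a holo `pdb_structure` already superposed onto `apo`.
#' @param ligand_resname ligand residue name in `holo_aligned`.
#' @param overlap_radius displacement cutoff, angstrom.
#' @return List with `count` and `waters` (data frame as in
#'   [find_active_site_waters()]).
#' @export
displaced_waters <- function(apo, holo_aligned, ligand_resname,
                             overlap_radius = 1.4) {
  stopifnot(overlap_radius > 0)
  lig <- select_atoms(holo_aligned, "ligand", resname = ligand_resname)
  at <- apo$atoms
  wo <- which(at$water & at$element == "O")
  if (!length(wo)) {
    return(list(count = 0L, waters = data.frame(
      resname = character(0), resid = integer(0), chain = character(0),
      water_id = character(0), min_distance = numeric(0),
      stringsAsFactors = FALSE)))
  }
  md <- min_dist_to(coords_of(apo, sel = wo),
                    coords_of(holo_aligned, sel = lig))
  keep <- md <= overlap_radius
  waters <- data.frame(
    resname = at$resname[wo][keep], resid = at$resid[wo][keep],
    chain = at$chain[wo][keep],
    water_id = paste0(at$resname[wo][keep], at$resid[wo][keep]),
    min_distance = md[keep], stringsAsFactors = FALSE
  )
  waters <- waters[order(waters$resid), , drop = FALSE]
  rownames(waters) <- NULL
  list(count = sum(keep), waters = waters)
}

#' Family-wide ligand-water contact table
#'
#' Aligns every structure onto the reference, applies the RMSD acceptance
#' filter, and reports one row per ligand-water hydrogen bond in each
#' accepted structure, flagging bridging waters.
#'
#' @param structures list of `pdb_structure` (holo family).
#' @param reference reference `pdb_structure` (e.g. the apoenzyme).
#' @param ligand_resnames single ligand residue name, or a named character
#'   vector mapping structure label to ligand residue name.
#' @param hbond_cutoff hydrogen-bond distance cutoff, angstrom.
#' @param rmsd_threshold acceptance RMSD, angstrom.
#' @param atom_level pairing level for the filter.
#' @return Data frame with `pdb_id`, `ligand`, `ligand_atom`, `water_id`,
#'   `distance_A`, `bridging`, ordered by `(pdb_id, ligand_atom)`. The
#'   attribute `"filter_summary"` carries the RMSD filter table.
#' @export
crystal_report <- function(structures, reference, ligand_resnames,
                           hbond_cutoff = 3.0, rmsd_threshold = 0.5,
                           atom_level = "ca") {
  filt <- rmsd_filter(structures, reference, rmsd_threshold, atom_level)
  rows <- list()
  for (st in filt$accepted) {
    resn <- if (!is.null(names(ligand_resnames))) {
      ligand_resnames[[st$label]]
    } else {
      ligand_resnames[[1L]]
    }
    if (is.null(resn) || is.na(resn)) next
    lig <- tryCatch(select_atoms(st, "ligand", resname = resn),
                    error = function(e) integer(0))
    if (!length(lig)) next
    wo <- which(st$atoms$water & st$atoms$element == "O")
    hb <- detect_hbonds_crystal(st, lig, wo, hbond_cutoff)
    if (!nrow(hb)) next
    br <- classify_bridging(st, lig, hbond_cutoff)
    wid <- st$atoms$resid[hb$idx_b]
    rows[[length(rows) + 1L]] <- data.frame(
      pdb_id = st$label, ligand = resn,
      ligand_atom = st$atoms$name[hb$idx_a],
      water_id = hb$atom_b, distance_A = hb$distance,
      bridging = wid %in% br$resid, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pdb_id = character(0), ligand = character(0),
               ligand_atom = character(0), water_id = character(0),
               distance_A = numeric(0), bridging = logical(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$pdb_id, out$ligand_atom, out$water_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_summary") <- filt$summary
  out
}
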