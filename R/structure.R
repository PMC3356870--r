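#' Structures, trajectories and atom selections
#'
#' The package represents a crystal structure as a `pdb_structure`: an ordered
#' atom table plus a label, and a trajectory as a `pdb_trajectory`: a topology
#' structure plus a `n_atoms x 3 x n_frames` coordinate array at a fixed frame
#' interval (ps). Multi-model PDB is the on-disk trajectory dialect: one MODEL
#' per frame over a shared topology.
#'
#' @name structure-model
NULL

new_structure <- function(atoms, label = "structure", model_id = 1L) {
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, label = label, model_id = as.integer(model_id)),
    class = "pdb_structure"
  )
}

new_trajectory <- function(topology, coords, frame_interval = 2) {
  stopifnot(inherits(topology, "pdb_structure"))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("trajectory coordinates must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology$atoms)) {
    stop("frame coordinate count does not match topology atom count")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a positive time step in ps")
  }
  structure(
    list(topology = topology, coords = coords, frame_interval = frame_interval),
    class = "pdb_trajectory"
  )
}

#' Number of frames in a trajectory
#' @param traj a `pdb_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  dim(traj$coords)[3]
}

#' Atom coordinates as a matrix
#'
#' @param x a `pdb_structure` or `pdb_trajectory`.
#' @param frame frame index (trajectories only).
#' @param sel optional atom index vector (e.g. from [select_atoms()]).
#' @return Numeric matrix with one row per atom and columns x, y, z (angstrom).
#' @export
coords_of <- function(x, frame = 1L, sel = NULL) {
  if (inherits(x, "pdb_trajectory")) {
    m <- x$coords[, , frame, drop = FALSE]
    dim(m) <- dim(x$coords)[1:2]
  } else if (inherits(x, "pdb_structure")) {
    m <- cbind(x$atoms$x, x$atoms$y, x$atoms$z)
  } else {
    stop("coords_of() expects a pdb_structure or pdb_trajectory")
  }
  colnames(m) <- c("x", "y", "z")
  if (!is.null(sel)) m <- m[as.integer(sel), , drop = FALSE]
  m
}

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a `pdb_trajectory`.
#' @param frame frame index (1-based).
#' @param label label for the resulting structure; defaults to the topology
#'   label.
#' @return A `pdb_structure` whose atom table carries the frame's coordinates.
#' @export
frame_structure <- function(traj, frame = 1L, label = NULL) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  nf <- n_frames(traj)
  if (frame < 1L || frame > nf) stop("frame index out of range")
  st <- traj$topology
  xyz <- coords_of(traj, frame)
  st$atoms$x <- xyz[, 1L]
  st$atoms$y <- xyz[, 2L]
  st$atoms$z <- xyz[, 3L]
  st$label <- label %||% st$label
  st$model_id <- as.integer(frame)
  st
}

#' Convert a structure to a single-frame trajectory
#' @param struct a `pdb_structure`.
#' @param frame_interval frame spacing in ps for the resulting trajectory.
#' @return A one-frame `pdb_trajectory`.
#' @export
as_trajectory <- function(struct, frame_interval = 2) {
  stopifnot(inherits(struct, "pdb_structure"))
  xyz <- coords_of(struct)
  new_trajectory(struct, array(xyz, c(nrow(xyz), 3L, 1L)), frame_interval)
}

#' Parse PDB-format text into a trajectory
#'
#' Reads fixed-column (v3.3) ATOM/HETATM records. MODEL/ENDMDL blocks become
#' trajectory frames; a file without MODEL records yields one frame. Waters
#' are flagged by residue name (`water_names`, case-insensitive). Only the
#' first alternate location (blank or "A") of each atom is kept.
#'
#' @param text a single string or character vector of PDB lines.
#' @param label label stored on the topology (e.g. a PDB id).
#' @param frame_interval time between models, ps.
#' @param water_names residue names recognised as water.
#' @return A `pdb_trajectory`; use [frame_structure()] for a single model.
#' @export
parse_pdb <- function(text, label = "structure", frame_interval = 2,
                      water_names = DEFAULT_WATER_NAMES) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- text
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  if (!any(is_atom)) stop("no ATOM or HETATM records found: empty input")

  model_of_line <- cumsum(is_model)
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  model_id <- model_of_line[is_atom]
  if (all(model_id == 0L)) model_id <- model_id + 1L
  if (any(model_id == 0L)) {
    stop("ATOM records found outside MODEL blocks in a multi-model file")
  }

  fld <- function(from, to) substr(atom_lines, from, to)
  altloc <- fld(17L, 17L)
  keep <- altloc %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  atom_lineno <- atom_lineno[keep]
  model_id <- model_id[keep]
  fld <- function(from, to) substr(atom_lines, from, to)

  xyz_txt <- cbind(fld(31L, 38L), fld(39L, 46L), fld(47L, 54L))
  xyz <- suppressWarnings(matrix(as.numeric(xyz_txt), ncol = 3L))
  bad <- which(rowSums(is.na(xyz)) > 0L)
  if (length(bad)) {
    stop(sprintf("unparsable coordinate field at line %d: '%s'",
                 atom_lineno[bad[1L]], trimws(atom_lines[bad[1L]])))
  }

  serial <- suppressWarnings(as.integer(fld(7L, 11L)))
  serial[is.na(serial)] <- seq_along(serial)[is.na(serial)]
  name <- trimws(fld(13L, 16L))
  resname <- trimws(fld(18L, 21L))
  chain <- fld(22L, 22L)
  resid <- suppressWarnings(as.integer(fld(23L, 26L)))
  if (anyNA(resid)) {
    stop(sprintf("unparsable residue number at line %d",
                 atom_lineno[which(is.na(resid))[1L]]))
  }
  occ <- suppressWarnings(as.numeric(fld(55L, 60L)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(fld(61L, 66L)))
  bfac[is.na(bfac)] <- 0
  element <- toupper(trimws(fld(77L, 78L)))
  element[element == ""] <- infer_element(name[element == ""])
  record <- trimws(fld(1L, 6L))

  n_models <- max(model_id)
  per_model <- tabulate(model_id, nbins = n_models)
  if (length(unique(per_model)) != 1L) {
    stop(sprintf(
      "inconsistent trajectory: models differ in atom count (%s)",
      paste(unique(per_model), collapse = ", ")
    ))
  }
  n_atoms <- per_model[1L]

  first <- model_id == model_id[1L]
  atoms <- data.frame(
    serial = serial[first], name = name[first], resname = resname[first],
    chain = chain[first], resid = resid[first],
    x = xyz[first, 1L], y = xyz[first, 2L], z = xyz[first, 3L],
    occ = occ[first], bfactor = bfac[first], element = element[first],
    record = record[first],
    water = toupper(resname[first]) %in% toupper(water_names),
    stringsAsFactors = FALSE
  )

  arr <- array(NA_real_, c(n_atoms, 3L, n_models))
  for (m in seq_len(n_models)) {
    arr[, , m] <- xyz[model_id == m, , drop = FALSE]
  }
  new_trajectory(new_structure(atoms, label = label), arr, frame_interval)
}

#' Read a PDB file from disk
#' @inheritParams parse_pdb
#' @param path file path.
#' @return A `pdb_trajectory`.
#' @export
read_pdb <- function(path, label = NULL, frame_interval = 2,
                     water_names = DEFAULT_WATER_NAMES) {
  label <- label %||% sub("\\.pdb$", "", basename(path))
  parse_pdb(readLines(path, warn = FALSE), label = label,
            frame_interval = frame_interval, water_names = water_names)
}

#' Write a structure or trajectory as PDB text
#'
#' Multi-frame trajectories are wrapped in MODEL/ENDMDL blocks, one per frame;
#' single structures (or one-frame trajectories) are written bare.
#' Coordinates are formatted `%8.3f`; `parse_pdb(write_pdb(x))` recovers all
#' stored atom fields.
#'
#' @param x a `pdb_structure` or `pdb_trajectory`.
#' @param path optional file to write; when `NULL` the text is returned.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(x, path = NULL) {
  traj <- if (inherits(x, "pdb_structure")) as_trajectory(x) else x
  stopifnot(inherits(traj, "pdb_trajectory"))
  if (max(abs(traj$coords)) >= 1e4) {
    stop("coordinate magnitude >= 10^4 angstrom cannot be formatted in PDB columns")
  }
  at <- traj$topology$atoms
  # Atom names shorter than 4 characters start in column 14 by convention.
  name_fmt <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1L, 4L),
                     sprintf(" %-3s", at$name))
  nf <- n_frames(traj)
  blocks <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- coords_of(traj, f)
    body <- sprintf(
      "%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$record, at$serial, name_fmt, at$resname, at$chain, at$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], at$occ, at$bfactor, at$element
    )
    blocks[[f]] <- if (nf > 1L) {
      c(sprintf("MODEL     %4d", f), body, "ENDMDL")
    } else {
      body
    }
  }
  out <- paste(c(unlist(blocks), "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

#' Select atoms of a structure
#'
#' Builds an atom index vector by category. `"ligand"` takes all HETATM atoms
#' of the named (non-water) residue; `"protein"` all ATOM records; `"water"`
#' all water-flagged residues; `"ca"` and `"backbone"` the protein C-alpha and
#' N/CA/C/O atoms; `"within"` all atoms of residues having at least one atom
#' within `radius` angstrom of the base selection `of` (whole residues are
#' kept so that waters count as molecules, not atoms).
#'
#' @param struct a `pdb_structure`.
#' @param kind one of `"ligand"`, `"protein"`, `"water"`, `"ca"`,
#'   `"backbone"`, `"within"`.
#' @param resname ligand residue name (for `kind = "ligand"`).
#' @param radius cutoff in angstrom (for `kind = "within"`).
#' @param of base selection (for `kind = "within"`).
#' @return Integer atom indices with class `atom_selection`.
#' @export
select_atoms <- function(struct, kind = c("ligand", "protein", "water", "ca",
                                          "backbone", "within"),
                         resname = NULL, radius = NULL, of = NULL) {
  stopifnot(inherits(struct, "pdb_structure"))
  kind <- match.arg(kind)
  at <- struct$atoms
  if (nrow(at) == 0L) stop("empty structure")
  idx <- switch(kind,
    ligand = {
      if (is.null(resname)) stop("ligand selection needs a residue name")
      i <- which(at$record == "HETATM" & !at$water &
                   toupper(at$resname) == toupper(resname))
      if (!length(i)) {
        stop(sprintf("empty selection: no HETATM residue named '%s'", resname))
      }
      i
    },
    protein = which(at$record == "ATOM"),
    water = which(at$water),
    ca = which(at$record == "ATOM" & at$name == "CA"),
    backbone = which(at$record == "ATOM" & at$name %in% c("N", "CA", "C", "O")),
    within = {
      if (is.null(radius) || radius <= 0) stop("within selection needs radius > 0")
      if (is.null(of) || !length(of)) stop("within selection needs a non-empty base selection")
      md <- min_dist_to(coords_of(struct), coords_of(struct, sel = of))
      hit_res <- unique(residue_key(at, which(md <= radius)))
      which(residue_key(at) %in% hit_res)
    }
  )
  structure(as.integer(idx), class = "atom_selection",
            description = if (kind == "ligand") paste0("ligand ", resname) else kind)
}

#' @export
print.pdb_structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("<pdb_structure> %s: %d atoms, %d residues (%d waters)\n",
              x$label, nrow(at), length(unique(residue_key(at))),
              length(unique(residue_key(at, which(at$water))))))
  invisible(x)
}

#' @export
print.pdb_trajectory <- function(x, ...) {
  cat(sprintf("<pdb_trajectory> %s: %d atoms, %d frames @ %g ps\n",
              x$topology$label, nrow(x$topology$atoms), n_frames(x),
              x$frame_interval))
  invisible(x)
}
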