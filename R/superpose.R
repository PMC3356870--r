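#' Least-squares superposition and RMSD
#'
#' Rigid-body (Kabsch) superposition of paired coordinate sets, structure
#' alignment by residue-number pairing, the RMSD acceptance filter used to
#' select family members, and per-frame trajectory RMSD traces.
#'
#' @name superpose
NULL

#' Optimal rigid superposition of paired point sets
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sqrt(mean(|R m_i + t - r_i|^2))` over paired points, via SVD of the
#' cross-covariance matrix with the reflection branch excluded
#' (`det(R) = +1`).
#'
#' @param mobile,reference `n x 3` coordinate matrices with paired rows,
#'   `n >= 3`, not all collinear.
#' @return A `superposition` list: `rotation` (3x3), `translation`
#'   (length-3), `rmsd` (angstrom), `n_pairs`.
#' @export
kabsch <- function(mobile, reference) {
  m <- matrix(as.numeric(mobile), ncol = 3L)
  r <- matrix(as.numeric(reference), ncol = 3L)
  if (nrow(m) != nrow(r)) stop("mobile and reference must pair row-for-row")
  n <- nrow(m)
  if (n < 3L) stop("insufficient points: superposition needs >= 3 pairs")
  cm <- colMeans(m)
  cr <- colMeans(r)
  mc <- sweep(m, 2L, cm)
  rc <- sweep(r, 2L, cr)
  for (cloud in list(mc, rc)) {
    sv <- svd(cloud)$d
    if (sum(sv > 1e-8 * max(sv, 1e-12)) < 2L) {
      stop("degenerate geometry: points are collinear or coincident")
    }
  }
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- tcrossprod(m, rot) + matrix(trans, n, 3L, byrow = TRUE)
  structure(
    list(rotation = rot, translation = trans,
         rmsd = sqrt(mean(rowSums((fitted - r)^2))), n_pairs = n),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#' @param fit a `superposition` from [kabsch()].
#' @param xyz an `n x 3` coordinate matrix.
#' @return The transformed coordinates.
#' @export
apply_superposition <- function(fit, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  tcrossprod(xyz, fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3L, byrow = TRUE)
}

# Indices of protein atoms at a pairing level.
#' @noRd
level_indices <- function(struct, atom_level) {
  at <- struct$atoms
  switch(atom_level,
    ca = which(at$record == "ATOM" & at$name == "CA"),
    backbone = which(at$record == "ATOM" & at$name %in% c("N", "CA", "C", "O")),
    all = which(at$record == "ATOM"),
    stop("atom_level must be one of 'ca', 'backbone', 'all'")
  )
}

#' Superpose one structure onto another
#'
#' Protein atoms are paired by `(chain, residue number, atom name)` — a same-
#' protein assumption: the family shares numbering, so no sequence alignment
#' is performed, and residue-name mismatches at a paired position (mutants)
#' are tolerated. The fitted rigid motion is applied to all atoms of
#' `mobile`, waters and ligand included.
#'
#' @param mobile,reference `pdb_structure` objects.
#' @param atom_level pairing level: `"ca"` (default), `"backbone"`, `"all"`.
#' @return List with `structure` (transformed copy of `mobile`) and `fit`
#'   (the `superposition`, carrying the pairing count).
#' @export
align_structures <- function(mobile, reference, atom_level = "ca") {
  im <- level_indices(mobile, atom_level)
  ir <- level_indices(reference, atom_level)
  key <- function(st, i) paste(st$atoms$chain[i], st$atoms$resid[i],
                               st$atoms$name[i], sep = "|")
  km <- key(mobile, im)
  kr <- key(reference, ir)
  shared <- intersect(km, kr)
  if (length(shared) < 3L) {
    stop(sprintf(
      "pairing error: only %d atoms pair at level '%s' (unmatched mobile: %s)",
      length(shared), atom_level,
      paste(utils::head(setdiff(km, kr), 5L), collapse = ", ")
    ))
  }
  im <- im[match(shared, km)]
  ir <- ir[match(shared, kr)]
  fit <- kabsch(coords_of(mobile, sel = im), coords_of(reference, sel = ir))
  out <- mobile
  xyz <- apply_superposition(fit, coords_of(mobile))
  out$atoms$x <- xyz[, 1L]
  out$atoms$y <- xyz[, 2L]
  out$atoms$z <- xyz[, 3L]
  list(structure = out, fit = fit)
}

#' Filter a structure family by post-superposition RMSD
#'
#' Each structure is superposed onto `reference` and kept when its fitted
#' RMSD at `atom_level` is at or below `threshold` (default 0.5 angstrom on
#' C-alpha). Structures that cannot be paired are rejected with a reason.
#'
#' @param structures list of `pdb_structure`.
#' @param reference the reference `pdb_structure` (e.g. the apoenzyme).
#' @param threshold acceptance RMSD, angstrom.
#' @param atom_level pairing level for the fit and the reported RMSD.
#' @return List with `accepted` / `rejected` (aligned structures, input order
#'   preserved) and `summary`, a data frame of label, rmsd, accepted, reason.
#' @export
rmsd_filter <- function(structures, reference, threshold = 0.5,
                        atom_level = "ca") {
  stopifnot(threshold > 0)
  labels <- vapply(structures, function(s) s$label, character(1L))
  accepted <- list()
  rejected <- list()
  summary <- data.frame(label = labels, rmsd = NA_real_, accepted = FALSE,
                        reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(structures)) {
    res <- tryCatch(align_structures(structures[[i]], reference, atom_level),
                    error = function(e) e)
    if (inherits(res, "error")) {
      summary$reason[i] <- conditionMessage(res)
      rejected[[length(rejected) + 1L]] <- structures[[i]]
      next
    }
    summary$rmsd[i] <- res$fit$rmsd
    if (res$fit$rmsd <= threshold) {
      summary$accepted[i] <- TRUE
      accepted[[length(accepted) + 1L]] <- res$structure
    } else {
      summary$reason[i] <- sprintf("rmsd %.3f > %.3f", res$fit$rmsd, threshold)
      rejected[[length(rejected) + 1L]] <- res$structure
    }
  }
  list(accepted = accepted, rejected = rejected, summary = summary)
}

#' Per-frame RMSD trace of a trajectory
#'
#' Every frame is rigid-fitted to frame 1 on `fit_selection`; the RMSD is
#' then reported on `report_selection` (default: the fit selection). Both
#' selections are fixed at frame 1, so the series is well defined even for
#' region-based selections.
#'
#' @param traj a `pdb_trajectory`.
#' @param fit_selection atoms used for the superposition.
#' @param report_selection atoms whose deviation is reported after the fit.
#' @return Data frame with `frame`, `time_ps`, `rmsd`.
#' @export
trajectory_rmsd <- function(traj, fit_selection, report_selection = fit_selection) {
  stopifnot(inherits(traj, "pdb_trajectory"))
  if (!length(fit_selection) || !length(report_selection)) {
    stop("empty selection")
  }
  nf <- n_frames(traj)
  ref_fit <- coords_of(traj, 1L, fit_selection)
  ref_rep <- coords_of(traj, 1L, report_selection)
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    fit <- kabsch(coords_of(traj, f, fit_selection), ref_fit)
    moved <- apply_superposition(fit, coords_of(traj, f, report_selection))
    rmsd[f] <- sqrt(mean(rowSums((moved - ref_rep)^2)))
  }
  data.frame(frame = seq_len(nf),
             time_ps = (seq_len(nf) - 1L) * traj$frame_interval,
             rmsd = rmsd)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}
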