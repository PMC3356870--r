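# minimal trajectory fixture: a few fixed ligand atoms plus waters whose
# per-frame oxygen positions are given explicitly
script_traj <- function(water_pos, lig_xyz = rbind(c(0, 0, 0), c(1, 0, 0)),
                        frame_interval = 2) {
  n_wat <- dim(water_pos)[1]
  nf <- dim(water_pos)[3]
  lig_names <- c("C1", "O2", "C3", "O4")[seq_len(nrow(lig_xyz))]
  rows <- list(data.frame(
    name = lig_names, resname = "LIG", chain = "A", resid = 900L,
    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
    element = substr(lig_names, 1, 1), record = "HETATM",
    stringsAsFactors = FALSE))
  for (w in seq_len(n_wat)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "O", resname = "WAT", chain = "W", resid = 500L + w,
      x = water_pos[w, 1, 1], y = water_pos[w, 2, 1], z = water_pos[w, 3, 1],
      element = "O", record = "HETATM", stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$occ <- 1
  at$bfactor <- 0
  at$water <- at$resname == "WAT"
  topo <- hydrosite:::new_structure(
    at[, c("serial", "name", "resname", "chain", "resid", "x", "y", "z",
           "occ", "bfactor", "element", "record", "water")])
  nl <- nrow(lig_xyz)
  coords <- array(NA_real_, c(nl + n_wat, 3, nf))
  coords[seq_len(nl), , ] <- array(lig_xyz, c(nl, 3, nf))
  if (n_wat > 0) coords[nl + seq_len(n_wat), , ] <- water_pos
  hydrosite:::new_trajectory(topo, coords, frame_interval)
}
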