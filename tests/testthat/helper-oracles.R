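# Independent oracles: explicit O(N^2) loops, quaternion search, window
# scans. Deliberately naive so they share no code path with the package.

brute_dist <- function(p, q) sqrt(sum((p - q)^2))

# all (i, j) index pairs with distance <= cutoff, by double loop
brute_pairs_within <- function(xyz_a, xyz_b, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      if (brute_dist(xyz_a[i, ], xyz_b[j, ]) <= cutoff) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# minimum distance from each row of a to any row of b, by double loop
brute_min_dist <- function(xyz_a, xyz_b) {
  vapply(seq_len(nrow(xyz_a)), function(i) {
    m <- Inf
    for (j in seq_len(nrow(xyz_b))) {
      m <- min(m, brute_dist(xyz_a[i, ], xyz_b[j, ]))
    }
    m
  }, numeric(1))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# global minimum RMSD over proper rotations by quaternion random search with
# Nelder-Mead polishing from the best starts (translation optimal at the
# centroid match, so only the rotation is searched)
quat_search_rmsd <- function(mobile, reference, n_start = 400) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    r <- quat_to_rot(q)
    sqrt(mean(rowSums((mc %*% t(r) - rc)^2)))
  }
  starts <- matrix(stats::rnorm(4 * n_start), ncol = 4)
  vals <- apply(starts, 1, obj)
  best <- Inf
  for (k in order(vals)[1:3]) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# longest presence window by exhaustive window scan: a valid window starts
# and ends present and contains no absence gap longer than gap_tolerance
brute_longest_window <- function(bits, gap_tolerance) {
  n <- length(bits)
  best <- 0L
  for (i in seq_len(n)) {
    if (!bits[i]) next
    for (j in i:n) {
      if (!bits[j]) next
      gaps <- rle(as.integer(bits[i:j]))
      zero_runs <- gaps$lengths[gaps$values == 0L]
      if (!length(zero_runs) || max(zero_runs) <= gap_tolerance) {
        best <- max(best, j - i + 1L)
      }
    }
  }
  best
}

# random structure with protein, one ligand and waters for oracle tests
random_structure <- function(n_protein = 30, n_waters = 20, n_ligand = 8,
                             box = 20, label = "RND") {
  if (n_protein < 1) stop("random_structure needs protein atoms")
  prot <- data.frame(
    name = rep(c("N", "CA", "C", "O"), length.out = n_protein),
    resname = "ALA", chain = "A",
    resid = rep(seq_len(ceiling(n_protein / 4)), each = 4)[seq_len(n_protein)],
    x = stats::runif(n_protein, -box, box),
    y = stats::runif(n_protein, -box, box),
    z = stats::runif(n_protein, -box, box),
    occ = 1, bfactor = 0,
    element = rep(c("N", "C", "C", "O"), length.out = n_protein),
    record = "ATOM", water = FALSE, stringsAsFactors = FALSE
  )
  lel <- sample(c("C", "N", "O", "S"), max(n_ligand, 1), replace = TRUE)[seq_len(n_ligand)]
  lig <- if (n_ligand == 0) NULL else data.frame(
    name = paste0(lel, seq_len(n_ligand)), resname = "LIG", chain = "A",
    resid = 900L,
    x = stats::runif(n_ligand, -4, 4), y = stats::runif(n_ligand, -4, 4),
    z = stats::runif(n_ligand, -4, 4),
    occ = 1, bfactor = 0, element = lel, record = "HETATM", water = FALSE,
    stringsAsFactors = FALSE
  )
  wat <- if (n_waters == 0) NULL else data.frame(
    name = "O", resname = "HOH", chain = "W",
    resid = 1000L + seq_len(n_waters),
    x = stats::runif(n_waters, -box, box), y = stats::runif(n_waters, -box, box),
    z = stats::runif(n_waters, -box, box),
    occ = 1, bfactor = 0, element = "O", record = "HETATM", water = TRUE,
    stringsAsFactors = FALSE
  )
  at <- rbind(prot, lig, wat)
  at$serial <- seq_len(nrow(at))
  at <- at[, c("serial", "name", "resname", "chain", "resid", "x", "y", "z",
               "occ", "bfactor", "element", "record", "water")]
  hydrosite:::new_structure(at, label = label)
}

random_rotation_matrix <- function() {
  quat_to_rot(stats::rnorm(4))
}

rigid_move <- function(struct, rot = random_rotation_matrix(),
                       trans = stats::runif(3, -10, 10)) {
  xyz <- coords_of(struct) %*% t(rot)
  xyz <- sweep(xyz, 2, -trans)
  struct$atoms$x <- xyz[, 1]
  struct$atoms$y <- xyz[, 2]
  struct$atoms$z <- xyz[, 3]
  struct
}
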