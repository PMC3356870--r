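# Internal geometry and bookkeeping helpers shared across modules.

# Heavy-atom elements treated as hydrogen-bond capable (donor or acceptor).
POLAR_ELEMENTS <- c("N", "O", "F", "S")

# Residue names recognised as water, upper-cased. TIP3 covers CHARMM-style
# solvent naming in multi-model trajectory files.
DEFAULT_WATER_NAMES <- c("HOH", "WAT", "TIP3")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance matrix between two n x 3 / m x 3 coordinate matrices.
# Cross-product form; clipped at zero against floating-point negatives.
#' @noRd
dist_xyz <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Minimum distance from each row of `a` to any row of `b`.
#' @noRd
min_dist_to <- function(a, b) {
  if (nrow(matrix(a, ncol = 3L)) == 0L || NROW(b) == 0L) {
    return(numeric(0))
  }
  d <- dist_xyz(a, b)
  apply(d, 1L, min)
}

# Human-readable atom references, in the field's RES@NAME / RESID@NAME style:
# waters keep their author-assigned residue number ("HOH1147@O"); other
# residues are referenced by residue name alone ("FID@C9").
#' @noRd
atom_ref <- function(resname, resid, name, water) {
  ifelse(water,
    paste0(resname, resid, "@", name),
    paste0(resname, "@", name)
  )
}

# Element inference for files lacking columns 77-78: strip digits, take the
# first alphabetic character (covers CA, O2', 1HB-style hydrogen names).
#' @noRd
infer_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  toupper(substr(stripped, 1L, 1L))
}

# Key identifying a residue within a structure.
#' @noRd
residue_key <- function(atoms, idx = seq_len(nrow(atoms))) {
  paste(atoms$chain[idx], atoms$resid[idx], atoms$resname[idx], sep = "|")
}

# Evaluate code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. Keeps generator determinism self-contained.
#' @noRd
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, sign-fixed).
#' @noRd
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
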