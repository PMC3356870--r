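test_that("a HETATM record is transcribed field by field", {
  line <- "HETATM 2275  O   HOH A2275       1.000   2.000   3.000  1.00 20.00           O"
  traj <- parse_pdb(line)
  at <- traj$topology$atoms
  expect_equal(nrow(at), 1L)
  expect_equal(at$serial, 2275L)
  expect_equal(at$name, "O")
  expect_equal(at$resname, "HOH")
  expect_equal(at$resid, 2275L)
  expect_true(at$water)
  expect_equal(unname(coords_of(traj)[1, ]), c(1, 2, 3))
})

test_that("MODEL blocks become frames and frame differences are preserved", {
  st <- random_structure(n_protein = 8, n_waters = 2, n_ligand = 2)
  traj1 <- as_trajectory(st)
  shifted <- st
  shifted$atoms$x <- shifted$atoms$x + 1
  coords <- array(c(coords_of(st), coords_of(shifted)),
                  c(nrow(st$atoms), 3, 2))
  traj <- hydrosite:::new_trajectory(st, coords)
  back <- parse_pdb(write_pdb(traj))
  expect_equal(n_frames(back), 2L)
  diff <- coords_of(back, 2) - coords_of(back, 1)
  expect_equal(unname(diff), matrix(rep(c(1, 0, 0), each = nrow(st$atoms)),
                                    ncol = 3), tolerance = 1e-9)
  expect_equal(n_frames(parse_pdb(write_pdb(traj1))), 1L)
  expect_equal(length(grep("^MODEL", strsplit(write_pdb(traj), "\n")[[1]])), 2L)
  expect_equal(length(grep("^MODEL", strsplit(write_pdb(traj1), "\n")[[1]])), 0L)
})

test_that("parse-write-parse is the identity on stored fields", {
  set.seed(101)
  for (rep in 1:5) {
    st <- random_structure(n_protein = sample(8:40, 1),
                           n_waters = sample(0:10, 1))
    p1 <- parse_pdb(write_pdb(st))
    p2 <- parse_pdb(write_pdb(p1))
    cols <- c("serial", "name", "resname", "chain", "resid", "element",
              "record", "water")
    expect_identical(p2$topology$atoms[, cols], p1$topology$atoms[, cols])
    expect_lt(max(abs(p2$coords - p1$coords)), 1e-3)
    expect_lt(max(abs(coords_of(p1) - coords_of(st))), 1e-3)
  }
})

test_that("parse errors carry diagnostics", {
  expect_error(parse_pdb("REMARK nothing here"), "empty")
  bad <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   x.000   3.000  1.00  0.00           C"
  )
  expect_error(parse_pdb(bad), "line 2")
  incons <- c("MODEL     1",
              "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
              "ATOM      2  CB  ALA A   1       2.000   2.000   3.000",
              "ENDMDL", "MODEL     2",
              "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
              "ENDMDL")
  expect_error(parse_pdb(incons), "inconsistent")
  far <- random_structure(n_protein = 4, n_waters = 0, n_ligand = 2)
  far$atoms$x[1] <- 12000
  expect_error(write_pdb(far), "10\\^4|1e4|formatted")
})

test_that("selections follow record, name and water conventions", {
  set.seed(7)
  st <- random_structure(n_protein = 24, n_waters = 6, n_ligand = 5)
  prot <- select_atoms(st, "protein")
  wat <- select_atoms(st, "water")
  lig <- select_atoms(st, "ligand", resname = "LIG")
  expect_length(intersect(prot, wat), 0)
  expect_length(intersect(prot, lig), 0)
  expect_length(intersect(wat, lig), 0)
  expect_setequal(select_atoms(st, "ca"),
                  which(st$atoms$name == "CA" & st$atoms$record == "ATOM"))
  expect_true(all(st$atoms$name[select_atoms(st, "backbone")] %in%
                    c("N", "CA", "C", "O")))
  expect_error(select_atoms(st, "ligand", resname = "XXX"), "empty selection")
})

test_that("within() keeps whole residues and matches a brute-force filter", {
  # one water at a known 4.0 A from a ligand atom
  at <- data.frame(
    serial = 1:3, name = c("C1", "O1", "O"), resname = c("LIG", "LIG", "HOH"),
    chain = c("A", "A", "W"), resid = c(900L, 900L, 1L),
    x = c(0, 1, 5), y = 0, z = 0, occ = 1, bfactor = 0,
    element = c("C", "O", "O"), record = c("HETATM", "HETATM", "HETATM"),
    water = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  st <- hydrosite:::new_structure(at)
  lig <- select_atoms(st, "ligand", resname = "LIG")
  expect_true(3L %in% select_atoms(st, "within", radius = 5, of = lig))
  expect_false(3L %in% select_atoms(st, "within", radius = 3, of = lig))

  set.seed(11)
  for (r in c(3.4, 5.0)) {
    big <- random_structure(n_protein = 120, n_waters = 50, n_ligand = 10)
    base <- select_atoms(big, "ligand", resname = "LIG")
    got <- select_atoms(big, "within", radius = r, of = base)
    md <- brute_min_dist(coords_of(big), coords_of(big, sel = base))
    hit_res <- unique(hydrosite:::residue_key(big$atoms, which(md <= r)))
    want <- which(hydrosite:::residue_key(big$atoms) %in% hit_res)
    expect_setequal(as.integer(got), want)
  }
})

test_that("within() is monotone in the radius", {
  set.seed(3)
  st <- random_structure(n_protein = 60, n_waters = 25)
  lig <- select_atoms(st, "ligand", resname = "LIG")
  radii <- c(2, 3.4, 5, 8)
  sels <- lapply(radii, function(r) select_atoms(st, "within", radius = r, of = lig))
  for (k in 2:length(radii)) {
    expect_true(all(sels[[k - 1]] %in% sels[[k]]))
  }
})

test_that("parsing agrees with an independent PDB reader on shared fields", {
  skip_if_not_installed("bio3d")
  set.seed(23)
  st <- random_structure(n_protein = 20, n_waters = 5, n_ligand = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, path)
  ours <- frame_structure(read_pdb(path))
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(nrow(ref$atom), nrow(ours$atoms))
  expect_equal(ref$atom$elety, ours$atoms$name)
  expect_equal(ref$atom$resno, ours$atoms$resid)
  expect_equal(ref$atom$x, ours$atoms$x, tolerance = 1e-6)
  expect_equal(ref$atom$y, ours$atoms$y, tolerance = 1e-6)
  expect_equal(ref$atom$z, ours$atoms$z, tolerance = 1e-6)
})
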