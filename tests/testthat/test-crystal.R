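# small hand-built complex: ligand with polar and carbon atoms, protein
# backbone oxygen, waters at controlled distances
make_complex <- function(water_pos, extra_waters = NULL) {
  rows <- list(
    data.frame(name = c("N", "CA", "C", "O"), resname = "GLY", chain = "A",
               resid = 1L, x = c(8, 7, 6, 5), y = c(0, 1, 0, 0), z = 0,
               element = c("N", "C", "C", "O"), record = "ATOM",
               stringsAsFactors = FALSE),
    data.frame(name = c("C1", "N2", "O3"), resname = "FID", chain = "A",
               resid = 900L, x = c(0, 1.2, -1.2), y = 0, z = 0,
               element = c("C", "N", "O"), record = "HETATM",
               stringsAsFactors = FALSE)
  )
  wat <- rbind(water_pos, extra_waters)
  for (k in seq_len(nrow(wat))) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "O", resname = "HOH", chain = "W", resid = 2000L + k,
      x = wat[k, 1], y = wat[k, 2], z = wat[k, 3],
      element = "O", record = "HETATM", stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$occ <- 1
  at$bfactor <- 0
  at$water <- at$resname == "HOH"
  hydrosite:::new_structure(
    at[, c("serial", "name", "resname", "chain", "resid", "x", "y", "z",
           "occ", "bfactor", "element", "record", "water")],
    label = "CPLX")
}

test_that("crystal hydrogen bonds use the polar-heavy-atom distance criterion", {
  st <- make_complex(matrix(c(1.2, 2.8, 0), 1))   # water O 2.8 A from ligand N2
  lig <- select_atoms(st, "ligand", resname = "FID")
  wat <- select_atoms(st, "water")
  hb <- detect_hbonds_crystal(st, lig, wat, cutoff = 3.0)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$atom_a, "FID@N2")
  expect_equal(hb$atom_b, "HOH2001@O")
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)

  st2 <- make_complex(matrix(c(0, 2.8, 0), 1))    # 2.8 A from carbon C1 only
  hb2 <- detect_hbonds_crystal(st2, select_atoms(st2, "ligand", resname = "FID"),
                               select_atoms(st2, "water"), cutoff = 3.0)
  expect_equal(nrow(hb2), 0L)
  expect_error(detect_hbonds_crystal(st, lig, lig), "disjoint")
})

test_that("crystal hydrogen bonds equal the brute-force all-pairs filter", {
  set.seed(31)
  for (rep in 1:5) {
    st <- random_structure(n_protein = 100, n_waters = 40, n_ligand = 10)
    lig <- select_atoms(st, "ligand", resname = "LIG")
    wat <- select_atoms(st, "water")
    hb <- detect_hbonds_crystal(st, lig, wat, cutoff = 3.0)
    polar <- which(st$atoms$element %in% c("N", "O", "F", "S"))
    ia <- intersect(as.integer(lig), polar)
    ib <- intersect(as.integer(wat), polar)
    want <- brute_pairs_within(coords_of(st, sel = ia), coords_of(st, sel = ib), 3.0)
    expect_equal(nrow(hb), NROW(want))
    if (NROW(want)) {
      expect_setequal(paste(hb$idx_a, hb$idx_b),
                      paste(ia[want[, 1]], ib[want[, 2]]))
    }
  }
})

test_that("active-site waters respect the 5 A boundary and the brute force", {
  near <- matrix(c(0, 4.9, 0), 1)
  far <- matrix(c(0, 5.1, 0), 1)
  st <- make_complex(near, far)
  lig <- select_atoms(st, "ligand", resname = "FID")
  asw <- find_active_site_waters(st, lig, radius = 5)
  expect_equal(asw$resid, 2001L)
  st0 <- make_complex(matrix(numeric(0), 0, 3))
  expect_equal(nrow(find_active_site_waters(st0, select_atoms(st0, "ligand", resname = "FID"))), 0L)

  set.seed(32)
  st <- random_structure(n_protein = 60, n_waters = 50)
  lig <- select_atoms(st, "ligand", resname = "LIG")
  got <- find_active_site_waters(st, lig, radius = 5)
  wo <- which(st$atoms$water & st$atoms$element == "O")
  md <- brute_min_dist(coords_of(st, sel = wo), coords_of(st, sel = lig))
  expect_setequal(got$resid, st$atoms$resid[wo][md <= 5])
})

test_that("bridging needs simultaneous ligand and protein contacts", {
  # water 1.9 A from ligand N2 (1.2,0,0) and 1.9 A from backbone O (5,0,0)
  w <- c(3.1, 0, 0)
  expect_lt(brute_dist(w, c(1.2, 0, 0)), 3)
  expect_lt(brute_dist(w, c(5, 0, 0)), 3)
  st <- make_complex(matrix(w, 1))
  lig <- select_atoms(st, "ligand", resname = "FID")
  br <- classify_bridging(st, lig, cutoff = 3.0)
  expect_equal(br$water_id, "HOH2001")
  expect_equal(br$n_ligand_contacts, 1L)
  expect_equal(br$n_protein_contacts, 1L)

  only_lig <- make_complex(matrix(c(1.2, 2.7, 0), 1))
  expect_equal(nrow(classify_bridging(only_lig,
                                      select_atoms(only_lig, "ligand", resname = "FID"))), 0L)
})

test_that("a two-water bridge is found only when chaining is enabled", {
  # water A hydrogen-bonds ligand N2 and O3 (two ligand contacts) and
  # water B; water B alone reaches the protein backbone O
  wa <- c(0, 2.4, 0)
  expect_lt(brute_dist(wa, c(1.2, 0, 0)), 3)
  expect_lt(brute_dist(wa, c(-1.2, 0, 0)), 3)
  expect_gt(brute_dist(wa, c(5, 0, 0)), 3)
  wb <- c(2.55, 1.2, 0)
  expect_lt(brute_dist(wa, wb), 3)
  expect_lt(brute_dist(wb, c(5, 0, 0)), 3)
  st <- make_complex(matrix(wa, 1), matrix(wb, 1))
  lig <- select_atoms(st, "ligand", resname = "FID")
  direct <- classify_bridging(st, lig, cutoff = 3.0)
  expect_false("HOH2001" %in% direct$water_id)
  chained <- classify_bridging(st, lig, cutoff = 3.0, chain_waters = TRUE)
  a_row <- chained[chained$water_id == "HOH2001", ]
  expect_equal(nrow(a_row), 1L)
  expect_equal(a_row$n_ligand_contacts, 2L)
  expect_true(a_row$chained)
})

test_that("conserved-water clustering recovers planted sites", {
  base <- make_complex(matrix(c(1.2, 2.8, 0), 1))
  structures <- lapply(1:5, function(i) { b <- base; b$label <- paste0("S", i); b })
  cl <- cluster_conserved_waters(structures)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$multiplicity, 5L)
  expect_equal(cl[[1]]$centroid, c(1.2, 2.8, 0), tolerance = 1e-9)

  # two sites 5 A apart, both in every structure: never merged
  two <- lapply(1:5, function(i) {
    b <- make_complex(matrix(c(1.2, 2.8, 0, 1.2, 7.8, 0), 2, byrow = TRUE))
    b$label <- paste0("S", i)
    b
  })
  cl2 <- cluster_conserved_waters(two, match_radius = 1.2)
  expect_length(cl2, 2L)
  expect_equal(vapply(cl2, function(x) x$multiplicity, integer(1)), c(5L, 5L))
  total <- sum(vapply(cl2, function(x) x$multiplicity, integer(1)))
  ids <- do.call(rbind, lapply(cl2, function(x) x$members))
  expect_equal(total, nrow(ids))
  expect_false(any(duplicated(ids[, c("label", "resid")])))
})

test_that("jittered planted site keeps its multiplicity", {
  set.seed(33)
  structures <- lapply(1:5, function(i) {
    pos <- c(1.2, 2.8, 0) + if (i <= 4) stats::rnorm(3, 0, 0.3) else c(0, 9, 0)
    b <- make_complex(matrix(pos, 1))
    b$label <- paste0("S", i)
    b
  })
  cl <- cluster_conserved_waters(structures, match_radius = 1.5)
  expect_equal(cl[[1]]$multiplicity, 4L)
})

test_that("displaced-water counting matches construction and brute force", {
  fam9 <- make_crystal_family(crystal_family_spec(n_displaced = 9, seed = 1))
  filt <- rmsd_filter(fam9$structures, fam9$apo)
  dw <- displaced_waters(fam9$apo, filt$accepted[[1]], "LIG")
  expect_equal(dw$count, 9L)

  fam6 <- make_crystal_family(crystal_family_spec(n_displaced = 6, seed = 1))
  filt6 <- rmsd_filter(fam6$structures, fam6$apo)
  expect_equal(displaced_waters(fam6$apo, filt6$accepted[[1]], "LIG")$count, 6L)

  expect_error(displaced_waters(fam9$apo, fam9$apo, "LIG"), "empty selection")

  # monotone in the overlap radius
  counts <- vapply(c(0.5, 1.4, 3), function(r) {
    displaced_waters(fam9$apo, filt$accepted[[1]], "LIG", overlap_radius = r)$count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))

  set.seed(34)
  apo <- random_structure(n_protein = 40, n_waters = 30, n_ligand = 0)
  holo <- random_structure(n_protein = 40, n_waters = 0, n_ligand = 8)
  got <- displaced_waters(apo, holo, "LIG", overlap_radius = 1.4)
  wo <- which(apo$atoms$water & apo$atoms$element == "O")
  lig <- select_atoms(holo, "ligand", resname = "LIG")
  md <- brute_min_dist(coords_of(apo, sel = wo), coords_of(holo, sel = lig))
  expect_equal(got$count, sum(md <= 1.4))
})

test_that("bridging waters are a subset of active-site waters", {
  set.seed(35)
  for (rep in 1:5) {
    st <- random_structure(n_protein = 80, n_waters = 40)
    lig <- select_atoms(st, "ligand", resname = "LIG")
    br <- classify_bridging(st, lig, cutoff = 3.0)
    asw <- find_active_site_waters(st, lig, radius = 5.0)
    expect_true(all(br$resid %in% asw$resid))
  }
})

test_that("the family contact table reproduces planted contacts", {
  fam <- make_crystal_family(crystal_family_spec(seed = 9))
  rep <- crystal_report(fam$structures, fam$apo, "LIG")
  truth <- fam$ground_truth$contacts
  planted <- paste(truth$label, truth$ligand_atom, paste0("HOH", truth$water_resid))
  got <- paste(rep$pdb_id, rep$ligand_atom, rep$water_id)
  got <- sub("@O$", "", got)
  expect_setequal(got, planted)
  expect_true(all(rep$bridging))
  expect_true(all(abs(rep$distance_A - 2.8) < 1e-6))
  expect_false(is.unsorted(rep$pdb_id))
})

test_that("a ligand with no nearby water yields no contact rows", {
  st <- make_complex(matrix(c(0, 12, 0), 1))
  st$label <- "DRY1"
  rep <- crystal_report(list(st), st, "FID")
  expect_equal(nrow(rep), 0L)
})
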