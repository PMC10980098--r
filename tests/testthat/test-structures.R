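test_that("fixture complexes round-trip through PDB text", {
  for (mode in c("docked", "separated", "clashing")) {
    cx <- make_toy_complex(mode = mode, seed = 7)
    txt <- write_pdb(cx)
    back <- parse_pdb(txt, "A", "B")
    expect_equal(nrow(back$atoms), nrow(cx$atoms))
    expect_equal(back$atoms$elety, cx$atoms$elety)
    expect_equal(back$atoms$resid, cx$atoms$resid)
    expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
                 round(as.matrix(cx$atoms[, c("x", "y", "z")]), 3),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("coordinates are serialized to the fixed 3-decimal PDB field", {
  cx <- make_toy_complex(seed = 1)
  cx$atoms$x[1] <- 1.23456
  txt <- write_pdb(cx)
  expect_match(strsplit(txt, "\n")[[1]][1], "   1\\.235")
})

test_that("parsing rejects missing chains and malformed ATOM records", {
  cx <- make_toy_complex(seed = 2)
  lines <- strsplit(write_pdb(cx), "\n")[[1]]
  only_a <- paste(lines[startsWith(lines, "ATOM") &
                          substr(lines, 22, 22) == "A"], collapse = "\n")
  expect_error(parse_pdb(only_a, "A", "B"), "chain 'B'",
               class = "pepforge_missing_chain")
  bad <- "ATOM      1  CA  ALA A   1      xx.xxx   6.134  -6.504  1.00  0.00           C"
  expect_error(parse_pdb(bad, "A", "B"), "line 1",
               class = "pepforge_parse_error")
})

test_that("parser drops heteroatoms/waters/hydrogens and resolves altlocs by occupancy", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  HB  ALA A   1       3.000   0.000   0.000  1.00  0.00           H",
    "ATOM      5  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  TRP B   1       0.000   4.000   0.000  1.00  0.00           C",
    "HETATM    8  O   HOH B  99       0.000   0.000   9.000  1.00  0.00           O",
    "END", sep = "\n")
  cx <- parse_pdb(txt, "A", "B")
  a1 <- residues(cx, "protein")[[1]]
  expect_equal(nrow(a1), 2)             # CA + one CB; hydrogen dropped
  expect_equal(a1$x[a1$elety == "CB"], 1.0)  # higher-occupancy altloc kept
  expect_false(any(cx$atoms$resid == "HOH"))
  # radii assigned by element from the table
  expect_equal(unique(cx$atoms$radius[cx$atoms$elesy == "C"]), 1.70)
})

test_that("altloc occupancy ties keep the first record encountered", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  GLY B   1       0.000   4.000   0.000  1.00  0.00           C",
    sep = "\n")
  cx <- parse_pdb(txt, "A", "B")
  expect_equal(residues(cx, "protein")[[1]]$x, 0.0)
})

test_that("write_pdb rejects residue numbers beyond the PDB field and empty chains", {
  cx <- make_toy_complex(seed = 3)
  cx$atoms$resno[cx$atoms$role == "peptide"] <-
    cx$atoms$resno[cx$atoms$role == "peptide"] + 10000L
  expect_error(write_pdb(cx), class = "pepforge_write_error")
  cx2 <- make_toy_complex(seed = 3)
  cx2$atoms <- cx2$atoms[cx2$atoms$role == "protein", ]
  expect_error(write_pdb(cx2), class = "pepforge_bad_complex")
})

test_that("min_residue_distance matches hand geometry and brute force", {
  mk <- function(xyz) data.frame(role = "protein", chain = "A", resno = 1,
                                 ins = "", resid = "ALA", elety = "CA",
                                 elesy = "C", x = xyz[, 1], y = xyz[, 2],
                                 z = xyz[, 3], radius = 1.7)
  a <- mk(matrix(c(0, 0, 0), 1))
  b <- mk(matrix(c(3, 4, 0), 1))
  expect_equal(min_residue_distance(a, b), 5.0)
  expect_equal(min_residue_distance(a, a), 0.0)
  set.seed(11)
  for (rep in 1:10) {
    r1 <- mk(matrix(rnorm(9), 3))
    r2 <- mk(matrix(rnorm(9, 2), 3))
    expect_equal(min_residue_distance(r1, r2), brute_min_dist(r1, r2))
    expect_equal(min_residue_distance(r1, r2), min_residue_distance(r2, r1))
  }
})

test_that("residue distance is rigid-motion invariant and metric on single atoms", {
  cx <- make_toy_complex(seed = 5)
  pr <- residues(cx, "protein"); pe <- residues(cx, "peptide")
  d0 <- min_residue_distance(pr[[1]], pe[[1]])
  R <- random_rotation(99)
  cx2 <- pepforge:::transform_complex(cx, R, c(5, -3, 12))
  pr2 <- residues(cx2, "protein"); pe2 <- residues(cx2, "peptide")
  expect_equal(min_residue_distance(pr2[[1]], pe2[[1]]), d0, tolerance = 1e-9)
  # triangle inequality on single-atom residues
  mk1 <- function(p) data.frame(role = "protein", chain = "A", resno = 1,
                                ins = "", resid = "GLY", elety = "CA",
                                elesy = "C", x = p[1], y = p[2], z = p[3],
                                radius = 1.7)
  set.seed(4)
  for (rep in 1:20) {
    A <- mk1(rnorm(3)); B <- mk1(rnorm(3)); C <- mk1(rnorm(3))
    expect_lte(min_residue_distance(A, C),
               min_residue_distance(A, B) + min_residue_distance(B, C) + 1e-12)
  }
})
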