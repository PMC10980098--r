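test_that("sphere point lattice is deterministic, unit-norm and near-uniform", {
  expect_error(sphere_points(11), class = "pepforge_bad_npoints")
  sp <- sphere_points(100)
  expect_equal(nrow(sp), 100)
  expect_equal(sqrt(rowSums(sp^2)), rep(1, 100), tolerance = 1e-9)
  expect_identical(sphere_points(960), sphere_points(960))
  expect_lt(sqrt(sum(colMeans(sphere_points(960))^2)), 1e-2)
})

test_that("isolated and non-interacting atoms reproduce the analytic sphere area", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
  analytic <- 4 * pi * 3.1^2
  expect_equal(shrake_rupley(one)$total_area, analytic,
               tolerance = 0.015)
  two_far <- data.frame(x = c(0, 100), y = 0, z = 0, radius = 1.7)
  expect_equal(shrake_rupley(two_far)$total_area, 2 * analytic,
               tolerance = 0.015)
})

test_that("overlapping equal spheres match the closed-form spherical-cap area", {
  for (d in c(2.0, 3.0, 4.0, 5.0)) {
    atoms <- data.frame(x = c(0, d), y = 0, z = 0, radius = 1.7)
    expect_equal(shrake_rupley(atoms)$total_area,
                 two_sphere_area(3.1, d), tolerance = 0.02)
  }
})

test_that("per-atom area converges to the analytic value with lattice size", {
  atoms <- data.frame(x = c(0, 3.0), y = 0, z = 0, radius = 1.7)
  res <- shrake_rupley(atoms, n_points = 4000)
  expect_equal(res$total_area, two_sphere_area(3.1, 3.0), tolerance = 0.005)
})

test_that("adding an atom never increases any other atom's exposed area", {
  set.seed(21)
  atoms <- data.frame(x = rnorm(8, sd = 2), y = rnorm(8, sd = 2),
                      z = rnorm(8, sd = 2), radius = runif(8, 1.2, 1.9))
  base <- shrake_rupley(atoms)$per_atom_area
  more <- rbind(atoms, data.frame(x = 0.5, y = 0.2, z = -0.1, radius = 1.7))
  grown <- shrake_rupley(more)$per_atom_area[1:8]
  expect_true(all(grown <= base + 1e-9))
})

test_that("total SASA is rigid-motion invariant up to lattice orientation", {
  cx <- make_toy_complex(seed = 9)
  t1 <- shrake_rupley(cx)$total_area
  cx2 <- pepforge:::transform_complex(cx, random_rotation(3), c(10, 0, -4))
  t2 <- shrake_rupley(cx2)$total_area
  expect_lt(abs(t1 - t2) / t1, 0.005)
})

test_that("buried interface area behaves by construction on the decoys", {
  sep <- make_toy_complex(mode = "separated", seed = 4)
  expect_equal(as.numeric(interface_buried_sasa(sep)), 0.0)
  docked <- make_toy_complex(mode = "docked", seed = 4)
  expect_gt(interface_buried_sasa(docked), 0)
})

test_that("two-atom interface matches the spherical-cap burial", {
  atoms <- data.frame(
    role = c("protein", "peptide"), chain = c("A", "B"), resno = 1, ins = "",
    resid = "ALA", elety = "CB", elesy = "C",
    x = c(0, 3.0), y = 0, z = 0, radius = 1.7, stringsAsFactors = FALSE)
  cx <- pepforge:::new_complex_structure(atoms, "A", "B", "two-atom")
  buried <- interface_buried_sasa(cx)
  analytic_buried <- 2 * 4 * pi * 3.1^2 - two_sphere_area(3.1, 3.0)
  expect_equal(as.numeric(buried), analytic_buried, tolerance = 0.02)
})

test_that("buried interface area is symmetric in chain roles", {
  cx <- make_toy_complex(seed = 13)
  sw <- cx
  sw$atoms$role <- ifelse(cx$atoms$role == "protein", "peptide", "protein")
  sw$atoms <- sw$atoms[order(match(sw$atoms$role, c("protein", "peptide"))), ]
  sw$protein_chain <- "B"; sw$peptide_chain <- "A"
  expect_equal(as.numeric(interface_buried_sasa(cx)),
               as.numeric(interface_buried_sasa(sw)), tolerance = 1e-9)
})

test_that("totals agree with an independent reference SASA implementation", {
  cx <- make_toy_complex(n_protein = 14, n_peptide = 6, seed = 20)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(cx, file = pdb)
  parsed <- parse_pdb(pdb, "A", "B")   # table radii on both sides of the check
  mine <- shrake_rupley(parsed)$total_area
  ref <- biopython_sasa(pdb)
  expect_false(is.na(ref))
  expect_lt(abs(mine - ref) / ref, 0.02)
})
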