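test_that("contact pairs match the brute-force scan on random toy complexes", {
  set.seed(31)
  for (rep in 1:12) {
    cx <- make_toy_complex(
      n_protein = sample(3:8, 1), n_peptide = sample(3:6, 1),
      interface_gap = runif(1, 2.0, 7.0),
      mode = sample(c("docked", "separated", "clashing"), 1),
      seed = rep)
    got <- binding_pairs(cx)$pairs
    want <- brute_binding_pairs(cx)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(as.matrix(got[, 1:2]), want, ignore_attr = TRUE)
    }
    # ratios and counts are consistent with the pair set
    for (side in c("protein", "peptide")) {
      col <- if (side == "protein") 1 else 2
      n_contact <- if (is.null(want)) 0 else length(unique(want[, col]))
      expect_equal(binding_site_count(cx, side), n_contact)
      expect_equal(binding_ratio(cx, side),
                   n_contact / length(residues(cx, side)))
    }
  }
})

test_that("the contact cutoff is a strict inequality", {
  atoms <- data.frame(
    role = c("protein", "peptide", "peptide"),
    chain = c("A", "B", "B"), resno = c(1, 1, 2), ins = "", resid = "GLY",
    elety = "CA", elesy = "C",
    x = c(0, 4.9, 5.1), y = 0, z = 0, radius = 1.7, stringsAsFactors = FALSE)
  cx <- pepforge:::new_complex_structure(atoms, "A", "B", "boundary")
  bp <- binding_pairs(cx, cutoff = 5.0)
  expect_equal(nrow(bp$pairs), 1)
  expect_equal(bp$pairs$peptide_resno, 1)
  exact <- atoms; exact$x[2] <- 5.0
  cx2 <- pepforge:::new_complex_structure(exact, "A", "B", "tie")
  expect_equal(nrow(binding_pairs(cx2, cutoff = 5.0)$pairs), 0)
})

test_that("separated chains yield no contacts and zero ratios", {
  cx <- make_toy_complex(mode = "separated", seed = 2)
  expect_equal(nrow(binding_pairs(cx)$pairs), 0)
  expect_equal(binding_ratio(cx, "protein"), 0)
  expect_equal(binding_ratio(cx, "peptide"), 0)
})

test_that("contact sets are monotone in the cutoff and rigid-motion invariant", {
  cx <- make_toy_complex(seed = 17)
  key <- function(bp) paste(bp$pairs$protein_resno, bp$pairs$peptide_resno)
  cuts <- c(3, 4, 5, 6, 8)
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(key(binding_pairs(cx, cuts[i - 1])) %in%
                      key(binding_pairs(cx, cuts[i]))))
  }
  moved <- pepforge:::transform_complex(cx, random_rotation(8), c(-2, 7, 1))
  expect_equal(key(binding_pairs(moved)), key(binding_pairs(cx)))
})

test_that("binding ratio counts unique residues over chain length", {
  # 10-residue protein with exactly two residues near the peptide
  prot <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(role = "protein", chain = "A", resno = i, ins = "",
               resid = "GLY", elety = "CA", elesy = "C",
               x = 10 * i, y = 0, z = 0, radius = 1.7)
  }))
  pep <- do.call(rbind, lapply(1:3, function(j) {
    data.frame(role = "peptide", chain = "B", resno = j, ins = "",
               resid = "GLY", elety = "CA", elesy = "C",
               x = 10 + 5 * (j - 1), y = 3, z = 0, radius = 1.7)
  }))
  cx <- pepforge:::new_complex_structure(rbind(prot, pep), "A", "B", "counting")
  expect_equal(binding_site_count(cx, "protein"), 2)
  expect_equal(binding_ratio(cx, "protein"), 0.2)
})
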