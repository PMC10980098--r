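test_that("kabsch recovers exact superpositions and validates input", {
  set.seed(71)
  P <- matrix(rnorm(18), 6, 3)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), class = "pepforge_bad_superposition")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), class = "pepforge_degenerate_points")

  sup_id <- kabsch(P, P)
  expect_equal(sup_id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup_id$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sup_id$rmsd, 0, tolerance = 1e-9)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 degrees about z
  Q <- P %*% t(Rz) + matrix(c(3, -1, 2), 6, 3, byrow = TRUE)
  sup <- kabsch(P, Q)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_equal(sup$rotation, Rz, tolerance = 1e-6)
})

test_that("kabsch rmsd is a lower bound over explicitly sampled rotations", {
  set.seed(72)
  P <- matrix(rnorm(18), 6, 3)
  Q <- matrix(rnorm(18), 6, 3)
  sup <- kabsch(P, Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sampled <- vapply(1:500, function(i) {
    R <- random_rotation(i)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }, numeric(1))
  expect_lte(sup$rmsd, min(sampled) + 1e-12)
})

test_that("TM-score is 1 for identical and rigidly moved structures", {
  cx <- make_toy_complex(seed = 14)
  expect_equal(tm_score(cx, cx), 1.0)
  moved <- pepforge:::transform_complex(cx, random_rotation(2), c(8, -2, 5))
  expect_equal(tm_score(moved, cx), 1.0, tolerance = 1e-6)
  # peptide-only alignment needs a non-collinear peptide C-alpha trace
  set.seed(75)
  glob <- make_ca_complex(matrix(rnorm(36, sd = 5), 12, 3), n_protein = 6)
  glob_moved <- pepforge:::transform_complex(glob, random_rotation(4),
                                             c(3, 3, -7))
  expect_equal(tm_score(glob_moved, glob, align_on = "peptide"), 1.0,
               tolerance = 1e-6)
  # invariance under rigid motion of either argument
  cand <- predict_structure(template_provider(cx),
                            chartr("ACDEF", "GGGGG", chain_sequence(cx, "peptide")))
  t0 <- tm_score(cand, cx)
  expect_equal(tm_score(pepforge:::transform_complex(cand, random_rotation(6),
                                                     c(1, 1, 1)), cx),
               t0, tolerance = 1e-6)
  expect_error(tm_score(make_toy_complex(n_peptide = 4, seed = 1), cx),
               class = "pepforge_length_mismatch")
})

test_that("a uniform displacement of d0 forces a TM-score of exactly one half", {
  set.seed(73)
  A <- matrix(rnorm(45, sd = 4), 15, 3)
  A <- sweep(A, 2, colMeans(A))       # centred base set
  P <- rbind(A, -A)                   # 30 points, centred and balanced
  L <- 30
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  eps <- c(rep(1, 15), rep(-1, 15))
  Q <- P + d0 * cbind(0, 0, eps)
  native <- make_ca_complex(Q, n_protein = 24)
  cand <- make_ca_complex(P, n_protein = 24)
  # by construction the optimal superposition is the identity, so every
  # residue sits exactly d0 from its partner
  expect_equal(tm_score(cand, native), 0.5, tolerance = 1e-9)
})

test_that("short-chain normalisation floors d0 at half an Angstrom", {
  expect_equal(pepforge:::tm_d0(6), 0.5)
  expect_equal(pepforge:::tm_d0(21), 0.5)
  expect_equal(pepforge:::tm_d0(30), 1.24 * 15^(1 / 3) - 1.8)
})

test_that("recovery reports count binding-site matches correctly", {
  lp <- make_recovery_landscape()
  nat <- attr(lp, "native_complex")
  native_seq <- attr(lp, "native_peptide")
  fake_archive <- function(seqs) {
    structures <- lapply(seqs, predict_structure, provider = lp)
    names(structures) <- seqs
    obj <- t(vapply(structures, function(st)
      c(interface_buried_sasa(st), contact_energy(st)), numeric(2)))
    cand <- data.frame(sequence = seqs, round = 0L, parent = native_seq,
                       status = "ok", interface_sasa = obj[, 1],
                       energy = obj[, 2], c1 = obj[, 1], c2 = -obj[, 2])
    structure(list(candidates = cand, structures = structures,
                   summary = data.frame(round = 0),
                   config = bo_config(), native_peptide = native_seq),
              class = "pep_archive")
  }
  # archive of just the native: 100% match, TM-score 1
  rep1 <- recovery_report(fake_archive(native_seq), nat)
  expect_equal(rep1$match_rate_pct, 100)
  expect_equal(rep1$best_tm_score, 1.0)
  expect_true(rep1$native_recovered)
  # 4 candidates, exactly one matching the native count
  seqs <- c(native_seq, "GGGWWW", "GGGGWW", "GGGGGW")
  rep2 <- recovery_report(fake_archive(seqs), nat)
  expect_equal(rep2$native_count, nchar(native_seq))
  expect_equal(rep2$match_rate_pct, 25)
})
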