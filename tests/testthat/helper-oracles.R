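# Independent brute-force / closed-form oracles used by the test suite.
# These deliberately use naive scalar loops and textbook formulas so that
# they share no code path with the package implementations they check.

# minimum inter-atomic distance by explicit double loop
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# all residue contact pairs by exhaustive scan
brute_binding_pairs <- function(complex, cutoff = 5.0) {
  pr <- residues(complex, "protein")
  pe <- residues(complex, "peptide")
  out <- NULL
  for (i in seq_along(pr)) {
    for (j in seq_along(pe)) {
      if (brute_min_dist(pr[[i]], pe[[j]]) < cutoff)
        out <- rbind(out, c(pr[[i]]$resno[1], pe[[j]]$resno[1]))
    }
  }
  out
}

# contact energy by explicit atom-pair loop
brute_contact_energy <- function(complex, pot = contact_potential()) {
  a <- complex$atoms
  P <- a[a$role == "protein", ]
  Q <- a[a$role == "peptide", ]
  e <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(Q))) {
      d <- sqrt((P$x[i] - Q$x[j])^2 + (P$y[i] - Q$y[j])^2 +
                  (P$z[i] - Q$z[j])^2)
      if (d < pot$clash_distance) e <- e + pot$clash_penalty
      else if (d < pot$contact_distance) e <- e - pot$well_depth
    }
  }
  e
}

# analytic total SASA of two equal spheres of expanded radius R at center
# distance d: each loses a cap of height h = R - d/2 while the spheres overlap
two_sphere_area <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Monte-Carlo 2-D hypervolume estimate: area fraction of the bounding box
# dominated by at least one front point; returns estimate and its std. error
mc_hypervolume <- function(front, ref, n = 1e6, seed = 1) {
  hi <- apply(front, 2, max)
  box <- prod(hi - ref)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    px <- runif(n, ref[1], hi[1])
    py <- runif(n, ref[2], hi[2])
    dom <- rep(FALSE, n)
    for (k in seq_len(nrow(front)))
      dom <- dom | (px <= front[k, 1] & py <= front[k, 2])
    p <- mean(dom)
    list(estimate = p * box, se = sqrt(p * (1 - p) / n) * box)
  })
}

# closed-form GP posterior (squared-exponential kernel, fixed hyperparams),
# written directly from the textbook equations
gp_posterior_direct <- function(X, y, Xq, lengthscale, signal_var, noise_var,
                                jitter = 1e-8) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    signal_var * exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  X <- as.matrix(X); Xq <- as.matrix(Xq)
  K <- k(X, X) + diag(noise_var + jitter * signal_var, nrow(X))
  Ks <- k(Xq, X)
  Kss <- k(Xq, Xq)
  Ki <- solve(K)
  list(mean = as.numeric(Ks %*% Ki %*% y),
       cov = Kss - Ks %*% Ki %*% t(Ks))
}

# Independent NEHVI estimator: per candidate, sample the joint posterior over
# (observed points, candidate) per objective via the closed-form posterior and
# average hypervolume differences computed with hypervolume_2d.
nehvi_oracle <- function(cand_X, gp, obs_X, ref, n_mc, seed) {
  n_obs <- nrow(obs_X)
  stats <- matrix(NA_real_, nrow(cand_X), 2,
                  dimnames = list(NULL, c("mean", "sd")))
  for (ci in seq_len(nrow(cand_X))) {
    joint <- rbind(obs_X, cand_X[ci, , drop = FALSE])
    samp <- vector("list", 2)
    for (j in 1:2) {
      m <- gp$models[[j]]
      post <- gp_posterior_direct(m$X, m$y, joint, m$lengthscale,
                                  m$signal_var, m$noise_var)
      C <- (post$cov + t(post$cov)) / 2 + diag(1e-10, nrow(joint))
      L <- chol(C)
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed + 31L * ci + j)
      Z <- matrix(rnorm(nrow(joint) * n_mc), nrow(joint), n_mc)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      # scale back to original units the way the fitted model stores them
      samp[[j]] <- (post$mean * m$y_sd + m$y_mean) +
        t(L) %*% Z * m$y_sd
    }
    diffs <- numeric(n_mc)
    for (t in seq_len(n_mc)) {
      front <- cbind(samp[[1]][seq_len(n_obs), t], samp[[2]][seq_len(n_obs), t])
      cpt <- c(samp[[1]][n_obs + 1, t], samp[[2]][n_obs + 1, t])
      keep <- front[, 1] >= ref[1] & front[, 2] >= ref[2]
      hv0 <- if (any(keep)) hypervolume_2d(front[keep, , drop = FALSE], ref) else 0
      aug <- rbind(front[keep, , drop = FALSE],
                   if (all(cpt >= ref)) cpt)
      hv1 <- if (!is.null(aug) && nrow(aug)) hypervolume_2d(aug, ref) else 0
      diffs[t] <- hv1 - hv0
    }
    stats[ci, ] <- c(mean(diffs), sd(diffs))
  }
  stats
}

# uniformly random proper rotation matrix
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal C-alpha-only complex from a coordinate matrix (rows = residues)
make_ca_complex <- function(coords, n_protein, source_id = "ca-fixture") {
  n <- nrow(coords)
  role <- c(rep("protein", n_protein), rep("peptide", n - n_protein))
  resno <- c(seq_len(n_protein), seq_len(n - n_protein))
  atoms <- data.frame(
    role = role, chain = ifelse(role == "protein", "A", "B"),
    resno = resno, ins = "", resid = "ALA", elety = "CA", elesy = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], radius = 1.7,
    stringsAsFactors = FALSE)
  pepforge:::new_complex_structure(atoms, "A", "B", source_id)
}

# total SASA from an independent reference implementation (Biopython's
# Shrake-Rupley), run on a PDB file through the system python
biopython_sasa <- function(pdb_path, probe = 1.4, n_points = 960) {
  script <- sprintf(paste0(
    "import warnings; warnings.filterwarnings('ignore')\n",
    "from Bio.PDB import PDBParser\n",
    "from Bio.PDB.SASA import ShrakeRupley\n",
    "s = PDBParser(QUIET=True).get_structure('x', '%s')\n",
    "sr = ShrakeRupley(probe_radius=%g, n_points=%d)\n",
    "sr.compute(s[0], level='A')\n",
    "print(sum(a.sasa for a in s[0].get_atoms()))\n"),
    pdb_path, probe, n_points)
  out <- system2("python", "-", input = script, stdout = TRUE)
  as.numeric(tail(out, 1))
}
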