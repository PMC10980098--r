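# Pareto dominance, exact 2-D hypervolume, and the Monte-Carlo noisy
# expected hypervolume improvement acquisition. All objective values here are
# in canonical maximise-all form.

as_points2 <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2)
    stop_pf("expected two-objective points (2 columns)",
            class = "pepforge_bad_points")
  storage.mode(p) <- "double"
  p
}

#' Pareto-optimal subset (maximise both objectives)
#'
#' A point dominates another when it is no worse in both objectives and
#' strictly better in at least one. Ties (exactly duplicated points) are all
#' retained. Sort-and-sweep, O(n log n).
#'
#' @param points numeric matrix with one row per point and 2 columns.
#' @return integer indices of the non-dominated rows, in input order.
#' @export
pareto_front <- function(points) {
  p <- as_points2(points)
  n <- nrow(p)
  if (n == 0L) stop_pf("no points supplied", class = "pepforge_bad_points")
  ord <- order(p[, 1], p[, 2], decreasing = TRUE)
  keep <- logical(n)
  besty <- -Inf
  bestx <- -Inf
  for (i in ord) {
    y <- p[i, 2]
    if (y > besty) {
      keep[i] <- TRUE
      besty <- y
      bestx <- p[i, 1]
    } else if (y == besty && p[i, 1] == bestx) {
      keep[i] <- TRUE  # exact duplicate of a kept point
    }
  }
  which(keep)
}

#' Exact 2-D hypervolume
#'
#' Area of objective space dominated by `front` relative to the reference
#' point, by sort-and-sweep over the non-dominated subset. Every front point
#' must weakly dominate `ref`.
#'
#' @param front numeric matrix of points (maximise-all).
#' @param ref reference point (length-2).
#' @return dominated area.
#' @export
hypervolume_2d <- function(front, ref) {
  p <- as_points2(front)
  stopifnot(length(ref) == 2)
  if (any(p[, 1] < ref[1] | p[, 2] < ref[2]))
    stop_pf("all front points must dominate the reference point",
            class = "pepforge_bad_reference")
  nd <- p[pareto_front(p), , drop = FALSE]
  nd <- unique(nd)
  ord <- order(nd[, 2])  # ascending y => descending x on a front
  nd <- nd[ord, , drop = FALSE]
  heights <- nd[, 2] - c(ref[2], nd[-nrow(nd), 2])
  sum((nd[, 1] - ref[1]) * heights)
}

# Hypervolume contribution of each candidate point against a fixed front,
# vectorised over candidates. `front` may be empty (matrix with 0 rows).
hv_contribution <- function(front, cand, ref) {
  cand <- as_points2(cand)
  a <- pmin(cand[, 1], Inf)
  b <- cand[, 2]
  contrib <- numeric(nrow(cand))
  if (nrow(front)) {
    f <- front[front[, 1] >= ref[1] & front[, 2] >= ref[2], , drop = FALSE]
  } else f <- front
  if (!nrow(f)) {
    w <- pmax(0, a - ref[1])
    h <- pmax(0, b - ref[2])
    return(w * h)
  }
  nd <- f[pareto_front(f), , drop = FALSE]
  nd <- unique(nd)
  nd <- nd[order(nd[, 2]), , drop = FALSE]  # y ascending, x descending
  k <- nrow(nd)
  ylo <- c(ref[2], nd[-k, 2])
  for (s in seq_len(k)) {
    h <- pmax(0, pmin(b, nd[s, 2]) - pmax(ref[2], ylo[s]))
    w <- pmax(0, a - nd[s, 1])
    contrib <- contrib + h * w
  }
  contrib + pmax(0, b - nd[k, 2]) * pmax(0, a - ref[1])
}

#' Noisy expected hypervolume improvement (Monte-Carlo)
#'
#' Joint-posterior-sampling estimator: for each Monte-Carlo draw the GP
#' posterior is sampled jointly at the observed embeddings (yielding a
#' plausible noise-free Pareto front) and at each candidate, conditionally on
#' that front sample; the draw's contribution for a candidate is the
#' hypervolume added to the sampled front. The acquisition value is the mean
#' over draws — non-negative by construction and deterministic for a given
#' seed. Base samples at the observed points are shared across candidates.
#'
#' @param candidates matrix of candidate embeddings (rows).
#' @param gp a fitted two-objective `gp_surrogate`.
#' @param observed_X matrix of embeddings of all evaluated candidates.
#' @param ref reference point (canonical scale, length 2).
#' @param n_mc number of Monte-Carlo draws (default 128).
#' @param seed RNG seed for the draws.
#' @return numeric vector of acquisition values, one per candidate row.
#' @export
nehvi <- function(candidates, gp, observed_X, ref, n_mc = 128, seed = NULL) {
  if (!inherits(gp, "gp_surrogate"))
    stop_pf("gp must be a fitted gp_surrogate", class = "pepforge_gp_error")
  if (gp$n_objectives != 2)
    stop_pf("nehvi requires a two-objective surrogate",
            class = "pepforge_gp_error")
  stopifnot(n_mc >= 1, length(ref) == 2)
  candidates <- as.matrix(candidates)
  observed_X <- as.matrix(observed_X)
  n_obs <- nrow(observed_X)
  n_cand <- nrow(candidates)

  # Per objective: posterior over observed points and conditionals for the
  # candidates given a sampled front.
  prep <- lapply(gp$models, function(m) {
    post <- predict.gp_surrogate(structure(list(models = list(m)),
                                           class = "gp_surrogate"),
                                 observed_X, full_cov = TRUE)[[1]]
    S <- post$cov
    eig_jitter <- 1e-9 * max(1, mean(diag(S)))
    Lp <- tryCatch(chol(S + diag(eig_jitter, n_obs)),
                   error = function(e) chol(S + diag(1e-6 * max(diag(S)) +
                                                       1e-12, n_obs)))
    # cross-covariances between candidates and observed points under the
    # posterior: cov(f(c), f(Xo)) = K(c,Xo) - K(c,X) K^-1 K(X,Xo) (times y_sd^2)
    Kco <- se_kernel(candidates, m$X, m$lengthscale, m$signal_var)
    Koo <- se_kernel(observed_X, m$X, m$lengthscale, m$signal_var)
    Vc <- forwardsolve(t(m$L), t(Kco))
    Vo <- forwardsolve(t(m$L), t(Koo))
    Sco <- (se_kernel(candidates, observed_X, m$lengthscale, m$signal_var) -
              crossprod(Vc, Vo)) * m$y_sd^2
    mean_c <- as.numeric(Kco %*% m$alpha) * m$y_sd + m$y_mean
    var_c <- pmax(0, m$signal_var - colSums(Vc^2)) * m$y_sd^2
    A <- t(solve(S + diag(eig_jitter, n_obs), t(Sco)))   # n_cand x n_obs
    cvar <- pmax(0, var_c - rowSums(A * Sco))
    list(mean_obs = post$mean, L_obs = Lp, mean_c = mean_c,
         A = A, csd = sqrt(cvar))
  })

  acq <- numeric(n_cand)
  with_seed(seed, {
    for (t in seq_len(n_mc)) {
      fobs <- matrix(0, n_obs, 2)
      fc <- matrix(0, n_cand, 2)
      for (j in 1:2) {
        pj <- prep[[j]]
        z <- stats::rnorm(n_obs)
        fobs[, j] <- pj$mean_obs + as.numeric(crossprod(pj$L_obs, z))
        w <- stats::rnorm(n_cand)
        fc[, j] <- pj$mean_c +
          as.numeric(pj$A %*% (fobs[, j] - pj$mean_obs)) + pj$csd * w
      }
      acq <- acq + hv_contribution(fobs, fc, ref)
    }
  })
  acq / n_mc
}
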