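# Exact Gaussian-process surrogates: one independent GP per objective over
# the sequence embedding, squared-exponential kernel, hyperparameters by
# marginal-likelihood maximisation from a fixed deterministic start grid.

se_kernel <- function(A, B, lengthscale, signal_var) {
  signal_var * exp(-0.5 * sqdist(A, B) / lengthscale^2)
}

# Negative log marginal likelihood and fitted factors for one objective.
gp_factors <- function(X, y, lengthscale, signal_var, noise_var,
                       jitter = 1e-8) {
  n <- length(y)
  K <- se_kernel(X, X, lengthscale, signal_var)
  diag(K) <- diag(K) + noise_var + jitter * signal_var
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nlml <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  list(L = L, alpha = alpha, nlml = nlml)
}

fit_one_gp <- function(X, y, hyperparams = NULL) {
  n <- length(y)
  if (n >= 2 && all(sqdist(X, X)[upper.tri(diag(n))] < 1e-12)) {
    warning("all training embeddings identical; GP fitted with jitter only",
            call. = FALSE)
  }
  if (!is.null(hyperparams)) {
    hp <- hyperparams
    fac <- gp_factors(X, y, hp$lengthscale, hp$signal_var, hp$noise_var)
    if (is.null(fac))
      stop_pf("GP covariance not positive definite at fixed hyperparameters",
              class = "pepforge_gp_error")
    return(c(hp, fac[c("L", "alpha")], list(X = X, y = y)))
  }
  d <- sqrt(sqdist(X, X))
  dv <- d[upper.tri(d)]
  dv <- dv[dv > 0]
  l0 <- if (length(dv)) stats::median(dv) else 1
  if (!is.finite(l0) || l0 <= 0) l0 <- 1
  obj <- function(theta) {
    fac <- gp_factors(X, y, exp(theta[1]), exp(theta[2]), exp(theta[3]))
    if (is.null(fac)) return(1e10)
    fac$nlml
  }
  # fixed deterministic restart grid (3 starts); on the small-lengthscale
  # ridge the signal/noise split is unidentifiable, so near-ties in marginal
  # likelihood are broken toward the lower-noise (interpolating) solution
  starts <- list(c(log(0.3 * l0), 0, log(1e-6)),
                 c(log(l0), 0, log(1e-2)),
                 c(log(3 * l0), 0, log(1e-4)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = c(log(l0) - 8, -8, log(1e-8)),
                   upper = c(log(l0) + 8, 8, 4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-4 ||
        (abs(fit$value - best$value) <= 1e-4 &&
           fit$par[3] < best$par[3])) best <- fit
  }
  if (is.null(best))
    stop_pf("GP hyperparameter optimisation failed", class = "pepforge_gp_error")
  hp <- list(lengthscale = exp(best$par[1]), signal_var = exp(best$par[2]),
             noise_var = exp(best$par[3]))
  fac <- gp_factors(X, y, hp$lengthscale, hp$signal_var, hp$noise_var)
  c(hp, fac[c("L", "alpha")], list(X = X, y = y))
}

#' Fit independent Gaussian-process surrogates
#'
#' One exact GP per objective column of `Y`, squared-exponential kernel, over
#' the rows of `X` (sequence embeddings). Objectives are standardised to zero
#' mean and unit variance internally (predictions are returned on the original
#' scale); hyperparameters are chosen by L-BFGS maximisation of the log
#' marginal likelihood from a fixed three-point start grid, so the fit is
#' deterministic. Supplying `hyperparams` (a list with `lengthscale`,
#' `signal_var`, `noise_var`, or a list of such lists, one per objective)
#' skips optimisation — useful for closed-form cross-checks.
#'
#' @param X numeric matrix of embeddings (rows = observations).
#' @param Y numeric vector or matrix of objective values (columns =
#'   objectives, canonical maximise-all form).
#' @param hyperparams optional fixed hyperparameters (see above).
#' @param standardize standardise each objective internally (default TRUE).
#' @return object of class `gp_surrogate`.
#' @export
fit_gp <- function(X, Y, hyperparams = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) < 2)
    stop_pf("GP fitting needs at least 2 points", class = "pepforge_gp_error")
  if (nrow(X) != nrow(Y))
    stop_pf("X and Y row counts differ", class = "pepforge_gp_error")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop_pf("non-finite values in GP training data",
            class = "pepforge_gp_error")
  m <- ncol(Y)
  if (!is.null(hyperparams) && !is.null(hyperparams$lengthscale))
    hyperparams <- rep(list(hyperparams), m)
  models <- vector("list", m)
  for (j in seq_len(m)) {
    y <- Y[, j]
    if (standardize) {
      mu <- mean(y)
      sd_ <- stats::sd(y)
      if (!is.finite(sd_) || sd_ < 1e-12) sd_ <- 1
    } else {
      mu <- 0; sd_ <- 1
    }
    mod <- fit_one_gp(X, (y - mu) / sd_, hyperparams[[j]])
    mod$y_mean <- mu
    mod$y_sd <- sd_
    models[[j]] <- mod
  }
  structure(list(models = models, n_objectives = m, n_train = nrow(X)),
            class = "gp_surrogate")
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf("<gp_surrogate> %d objective(s), %d training points\n",
              x$n_objectives, x$n_train))
  for (j in seq_along(x$models)) {
    m <- x$models[[j]]
    cat(sprintf("  [%d] lengthscale %.3g, signal_var %.3g, noise_var %.3g\n",
                j, m$lengthscale, m$signal_var, m$noise_var))
  }
  invisible(x)
}

#' Posterior prediction from a GP surrogate
#'
#' @param object a `gp_surrogate`.
#' @param Xnew matrix of query embeddings.
#' @param full_cov also return the full posterior covariance matrix.
#' @param ... unused.
#' @return a list with one element per objective, each containing `mean`,
#'   `var` (pointwise, floored at 0) and, when requested, `cov`.
#' @export
predict.gp_surrogate <- function(object, Xnew, full_cov = FALSE, ...) {
  Xnew <- as.matrix(Xnew)
  lapply(object$models, function(m) {
    Ks <- se_kernel(Xnew, m$X, m$lengthscale, m$signal_var)
    mean_std <- as.numeric(Ks %*% m$alpha)
    V <- forwardsolve(t(m$L), t(Ks))
    out <- list(mean = mean_std * m$y_sd + m$y_mean)
    if (full_cov) {
      Kss <- se_kernel(Xnew, Xnew, m$lengthscale, m$signal_var)
      S <- Kss - crossprod(V)
      S <- (S + t(S)) / 2
      out$cov <- S * m$y_sd^2
      out$var <- pmax(0, diag(S)) * m$y_sd^2
    } else {
      v <- m$signal_var - colSums(V^2)
      out$var <- pmax(0, v) * m$y_sd^2
    }
    out
  })
}
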