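# Native-recovery metrics: optimal rigid superposition, TM-score, and the
# binding-site-count match rate over an optimization archive.

#' Kabsch optimal superposition
#'
#' Least-squares rigid-body superposition of point set `P` onto `Q` (paired
#' rows): closed-form solution via the SVD of the cross-covariance, with the
#' reflection corrected so the rotation is proper (determinant +1).
#'
#' @param P,Q `N x 3` coordinate matrices, `N >= 3`, rows paired.
#' @return object of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd`. The transform maps `P` onto `Q`:
#'   `P %*% t(rotation) + translation`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop_pf("P and Q must be N x 3 matrices with equal N",
            class = "pepforge_bad_superposition")
  if (nrow(P) < 3)
    stop_pf("superposition needs at least 3 points",
            class = "pepforge_bad_superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop_pf("degenerate (collinear) point set; rotation is not unique",
            class = "pepforge_degenerate_points")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

calpha_coords <- function(complex, align_on) {
  sides <- if (align_on == "peptide") "peptide" else c("protein", "peptide")
  rows <- do.call(rbind, lapply(sides, function(s) {
    a <- complex$atoms[complex$atoms$role == s & complex$atoms$elety == "CA", ,
                       drop = FALSE]
    a
  }))
  if (nrow(rows) == 0L)
    stop_pf("no C-alpha atoms in selection", class = "pepforge_bad_selection")
  as.matrix(rows[, c("x", "y", "z")])
}

tm_d0 <- function(L) {
  # the standard normalisation is non-positive for short chains; floor at
  # 0.5 A, the convention of reference TM-score implementations
  if (L > 21) max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8) else 0.5
}

#' TM-score between a candidate and the native complex
#'
#' Length-normalised structural similarity in (0, 1]: C-alpha coordinates of
#' the chosen selection are superposed by [kabsch()] and scored as
#' `mean(1 / (1 + (d_i/d0)^2))` with `d0 = 1.24 (L-15)^(1/3) - 1.8` floored
#' at 0.5 Angstrom for short selections (`L <= 21`). Residue correspondence
#' is positional — candidates are expected to share the native's residue
#' count (no alignment search is performed).
#'
#' @param candidate,native `complex_structure` objects.
#' @param align_on `"complex"` (all C-alphas, default) or `"peptide"`.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(candidate, native, align_on = c("complex", "peptide")) {
  align_on <- match.arg(align_on)
  P <- calpha_coords(candidate, align_on)
  Q <- calpha_coords(native, align_on)
  if (nrow(P) != nrow(Q))
    stop_pf("selections differ in residue count (%d vs %d); no alignment search is performed",
            nrow(P), nrow(Q), class = "pepforge_length_mismatch")
  sup <- kabsch(P, Q)
  aligned <- sweep(P %*% t(sup$rotation), 2, sup$translation, "+")
  d <- sqrt(rowSums((aligned - Q)^2))
  L <- nrow(Q)
  mean(1 / (1 + (d / tm_d0(L))^2))
}

#' Native-recovery report for an optimization archive
#'
#' Compares every scored candidate against the native complex: the fraction
#' (as a percentage) whose peptide-side binding-site count exactly matches
#' the native's, the best TM-score over the archive, the best candidate per
#' objective, and the per-round objective traces.
#'
#' @param archive a `pep_archive` with stored structures.
#' @param native_complex the native `complex_structure`.
#' @param cutoff residue-contact cutoff, Angstrom.
#' @return object of class `recovery_report`.
#' @export
recovery_report <- function(archive, native_complex, cutoff = 5.0) {
  stopifnot(inherits(archive, "pep_archive"))
  validate_complex(native_complex)
  native_count <- binding_site_count(native_complex, "peptide", cutoff)
  ok <- archive$candidates[archive$candidates$status == "ok", , drop = FALSE]
  counts <- vapply(ok$sequence, function(s) {
    st <- archive$structures[[s]]
    if (is.null(st)) return(NA_integer_)
    binding_site_count(st, "peptide", cutoff)
  }, integer(1))
  tm <- vapply(ok$sequence, function(s) {
    st <- archive$structures[[s]]
    if (is.null(st)) return(NA_real_)
    tryCatch(tm_score(st, native_complex, "complex"), error = function(e) NA_real_)
  }, numeric(1))
  match_rate <- 100 * mean(counts == native_count, na.rm = TRUE)
  o <- archive$config$objectives
  best_per_obj <- lapply(1:2, function(j) {
    col <- paste0("c", j)
    ok[which.max(ok[[col]]), c("sequence", "round", o)]
  })
  names(best_per_obj) <- o
  structure(list(
    native_count = native_count,
    candidate_counts = data.frame(sequence = ok$sequence, round = ok$round,
                                  peptide_sites = unname(counts),
                                  matches_native = unname(counts) == native_count,
                                  tm_score = unname(tm)),
    match_rate_pct = match_rate,
    best_tm_score = if (all(is.na(tm))) NA_real_ else max(tm, na.rm = TRUE),
    best_per_objective = best_per_obj,
    native_recovered = archive$native_peptide %in% ok$sequence,
    traces = archive$summary,
    cutoff = cutoff), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  native peptide binding sites: %d (cutoff %.1f A)\n",
              x$native_count, x$cutoff))
  cat(sprintf("  binding-site-count match rate: %.2f%% of %d candidates\n",
              x$match_rate_pct, nrow(x$candidate_counts)))
  cat(sprintf("  best TM-score vs native: %.3f\n", x$best_tm_score))
  cat(sprintf("  native sequence recovered: %s\n", x$native_recovered))
  invisible(x)
}
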