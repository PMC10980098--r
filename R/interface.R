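# Binding-site detection and per-chain binding ratios.
#
# Two residues are in contact when their minimum heavy-atom distance is
# strictly below the cutoff (default 5 Angstrom, the standard residue-contact
# criterion for protein-peptide interfaces).

# All inter-chain residue pair minimum distances as a matrix
# (protein residues x peptide residues).
residue_distance_matrix <- function(complex) {
  a <- complex$atoms
  P <- a[a$role == "protein", , drop = FALSE]
  Q <- a[a$role == "peptide", , drop = FALSE]
  D2 <- sqdist(as.matrix(P[, c("x", "y", "z")]),
               as.matrix(Q[, c("x", "y", "z")]))
  pkey <- factor(paste0(P$resno, P$ins), levels = unique(paste0(P$resno, P$ins)))
  qkey <- factor(paste0(Q$resno, Q$ins), levels = unique(paste0(Q$resno, Q$ins)))
  # min over atom groups: first collapse columns per peptide residue,
  # then rows per protein residue
  qs <- split(seq_len(nrow(Q)), qkey)
  colmin <- vapply(qs, function(ix) {
    do.call(pmin, as.data.frame(D2[, ix, drop = FALSE]))
  }, numeric(nrow(P)))
  if (nrow(P) == 1L) colmin <- matrix(colmin, nrow = 1L)
  ps <- split(seq_len(nrow(P)), pkey)
  M <- t(vapply(ps, function(ix) {
    apply(colmin[ix, , drop = FALSE], 2, min)
  }, numeric(length(qs))))
  if (length(qs) == 1L) M <- matrix(M, ncol = 1L)
  dimnames(M) <- list(levels(pkey), levels(qkey))
  sqrt(M)
}

#' Inter-chain residue contacts ("binding sites")
#'
#' All and only the protein/peptide residue pairs whose minimum heavy-atom
#' distance is strictly less than `cutoff`.
#'
#' @param complex a `complex_structure`.
#' @param cutoff contact distance in Angstrom (default 5).
#' @return object of class `binding_pairs`: a data frame of
#'   `(protein_resno, peptide_resno, distance)` plus the cutoff.
#' @export
binding_pairs <- function(complex, cutoff = 5.0) {
  validate_complex(complex)
  D <- residue_distance_matrix(complex)
  hit <- which(D < cutoff, arr.ind = TRUE)
  prot_res <- residues(complex, "protein")
  pep_res <- residues(complex, "peptide")
  prot_no <- vapply(prot_res, function(r) r$resno[1], numeric(1))
  pep_no <- vapply(pep_res, function(r) r$resno[1], numeric(1))
  pairs <- data.frame(
    protein_resno = unname(prot_no[hit[, 1]]),
    peptide_resno = unname(pep_no[hit[, 2]]),
    distance = D[hit])
  pairs <- pairs[order(pairs$protein_resno, pairs$peptide_resno), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, cutoff = cutoff), class = "binding_pairs")
}

#' @export
print.binding_pairs <- function(x, ...) {
  cat(sprintf("<binding_pairs> %d contacts at cutoff %.2f A\n",
              nrow(x$pairs), x$cutoff))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10))
  invisible(x)
}

#' Number of contacting residues on one chain
#'
#' Count of unique residues on `side` within `cutoff` of any residue of the
#' partner chain — the numerator of [binding_ratio()].
#'
#' @inheritParams binding_pairs
#' @param side `"protein"` or `"peptide"`.
#' @export
binding_site_count <- function(complex, side = c("protein", "peptide"),
                               cutoff = 5.0) {
  side <- match.arg(side)
  bp <- binding_pairs(complex, cutoff)
  col <- if (side == "protein") "protein_resno" else "peptide_resno"
  length(unique(bp$pairs[[col]]))
}

#' Binding ratio of one chain
#'
#' Fraction of a chain's residues that contact the partner chain: unique
#' contacting residues on `side` divided by the chain's residue count.
#'
#' @inheritParams binding_site_count
#' @return a fraction in `[0, 1]`.
#' @export
binding_ratio <- function(complex, side = c("protein", "peptide"),
                          cutoff = 5.0) {
  side <- match.arg(side)
  binding_site_count(complex, side, cutoff) / chain_length(complex, side)
}
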