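# Stability objective. The production route is an external free-energy
# calculator (e.g. an empirical force field reporting dG) wired in through
# `external_energy()`; the self-contained route is a simple inter-chain
# contact potential whose ordering, not its absolute scale, is what the
# optimizer consumes (lower = more stable).

#' Contact potential parameters
#'
#' Square-well inter-chain pair potential: a favourable well of depth
#' `well_depth` for heavy-atom pairs with `clash_distance <= d <
#' contact_distance`, and a `clash_penalty` for pairs closer than
#' `clash_distance`. Units are arbitrary; objectives are standardised inside
#' the optimizer so only the ordering matters.
#'
#' @param well_depth depth of the favourable contact well.
#' @param contact_distance outer contact distance, Angstrom (aligned with the
#'   5-Angstrom residue-contact cutoff).
#' @param clash_distance steric-clash distance, Angstrom.
#' @param clash_penalty energy added per clashing atom pair.
#' @export
contact_potential <- function(well_depth = 1.0, contact_distance = 5.0,
                              clash_distance = 2.5, clash_penalty = 10.0) {
  if (!(clash_distance < contact_distance))
    stop_pf("clash_distance must be smaller than contact_distance",
            class = "pepforge_bad_potential")
  stopifnot(well_depth >= 0, clash_penalty >= 0, clash_distance > 0)
  structure(list(well_depth = well_depth,
                 contact_distance = contact_distance,
                 clash_distance = clash_distance,
                 clash_penalty = clash_penalty),
            class = "contact_potential")
}

#' Inter-chain contact energy
#'
#' Sum over all protein/peptide heavy-atom pairs of `-well_depth` for pairs in
#' the contact well and `+clash_penalty` for clashing pairs; intra-chain terms
#' are not scored. Exactly zero once the chains are separated beyond the
#' contact distance.
#'
#' @param complex a `complex_structure`.
#' @param pot a [contact_potential()].
#' @return scalar energy (lower = more stable).
#' @export
contact_energy <- function(complex, pot = contact_potential()) {
  validate_complex(complex)
  stopifnot(inherits(pot, "contact_potential"))
  a <- complex$atoms
  P <- as.matrix(a[a$role == "protein", c("x", "y", "z")])
  Q <- as.matrix(a[a$role == "peptide", c("x", "y", "z")])
  d2 <- sqdist(P, Q)
  n_clash <- sum(d2 < pot$clash_distance^2)
  n_contact <- sum(d2 >= pot$clash_distance^2 & d2 < pot$contact_distance^2)
  n_clash * pot$clash_penalty - n_contact * pot$well_depth
}

#' Energy via an external calculator
#'
#' Adapter contract for plugging in a real free-energy program: the complex is
#' written to a temporary PDB file, the adapter command is invoked with that
#' path as its final argument, and the last whitespace-delimited token of its
#' standard output is parsed as the energy. Every failure mode (missing
#' executable, non-zero exit, non-numeric output) raises a structured error;
#' there is no silent fallback.
#'
#' @param complex a `complex_structure`.
#' @param command adapter executable.
#' @param args extra arguments placed before the PDB path.
#' @return scalar energy as reported by the adapter.
#' @export
external_energy <- function(complex, command, args = character()) {
  validate_complex(complex)
  if (!nzchar(Sys.which(command)) && !file.exists(command))
    stop_pf("external energy adapter '%s' not found", command,
            class = "pepforge_adapter_missing")
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_pdb(complex, file = pdb)
  out <- suppressWarnings(system2(command, c(args, pdb), stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop_pf("external energy adapter '%s' exited with status %d", command,
            status, class = "pepforge_adapter_failed")
  tokens <- unlist(strsplit(paste(out, collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop_pf("external energy adapter produced no output",
            class = "pepforge_adapter_parse")
  val <- suppressWarnings(as.numeric(tokens[length(tokens)]))
  if (is.na(val))
    stop_pf("could not parse energy from adapter output token '%s'",
            tokens[length(tokens)], class = "pepforge_adapter_parse")
  val
}
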