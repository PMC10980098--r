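# Deterministic synthetic protein-peptide complexes. These emulate the
# geometry every module needs - an extended chain with one pseudo side-chain
# atom per residue, a bound peptide forming a contact interface, and
# controlled decoys - without any physical realism beyond atom packing.

toy_residue_atoms <- function(role, chain, resno, aa, ca, cb) {
  data.frame(
    role = role, chain = chain, resno = resno, ins = "",
    resid = unname(AA_THREE[aa]), elety = c("CA", "CB"), elesy = "C",
    x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3]),
    radius = c(1.70, sidechain_radius(aa)),
    stringsAsFactors = FALSE)
}

#' Synthetic protein-peptide toy complex
#'
#' Protein: an extended chain (C-alpha spacing 3.8 Angstrom along x) with one
#' volume-scaled pseudo side-chain atom per residue pointing at the peptide.
#' Peptide: a parallel chain whose side chains point back at the protein.
#' `mode` controls the decoy geometry: `"docked"` places the chains so that
#' side-chain tips are about `interface_gap` apart (contacts at the 5-Angstrom
#' cutoff for the default gap), `"separated"` moves the peptide 100 Angstrom
#' away (no interface), `"clashing"` overlaps the chains (steric clashes).
#' Sequences are drawn uniformly; everything is deterministic per seed.
#'
#' @param n_protein,n_peptide residue counts (>= 3 each).
#' @param interface_gap approximate side-chain tip separation, Angstrom.
#' @param mode `"docked"`, `"separated"` or `"clashing"`.
#' @param seed RNG seed for the sequences.
#' @return a `complex_structure` (protein chain A, peptide chain B).
#' @export
make_toy_complex <- function(n_protein = 10, n_peptide = 6,
                             interface_gap = 4.5,
                             mode = c("docked", "separated", "clashing"),
                             seed = 1) {
  mode <- match.arg(mode)
  if (n_protein < 3 || n_peptide < 3)
    stop_pf("toy complexes need at least 3 residues per chain",
            class = "pepforge_bad_fixture")
  seqs <- with_seed(seed, list(
    prot = sample(AA_ALPHABET, n_protein, replace = TRUE),
    pep = sample(AA_ALPHABET, n_peptide, replace = TRUE)))
  y_pep <- switch(mode,
                  docked = interface_gap + 3.0,
                  separated = 100.0,
                  clashing = 1.0)
  res <- list()
  for (i in seq_len(n_protein)) {
    aa <- seqs$prot[i]
    ca <- c(3.8 * (i - 1), 0, 0)
    cb <- ca + c(0, sidechain_offset(aa), 0)
    res[[length(res) + 1L]] <- toy_residue_atoms("protein", "A", i, aa, ca, cb)
  }
  for (j in seq_len(n_peptide)) {
    aa <- seqs$pep[j]
    ca <- c(3.8 * (j - 1), y_pep, 0)
    cb <- ca - c(0, sidechain_offset(aa), 0)
    res[[length(res) + 1L]] <- toy_residue_atoms("peptide", "B", j, aa, ca, cb)
  }
  atoms <- do.call(rbind, res)
  rownames(atoms) <- NULL
  new_complex_structure(atoms, "A", "B",
                        sprintf("toy-%s-seed%d", mode, seed))
}

#' Native-recovery optimization landscape
#'
#' Builds a docked toy complex plus a template-threading provider in which the
#' native peptide sequence is, by construction, the global optimum of both
#' default objectives (buried interface area, maximised; contact energy,
#' minimised). Each protein "pocket" atom is placed so the native side chain
#' sits just inside the contact well (4.93 Angstrom) and maximally buried;
#' because pseudo-side-chain offset and radius grow with residue volume, any
#' substitution at a position shrinks that position's buried area and drops
#' its favourable contact. The guarantee therefore requires every native
#' residue to be volume-maximal, i.e. tryptophan; a warning is issued
#' otherwise. Default native: `"WWWWWW"`.
#'
#' @param native_peptide one-letter native sequence (default all-Trp 6-mer).
#' @param seed kept for interface symmetry with the other fixtures; the
#'   construction itself is deterministic.
#' @return a `structure_provider` with attributes `native_complex` (the
#'   threaded native) and `native_peptide`.
#' @export
make_recovery_landscape <- function(native_peptide = "WWWWWW", seed = 1) {
  chars <- validate_peptide_sequence(native_peptide, "native_peptide")
  if (any(chars != "W"))
    warning("recovery landscape native-optimum guarantee holds only for ",
            "volume-maximal (all-W) native peptides", call. = FALSE)
  L <- length(chars)
  if (L < 3)
    stop_pf("native peptide must have at least 3 residues",
            class = "pepforge_bad_fixture")
  contact_d <- 4.93   # native side chain just inside the 5 A contact well
  res <- list()
  for (i in seq_len(L)) {
    x <- 3.8 * (i - 1)
    # protein pocket residue: CA buried below, pseudo-atom facing peptide
    pocket_y <- -(sidechain_offset(chars[i]) + contact_d)
    pocket <- data.frame(
      role = "protein", chain = "A", resno = i, ins = "",
      resid = "GLY", elety = c("CA", "CB"), elesy = "C",
      x = x, y = c(pocket_y - 2.5, pocket_y), z = 0,
      radius = c(1.70, 1.40), stringsAsFactors = FALSE)
    res[[length(res) + 1L]] <- pocket
  }
  for (i in seq_len(L)) {
    x <- 3.8 * (i - 1)
    aa <- chars[i]
    ca <- c(x, 0, 0)
    cb <- c(x, -sidechain_offset(aa), 0)
    res[[length(res) + 1L]] <- toy_residue_atoms("peptide", "B", i, aa, ca, cb)
  }
  atoms <- do.call(rbind, res)
  rownames(atoms) <- NULL
  template <- new_complex_structure(atoms, "A", "B",
                                    sprintf("recovery-landscape-seed%d", seed))
  provider <- template_provider(template)
  attr(provider, "native_complex") <- template
  attr(provider, "native_peptide") <- native_peptide
  provider
}
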