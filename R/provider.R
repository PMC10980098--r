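# Structure providers: anything that turns a peptide sequence into a
# protein-peptide complex with the fixed target. The desk-scale provider is
# template threading onto a native complex; a documented adapter contract
# allows swapping in a real complex-structure predictor.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Thread a peptide sequence onto a native complex template
#'
#' Cheap structure surrogate: the native coordinates are kept rigid and, at
#' each mutated peptide position, the side-chain atoms are replaced by a
#' single pseudo-atom along the template's C-alpha to C-beta direction. The
#' pseudo-atom's offset from C-alpha and its radius both scale with the cube
#' root of the residue volume, so substitutions move the structural
#' objectives the way side-chain bulk does. Unmutated residues are untouched;
#' threading the native sequence returns the template unchanged.
#'
#' @param native_complex a `complex_structure` template.
#' @param peptide_seq one-letter sequence, same length as the template
#'   peptide.
#' @return a `complex_structure`.
#' @export
thread_template <- function(native_complex, peptide_seq) {
  validate_complex(native_complex)
  chars <- validate_peptide_sequence(peptide_seq, "peptide_seq")
  pep <- residues(native_complex, "peptide")
  if (length(chars) != length(pep))
    stop_pf("peptide_seq length %d does not match template peptide length %d",
            length(chars), length(pep), class = "pepforge_length_mismatch")
  native_chars <- vapply(pep, function(r) {
    one <- aa_one_from_three(r$resid[1]); if (is.na(one)) "X" else one
  }, character(1))
  out_res <- vector("list", length(pep))
  for (i in seq_along(pep)) {
    r <- pep[[i]]
    if (chars[i] == native_chars[i]) {
      out_res[[i]] <- r
      next
    }
    ca <- r[r$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L)
      stop_pf("peptide residue %s has no C-alpha atom; cannot thread",
              r$resno[1], class = "pepforge_bad_residue")
    ca_pos <- as.numeric(ca[1, c("x", "y", "z")])
    cb <- r[r$elety == "CB", , drop = FALSE]
    if (nrow(cb) > 0L) {
      u <- as.numeric(cb[1, c("x", "y", "z")]) - ca_pos
    } else {
      nn <- r[r$elety == "N", , drop = FALSE]
      cc <- r[r$elety == "C", , drop = FALSE]
      if (nrow(nn) && nrow(cc)) {
        mid <- (as.numeric(nn[1, c("x", "y", "z")]) +
                  as.numeric(cc[1, c("x", "y", "z")])) / 2
        u <- ca_pos - mid
      } else u <- c(0, 0, 1)
    }
    nu <- sqrt(sum(u^2))
    u <- if (nu > 1e-9) u / nu else c(0, 0, 1)
    pos <- ca_pos + u * sidechain_offset(chars[i])
    bb <- r[r$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    side <- bb[1, , drop = FALSE]  # copy chain/residue metadata from backbone
    side$elety <- "CB"
    side$elesy <- "C"
    side$x <- pos[1]; side$y <- pos[2]; side$z <- pos[3]
    side$radius <- sidechain_radius(chars[i])
    newr <- rbind(bb, side)
    newr$resid <- AA_THREE[chars[i]]
    out_res[[i]] <- newr
  }
  prot <- native_complex$atoms[native_complex$atoms$role == "protein", ,
                               drop = FALSE]
  atoms <- rbind(prot, do.call(rbind, out_res))
  rownames(atoms) <- NULL
  new_complex_structure(atoms, native_complex$protein_chain,
                        native_complex$peptide_chain,
                        paste0(native_complex$source_id, "-threaded"))
}

new_structure_provider <- function(fun, label) {
  structure(list(fun = fun, label = label), class = "structure_provider")
}

#' Predict a complex structure for a peptide sequence
#'
#' @param provider a `structure_provider`.
#' @param peptide_seq one-letter peptide sequence.
#' @return a `complex_structure`.
#' @export
predict_structure <- function(provider, peptide_seq) {
  stopifnot(inherits(provider, "structure_provider"))
  provider$fun(peptide_seq)
}

#' @export
print.structure_provider <- function(x, ...) {
  cat(sprintf("<structure_provider> %s\n", x$label))
  invisible(x)
}

#' Template-threading structure provider
#'
#' Wraps [thread_template()] over a fixed native complex; deterministic and
#' seed-free.
#'
#' @param native_complex the template `complex_structure`.
#' @export
template_provider <- function(native_complex) {
  validate_complex(native_complex)
  force(native_complex)
  new_structure_provider(
    function(peptide_seq) thread_template(native_complex, peptide_seq),
    sprintf("template threading on '%s'", native_complex$source_id))
}

#' External structure-prediction adapter
#'
#' Integration point for a real complex-structure predictor run outside this
#' package: the target and peptide sequences are written as FASTA files, the
#' command is invoked as `command <args> <protein.fasta> <peptide.fasta>`, and
#' its last line of standard output must be the path of the predicted PDB,
#' which is parsed with the given chain assignment. Failures raise structured
#' errors.
#'
#' @param command adapter executable.
#' @param protein_seq target protein sequence written for the adapter.
#' @param protein_chain,peptide_chain chain ids in the returned PDB.
#' @param args extra adapter arguments.
#' @export
external_provider <- function(command, protein_seq, protein_chain = "A",
                              peptide_chain = "B", args = character()) {
  if (!nzchar(Sys.which(command)) && !file.exists(command))
    stop_pf("structure adapter '%s' not found", command,
            class = "pepforge_adapter_missing")
  new_structure_provider(function(peptide_seq) {
    fa_p <- tempfile(fileext = ".fasta")
    fa_q <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fa_p, fa_q)))
    seqinr::write.fasta(list(strsplit(protein_seq, "")[[1]]), "target", fa_p)
    seqinr::write.fasta(list(strsplit(peptide_seq, "")[[1]]), "peptide", fa_q)
    out <- suppressWarnings(system2(command, c(args, fa_p, fa_q),
                                    stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop_pf("structure adapter exited with status %d", status,
              class = "pepforge_adapter_failed")
    path <- trimws(utils::tail(out[nzchar(trimws(out))], 1))
    if (!length(path) || !file.exists(path))
      stop_pf("structure adapter did not return a PDB path",
              class = "pepforge_adapter_parse")
    parse_pdb(path, protein_chain, peptide_chain)
  }, sprintf("external adapter '%s'", command))
}
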