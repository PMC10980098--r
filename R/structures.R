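#' Van der Waals radii table
#'
#' Element-keyed heavy-atom radii (Angstrom) used to dress parsed structures
#' for surface-area calculations. Defaults are the standard Bondi-style set
#' (C 1.70, N 1.55, O 1.52, S 1.80) with a carbon-like fallback for elements
#' not in the table.
#'
#' @param overrides named numeric vector of element radii to add or replace.
#' @param default radius used for elements absent from the table.
#' @return an object of class `radii_table`.
#' @export
radii_table <- function(overrides = NULL, default = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    radii[toupper(names(overrides))] <- overrides
  }
  all_r <- c(radii, default)
  if (any(all_r <= 0.5) || any(all_r >= 3.0))
    stop_pf("all van der Waals radii must lie in (0.5, 3.0) Angstrom",
            class = "pepforge_bad_radii")
  structure(list(radii = radii, default = default), class = "radii_table")
}

radius_for_element <- function(table, element) {
  r <- table$radii[toupper(element)]
  r[is.na(r)] <- table$default
  unname(r)
}

new_complex_structure <- function(atoms, protein_chain, peptide_chain,
                                  source_id = "") {
  stopifnot(is.data.frame(atoms))
  obj <- structure(
    list(atoms = atoms, protein_chain = protein_chain,
         peptide_chain = peptide_chain, source_id = source_id),
    class = "complex_structure")
  validate_complex(obj)
  obj
}

validate_complex <- function(x) {
  if (!inherits(x, "complex_structure"))
    stop_pf("not a complex_structure", class = "pepforge_bad_complex")
  a <- x$atoms
  need <- c("role", "chain", "resno", "ins", "resid", "elety", "elesy",
            "x", "y", "z", "radius")
  if (!all(need %in% names(a)))
    stop_pf("atom table is missing columns", class = "pepforge_bad_complex")
  if (x$protein_chain == x$peptide_chain)
    stop_pf("protein and peptide chain identifiers must differ",
            class = "pepforge_bad_complex")
  for (side in c("protein", "peptide")) {
    sub <- a[a$role == side, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop_pf("%s chain has no atoms", side, class = "pepforge_bad_complex")
    key <- paste(sub$resno, sub$ins, sep = "|")
    first <- !duplicated(key)
    rn <- sub$resno[first]; ic <- sub$ins[first]
    # residues must appear in strictly increasing (resno, insertion) order
    cmp <- rn[-1] > rn[-length(rn)] |
      (rn[-1] == rn[-length(rn)] & ic[-1] > ic[-length(ic)])
    if (length(rn) > 1L && !all(cmp))
      stop_pf("%s residues are not in strictly increasing sequence order",
              side, class = "pepforge_bad_complex")
  }
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop_pf("non-finite atom coordinates", class = "pepforge_bad_complex")
  if (any(a$radius <= 0))
    stop_pf("non-positive atom radius", class = "pepforge_bad_complex")
  invisible(x)
}

infer_element <- function(elety) {
  # Strip digits/primes, then take a leading two-letter element if recognised,
  # else the first letter. Covers names like "1HB", "CA", "SD", "OXT".
  s <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(s, 1, 1))
  ifelse(first == "", "C", first)
}

#' Parse a protein-peptide complex from PDB text
#'
#' Reads fixed-width ATOM records (via bio3d), keeps the first MODEL only,
#' drops HETATM records, waters and hydrogens, resolves alternate locations to
#' the highest-occupancy altloc (ties: first encountered), and assigns van der
#' Waals radii by element.
#'
#' @param text a single string (or character vector of lines) of PDB content,
#'   or a path to a PDB file.
#' @param protein_chain,peptide_chain one-character chain identifiers.
#' @param radii a [radii_table()].
#' @param source_id free-text label stored on the result.
#' @return a `complex_structure`: atom table plus chain roles.
#' @export
parse_pdb <- function(text, protein_chain, peptide_chain,
                      radii = radii_table(), source_id = NULL) {
  stopifnot(nchar(protein_chain) == 1L, nchar(peptide_chain) == 1L)
  if (protein_chain == peptide_chain)
    stop_pf("protein and peptide chains must differ",
            class = "pepforge_bad_complex")
  is_path <- length(text) == 1L && !grepl("\n", text) &&
    !startsWith(text, "ATOM") && !startsWith(text, "HEADER") &&
    file.exists(text)
  if (is_path) {
    lines <- readLines(text)
    if (is.null(source_id)) source_id <- basename(text)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "pdb-text"
  }

  # Validate coordinate fields of ATOM records up front so a malformed line is
  # reported with its line number rather than as a parser failure downstream.
  atom_idx <- grep("^ATOM  ", lines)
  if (!length(atom_idx))
    stop_pf("no ATOM records found", class = "pepforge_parse_error")
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop_pf("unparseable ATOM record at line %d (too short)", i,
              class = "pepforge_parse_error")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop_pf("unparseable coordinates in ATOM record at line %d", i,
              class = "pepforge_parse_error")
  }

  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- bio3d::read.pdb(f, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  elesy <- at$elesy
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- infer_element(at$elety[miss])
  elesy <- toupper(elesy)
  keep <- !(elesy %in% c("H", "D")) & !(at$resid %in% c("HOH", "DOD", "WAT"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]

  # Resolve altlocs: within (chain, resno, insert, atom name) keep the highest
  # occupancy; ties go to the record encountered first.
  ins <- ifelse(is.na(at$insert), "", at$insert)
  grp <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(grp, -occ, seq_len(nrow(at)))
  keep2 <- !duplicated(grp[ord])
  sel <- sort(ord[keep2])
  at <- at[sel, , drop = FALSE]
  elesy <- elesy[sel]
  ins <- ins[sel]

  for (ch in c(protein_chain, peptide_chain)) {
    if (!any(at$chain == ch))
      stop_pf("requested chain '%s' not present in PDB input", ch,
              class = "pepforge_missing_chain")
  }
  in_sel <- at$chain %in% c(protein_chain, peptide_chain)
  at <- at[in_sel, , drop = FALSE]
  elesy <- elesy[in_sel]
  ins <- ins[in_sel]

  role <- ifelse(at$chain == protein_chain, "protein", "peptide")
  atoms <- data.frame(
    role = role, chain = at$chain, resno = at$resno, ins = ins,
    resid = at$resid, elety = at$elety, elesy = elesy,
    x = at$x, y = at$y, z = at$z,
    radius = radius_for_element(radii, elesy),
    stringsAsFactors = FALSE)
  # Order residues by (resno, insertion code lexicographic), atoms in file
  # order within a residue.
  atoms <- atoms[order(match(atoms$role, c("protein", "peptide")),
                       atoms$resno, atoms$ins), , drop = FALSE]
  rownames(atoms) <- NULL
  new_complex_structure(atoms, protein_chain, peptide_chain, source_id)
}

#' Serialize a complex back to PDB text
#'
#' Fixed-width ATOM records with 3-decimal coordinates; inverse of
#' [parse_pdb()] up to radii (which are reassigned by element on re-parse).
#'
#' @param complex a `complex_structure`.
#' @param file optional path; when given the text is also written there.
#' @return the PDB text as a single string, invisibly when `file` is given.
#' @export
write_pdb <- function(complex, file = NULL) {
  validate_complex(complex)
  a <- complex$atoms
  if (any(a$resno > 9999))
    stop_pf("residue number %d exceeds the 4-digit PDB field",
            max(a$resno), class = "pepforge_write_error")
  f <- file %||% tempfile(fileext = ".pdb")
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = f, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$elesy)
  txt <- paste(readLines(f), collapse = "\n")
  if (is.null(file)) unlink(f) else return(invisible(txt))
  txt
}

#' Residue records of one chain
#'
#' @param complex a `complex_structure`.
#' @param side `"protein"` or `"peptide"`.
#' @return a list of per-residue atom data frames, in sequence order, named by
#'   residue number (with any insertion code appended).
#' @export
residues <- function(complex, side = c("protein", "peptide")) {
  side <- match.arg(side)
  a <- complex$atoms[complex$atoms$role == side, , drop = FALSE]
  key <- paste0(a$resno, a$ins)
  split(a, factor(key, levels = unique(key)))
}

chain_length <- function(complex, side) length(residues(complex, side))

#' One-letter sequence of a chain
#' @inheritParams residues
#' @return single string; unknown residue names become `X`.
#' @export
chain_sequence <- function(complex, side = c("protein", "peptide")) {
  side <- match.arg(side)
  res <- residues(complex, side)
  three <- vapply(res, function(r) r$resid[1], character(1))
  one <- aa_one_from_three(three)
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Minimum inter-residue atomic distance
#'
#' Minimum Euclidean distance over all heavy-atom pairs of two residues (the
#' proximity measure behind the 5-Angstrom binding-site cutoff). Hydrogens are
#' already excluded at parse time. `method = "calpha"` restricts both residues
#' to their C-alpha atoms.
#'
#' @param a,b per-residue atom data frames as returned by [residues()].
#' @param method `"heavy"` (default) or `"calpha"`.
#' @return distance in Angstrom.
#' @export
min_residue_distance <- function(a, b, method = c("heavy", "calpha")) {
  method <- match.arg(method)
  if (method == "calpha") {
    a <- a[a$elety == "CA", , drop = FALSE]
    b <- b[b$elety == "CA", , drop = FALSE]
  }
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop_pf("residue has no atoms for method '%s'", method,
            class = "pepforge_bad_residue")
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  sqrt(min(sqdist(A, B)))
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure '%s'>\n", x$source_id))
  cat(sprintf("  protein chain %s: %d residues, %d atoms\n", x$protein_chain,
              chain_length(x, "protein"), sum(x$atoms$role == "protein")))
  cat(sprintf("  peptide chain %s: %d residues, %d atoms\n", x$peptide_chain,
              chain_length(x, "peptide"), sum(x$atoms$role == "peptide")))
  invisible(x)
}

# Apply a rigid-body transform (rotation matrix R, translation t) to all atoms.
transform_complex <- function(complex, R = diag(3), t = c(0, 0, 0)) {
  a <- complex$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  complex$atoms <- a
  complex
}
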