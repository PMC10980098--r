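#' Deterministic physicochemical sequence embedding
#'
#' Maps a peptide sequence to a fixed-length continuous vector for the
#' Gaussian-process surrogate. Each residue contributes a 24-dimensional
#' block: four z-scored physicochemical descriptors (Kyte-Doolittle
#' hydropathy, net charge, Zamyatnin volume, polarity) followed by a 20-way
#' one-hot identity. Blocks are concatenated, zero-padded to `max_len`
#' residues, and a normalised length feature is appended, giving dimension
#' `24 * max_len + 1`. The map is deterministic and local: sequences
#' differing at one position differ only in that residue's block (and the
#' length feature if lengths differ).
#'
#' @param seq one-letter amino-acid string (standard 20-letter alphabet).
#' @param max_len maximum peptide length the embedding is padded to.
#' @return numeric vector of length `24 * max_len + 1`.
#' @export
embed_sequence <- function(seq, max_len = 20) {
  chars <- validate_peptide_sequence(seq)
  if (length(chars) > max_len)
    stop_pf("sequence length %d exceeds max_len %d", length(chars), max_len,
            class = "pepforge_bad_sequence")
  desc <- cbind(scale(AA_HYDROPATHY), scale(AA_CHARGE),
                scale(AA_VOLUME), scale(AA_POLAR))
  rownames(desc) <- AA_ALPHABET
  block <- 24L
  out <- numeric(block * max_len + 1L)
  for (i in seq_along(chars)) {
    aa <- chars[i]
    onehot <- as.numeric(AA_ALPHABET == aa)
    out[(i - 1L) * block + seq_len(block)] <- c(desc[aa, ], onehot)
  }
  out[length(out)] <- length(chars) / max_len
  out
}

embed_matrix <- function(seqs, max_len) {
  t(vapply(seqs, embed_sequence, numeric(24L * max_len + 1L),
           max_len = max_len))
}

#' Canonicalise objective values to maximise-all form
#'
#' The optimizer works internally in a maximise-everything convention;
#' objectives declared `"minimize"` are negated on ingest. Applying the map
#' twice returns the original values.
#'
#' @param values numeric vector or matrix (columns = objectives).
#' @param directions character vector of `"maximize"`/`"minimize"`.
#' @export
canonical_objectives <- function(values, directions) {
  if (!all(directions %in% c("maximize", "minimize")))
    stop_pf("directions must be 'maximize' or 'minimize'",
            class = "pepforge_bad_direction")
  sgn <- ifelse(directions == "minimize", -1, 1)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(sgn))
    sweep(values, 2, sgn, "*")
  } else {
    stopifnot(length(values) == length(sgn))
    values * sgn
  }
}
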