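# Seeded random mutagenesis: the source of candidate peptide sequences.

#' Mutate a peptide sequence
#'
#' Substitutes exactly `n_mutations` positions, chosen uniformly without
#' replacement; each substitution is drawn uniformly from the 19 residues
#' different from the current one. Deterministic for a given seed.
#'
#' @param seq one-letter sequence.
#' @param n_mutations number of positions to substitute (0 returns `seq`).
#' @param seed RNG seed (NULL uses the current stream).
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, n_mutations, seed = NULL) {
  chars <- validate_peptide_sequence(seq)
  L <- length(chars)
  if (n_mutations < 0 || n_mutations > L)
    stop_pf("n_mutations must be between 0 and the sequence length (%d)", L,
            class = "pepforge_bad_mutation")
  if (n_mutations == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(L, n_mutations)
    for (p in pos) {
      choices <- setdiff(AA_ALPHABET, chars[p])
      chars[p] <- choices[sample.int(19L, 1L)]
    }
  })
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

#' Seed pool of mutated peptides
#'
#' Draws `n_seeds` unique mutants of the native peptide at the requested
#' Hamming distance (collisions are re-drawn, with a bounded number of
#' retries). The native sequence itself can optionally be included as an
#' extra, already-optimal seed.
#'
#' @param native_peptide one-letter native sequence.
#' @param n_seeds number of unique mutants (>= 1).
#' @param mutations_per_seed Hamming distance of each seed from the native.
#' @param seed RNG seed.
#' @param include_native also include the native sequence.
#' @return a data frame of class `candidate_pool` with columns `sequence`,
#'   `round` (0 for seeds) and `parent`.
#' @export
seed_pool <- function(native_peptide, n_seeds, mutations_per_seed = 2,
                      seed = NULL, include_native = FALSE) {
  chars <- validate_peptide_sequence(native_peptide, "native_peptide")
  stopifnot(n_seeds >= 1)
  L <- length(chars)
  m <- mutations_per_seed
  capacity <- choose(L, m) * 19^m
  if (n_seeds > capacity)
    stop_pf("requested %d unique seeds but only %.0f sequences exist at Hamming distance %d",
            n_seeds, capacity, m, class = "pepforge_pool_exhausted")
  seqs <- character(0)
  with_seed(seed, {
    tries <- 0L
    max_tries <- 200L * n_seeds
    while (length(seqs) < n_seeds && tries < max_tries) {
      s <- mutate_sequence(native_peptide, m)
      if (!(s %in% seqs) && s != native_peptide) seqs <- c(seqs, s)
      tries <- tries + 1L
    }
  })
  if (length(seqs) < n_seeds)
    stop_pf("could not draw %d unique seeds after bounded retries", n_seeds,
            class = "pepforge_pool_exhausted")
  if (include_native) seqs <- c(native_peptide, seqs)
  pool <- data.frame(sequence = seqs, round = 0L, parent = native_peptide,
                     stringsAsFactors = FALSE)
  class(pool) <- c("candidate_pool", "data.frame")
  pool
}
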