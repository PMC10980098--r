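# Amino-acid reference data used by the sequence embedding and by the
# pseudo-side-chain geometry of threaded/synthetic structures.
#
# Volumes are the Zamyatnin (1972) mean residue volumes in cubic Angstroms;
# hydrophobicity is the Kyte-Doolittle scale; charge is the net formal charge
# at pH 7 (His given a fractional +0.1); polarity is a binary polar/apolar flag.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

AA_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

AA_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
               H = 0.1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
               T = 0, W = 0, Y = 0, V = 0)

AA_POLAR <- c(A = 0, R = 1, N = 1, D = 1, C = 0, Q = 1, E = 1, G = 0,
              H = 1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 1,
              T = 1, W = 0, Y = 1, V = 0)

aa_one_from_three <- function(three) {
  m <- names(AA_THREE)[match(toupper(three), AA_THREE)]
  m
}

# Distance from C-alpha to the single pseudo-side-chain atom, and that atom's
# radius, both scaled with residue volume so that sequence changes move the
# structural objectives. The offset constant is chosen so alanine sits near the
# canonical 1.5 A C-alpha -> C-beta bond length.
sidechain_offset <- function(aa) {
  v <- AA_VOLUME[aa]
  unname(0.35 * v^(1 / 3))
}

sidechain_radius <- function(aa) {
  v <- AA_VOLUME[aa]
  unname(0.5 * (3 * v / (4 * pi))^(1 / 3))
}

validate_peptide_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_pf("%s must be a non-empty single string", what,
            class = "pepforge_bad_sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad))
    stop_pf("invalid amino-acid character '%s' at position %d of %s",
            chars[bad[1]], bad[1], what, class = "pepforge_bad_sequence")
  chars
}
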