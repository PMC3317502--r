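# Shared constants and small helpers used across the pipeline stages.

# The twenty standard amino acids, in the fixed order used by every
# position-specific scoring matrix in the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale (Kyte & Doolittle 1982, J Mol Biol 157).
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# One fixed codon per amino acid for deterministic back-translation of
# synthetic proteins. Codon usage is irrelevant downstream of ORF finding,
# so a single canonical codon keeps fixtures byte-reproducible.
BACKTRANSLATION_CODON <- c(
  A = "GCT", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
  G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
  M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
  S = "TCC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC"
)
STOP_CODON <- "TAA"

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after seeding R's RNG with `seed`, then restores the
#' caller's RNG state, so seeded operations never perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Derive a per-stage sub-seed from a run seed. The modulus keeps every
# derived seed within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

paste_chars <- function(x) paste(x, collapse = "")

#' Reverse-complement a DNA string
#' @param x DNA character scalar (A/C/G/T/N).
#' @return Reverse-complemented character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string to protein
#'
#' Thin wrapper over [Biostrings::translate()]; codons containing ambiguity
#' characters (N) translate to `X`.
#'
#' @param x DNA character scalar whose length is a multiple of 3.
#' @return Amino-acid character scalar.
#' @keywords internal
translate_dna <- function(x) {
  if (nchar(x) %% 3L != 0L) stop("sequence length not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# Back-translate a protein with the fixed codon table, appending a stop.
backtranslate <- function(protein) {
  aa <- split_chars(protein)
  bad <- setdiff(aa, names(BACKTRANSLATION_CODON))
  if (length(bad) > 0L) {
    stop("cannot back-translate residues: ", paste(unique(bad), collapse = ", "))
  }
  paste0(paste(BACKTRANSLATION_CODON[aa], collapse = ""), STOP_CODON)
}

# Mutate a protein: each site substituted with probability `rate` to a
# uniformly drawn different residue. Uses the current RNG stream.
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- split_chars(protein)
  hit <- stats::runif(length(aa)) < rate
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1L)
    }, character(1L))
  }
  paste_chars(aa)
}

# Fraction of differing sites between two equal-length residue strings.
diff_fraction <- function(a, b) {
  ca <- split_chars(a)
  cb <- split_chars(b)
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
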