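#' Standard genetic code (DNA alphabet)
#'
#' Named character vector mapping each of the 64 DNA codons to its
#' one-letter amino-acid code, with stop codons rendered as `"*"`.
#' RNA codons (containing `U`) are deliberately not accepted anywhere in
#' the package; all sequences are handled in the DNA alphabet.
#'
#' @format Named character vector of length 64.
#' @export
genetic_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Most frequent human codon per amino acid; used when back-translating
# designed peptides (the assay is agnostic to synonymous choice).
preferred_codon <- c(
  A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
  Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
  L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG"
)

#' One-letter codes of the 20 standard amino acids
#' @export
standard_aa <- sort(unique(unname(genetic_code[genetic_code != "*"])))

split_codons <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate DNA in frame 0 under the standard genetic code
#'
#' @param nt Character vector of DNA sequences (A/C/G/T only), each with
#'   length divisible by 3.
#' @return Character vector of peptides; stop codons appear as `"*"`.
#' @examples
#' translate_dna("AAAGTG")
#' @export
translate_dna <- function(nt) {
  vapply(nt, function(x) {
    codons <- split_codons(toupper(x))
    aa <- genetic_code[codons]
    if (anyNA(aa)) {
      bad <- codons[is.na(aa)]
      stop("invalid codon(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Back-translate a peptide using the most frequent human codons
#'
#' @param peptide Character vector of peptides over the 20 standard
#'   amino acids.
#' @return Character vector of DNA sequences.
#' @export
backtranslate_peptide <- function(peptide) {
  vapply(peptide, function(p) {
    aa <- strsplit(toupper(p), "")[[1]]
    codons <- preferred_codon[aa]
    if (anyNA(codons)) {
      bad <- unique(aa[is.na(codons)])
      stop("non-standard amino acid(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    paste(codons, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings; substitutions only.
hamming <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}
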