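# Reporter insert library design.
#
# The main pool tiles every ordered codon pair (6 nt) as an 8x tandem
# repeat, giving a 48-nt insert encoding a 16-residue dipeptide repeat.
# Variant pools shorten the repeat (padding with a Ser-Gly linker),
# alter the repeat periodicity at fixed amino-acid composition, or
# combine two dipeptides into 4-residue units repeated 4x.

DNA_BASES <- c("A", "C", "G", "T")

#' Enumerate the full dicodon-repeat library
#'
#' One insert per ordered codon pair (64 x 64 = 4096), in lexicographic
#' order. Each insert is the codon pair repeated `n_repeats` times
#' (default 8, i.e. 48 nt) and carries its frame-0 translation with stop
#' codons rendered as `"*"`.
#'
#' @param n_repeats Tandem repeat count of the codon pair.
#' @return A tibble with columns `insert_id`, `codon1`, `codon2`,
#'   `n_repeats`, `nt_seq`, `peptide`.
#' @examples
#' lib <- enumerate_codon_pairs()
#' nrow(lib)  # 4096
#' @export
enumerate_codon_pairs <- function(n_repeats = 8L) {
  stopifnot(n_repeats >= 1L)
  codons <- sort(names(genetic_code))
  grid <- expand.grid(codon2 = codons, codon1 = codons,
                      stringsAsFactors = FALSE)[, c("codon1", "codon2")]
  unit <- paste0(grid$codon1, grid$codon2)
  nt <- strrep(unit, n_repeats)
  tibble::tibble(
    insert_id = paste0(grid$codon1, "_", grid$codon2),
    codon1 = grid$codon1,
    codon2 = grid$codon2,
    n_repeats = as.integer(n_repeats),
    nt_seq = nt,
    peptide = strrep(paste0(genetic_code[grid$codon1],
                            genetic_code[grid$codon2]), n_repeats)
  )
}

#' Frameshift partner of a codon pair
#'
#' The codon pair whose frame-0 repeat peptide equals the peptide read
#' from a shifted frame of the infinite dicodon repeat: the 6-mer
#' `codon1 + codon2` rotated left by `shift` nucleotides and re-split
#' into two codons. A shift of 3 swaps the codons; a shift of 0 is the
#' identity.
#'
#' @param codon1,codon2 Character vectors of 3-nt codons (recycled).
#' @param shift Integer in 0..3 (scalar).
#' @return A tibble with columns `codon1`, `codon2` of the partner pairs.
#' @examples
#' frameshift_partner("GTG", "AAA", 1)  # TGA / AAG
#' @export
frameshift_partner <- function(codon1, codon2, shift) {
  stopifnot(length(shift) == 1L, shift %in% 0:3)
  hexamer <- paste0(codon1, codon2)
  if (shift > 0L) {
    hexamer <- paste0(substring(hexamer, shift + 1L, 6L),
                      substring(hexamer, 1L, shift))
  }
  tibble::tibble(codon1 = substring(hexamer, 1L, 3L),
                 codon2 = substring(hexamer, 4L, 6L))
}

# Peptide of one periodicity block pattern: b copies of the dipeptide
# followed by b copies of its reversal, tiled to `len` residues.
periodicity_peptide <- function(dipeptide, block, len = 16L) {
  fwd <- strsplit(dipeptide, "")[[1]]
  rev_dp <- paste(rev(fwd), collapse = "")
  unit <- paste0(strrep(dipeptide, block), strrep(rev_dp, block))
  full <- strrep(unit, ceiling(len / nchar(unit)))
  substring(full, 1L, len)
}

#' Build a designed variant series for a dipeptide
#'
#' Three designs mirroring the variant reporter pools:
#' * `length_series`: 1-8 tandem dipeptide repeats, padded 3' with a
#'   Ser-Gly linker (codons `AGCGGT`) to a constant 48 nt;
#' * `periodicity`: block sizes 1, 2 and 4 interspersing the dipeptide
#'   with its reversal, plus the pure 8x repeat, all with the amino-acid
#'   composition of the pure repeat;
#' * `combination`: every distinct 4-residue unit formed by permuting
#'   the residues of two dipeptides, repeated 4x (e.g. `SVKF` repeated
#'   four times from VK + SF).
#'
#' Designed peptides are back-translated with the most frequent human
#' codon per amino acid.
#'
#' @param dipeptide 2-letter amino-acid string.
#' @param design One of `"length_series"`, `"periodicity"`,
#'   `"combination"`.
#' @param partner Second dipeptide, required for `design = "combination"`.
#' @return A tibble with columns `insert_id`, `base_dipeptide`, `design`,
#'   `design_param`, `nt_seq`, `peptide`.
#' @export
build_variant_series <- function(dipeptide,
                                 design = c("length_series", "periodicity",
                                            "combination"),
                                 partner = NULL) {
  design <- match.arg(design)
  dipeptide <- toupper(dipeptide)
  aa <- strsplit(dipeptide, "")[[1]]
  if (nchar(dipeptide) != 2L || !all(aa %in% standard_aa)) {
    stop("dipeptide must be two standard amino acids", call. = FALSE)
  }
  if (design == "length_series") {
    n <- 1:8
    peptides <- vapply(n, function(k) {
      paste0(strrep(dipeptide, k), strrep("SG", 8L - k))
    }, character(1))
    nt <- vapply(seq_along(n), function(i) {
      paste0(strrep(backtranslate_peptide(dipeptide), n[i]),
             strrep("AGCGGT", 8L - n[i]))
    }, character(1))
    params <- n
  } else if (design == "periodicity") {
    blocks <- c(1L, 2L, 4L, 8L)  # block 8 is the pure repeat
    peptides <- vapply(blocks, function(b) {
      if (b == 8L) strrep(dipeptide, 8L) else periodicity_peptide(dipeptide, b)
    }, character(1))
    nt <- backtranslate_peptide(peptides)
    params <- blocks
  } else {
    if (is.null(partner)) {
      stop("design = \"combination\" requires a partner dipeptide",
           call. = FALSE)
    }
    partner <- toupper(partner)
    paa <- strsplit(partner, "")[[1]]
    if (nchar(partner) != 2L || !all(paa %in% standard_aa)) {
      stop("partner must be two standard amino acids", call. = FALSE)
    }
    pool <- c(aa, paa)
    perms <- expand.grid(1:4, 1:4, 1:4, 1:4)
    keep <- apply(perms, 1L, function(p) all(sort(p) == 1:4))
    units <- unique(apply(perms[keep, ], 1L, function(p) {
      paste(pool[p], collapse = "")
    }))
    units <- sort(units)
    peptides <- strrep(units, 4L)
    nt <- backtranslate_peptide(peptides)
    params <- seq_along(units)
  }
  out <- tibble::tibble(
    insert_id = paste0(dipeptide,
                       if (design == "combination") paste0(partner) else "",
                       "_", design, "_", params),
    base_dipeptide = dipeptide,
    design = design,
    design_param = as.integer(params),
    nt_seq = nt,
    peptide = peptides
  )
  stopifnot(all(nchar(out$nt_seq) == 48L))
  out
}

#' Generate random VNN barcodes
#'
#' 24-nt barcodes built from 8 tandem VNN codons (V = A, C or G), a
#' design that excludes in-frame stop codons by construction (all three
#' stop codons begin with T). Draws are uniform over the 48^8 valid
#' barcodes; returned barcodes are distinct.
#'
#' @param n Number of barcodes.
#' @return Character vector of `n` distinct 24-nt barcodes.
#' @export
generate_barcode <- function(n = 1L) {
  draw <- function(k) {
    v <- sample(c("A", "C", "G"), 8L * k, replace = TRUE)
    n1 <- sample(DNA_BASES, 8L * k, replace = TRUE)
    n2 <- sample(DNA_BASES, 8L * k, replace = TRUE)
    codons <- paste0(v, n1, n2)
    apply(matrix(codons, nrow = 8L), 2L, paste, collapse = "")
  }
  bc <- unique(draw(n))
  while (length(bc) < n) {
    bc <- unique(c(bc, draw(n - length(bc))))
  }
  bc[seq_len(n)]
}

#' Write a reporter library as FASTA
#'
#' Record ids are insert ids; sequences are the 48-nt inserts.
#'
#' @param library Tibble with `insert_id` and `nt_seq` columns.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library$nt_seq)
  names(seqs) <- library$insert_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a reporter library manifest as TSV
#'
#' @param library Library tibble (any design).
#' @param path Output TSV path.
#' @export
write_library_manifest <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
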