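# Physicochemical scales of the 20 standard amino acids.
#
# pI: isoelectric point of the free amino acid (pH units) and
# bulkiness: ratio of side-chain volume to length (A^2), both from the
# Zimmerman scale. cf_helix / cf_strand: Chou-Fasman conformational
# propensities (dimensionless). A second, independent transcription of
# the same tables lives in inst/extdata/aa_scales.tsv and is compared
# against this one in the test suite.
.aa_scales_tbl <- local({
  tbl <- data.frame(
    aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    pI = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59, 6.02,
           5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89, 5.66, 5.96),
    bulkiness = c(11.50, 14.28, 12.82, 11.68, 13.46, 14.45, 13.57, 3.40,
                  13.69, 21.40, 21.40, 15.71, 16.25, 19.80, 17.43, 9.47,
                  15.77, 21.67, 18.03, 21.57),
    cf_helix = c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00,
                 1.08, 1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08,
                 0.69, 1.06),
    cf_strand = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87,
                  1.60, 1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37,
                  1.47, 1.70),
    stringsAsFactors = FALSE
  )
  tbl[order(tbl$aa), ]
})

#' Amino-acid physicochemical scales
#'
#' Per-residue isoelectric point (pI), bulkiness (side-chain
#' volume/length ratio, in square Angstroms), and Chou-Fasman alpha-helix
#' and beta-strand propensities for the 20 standard amino acids.
#'
#' @return A tibble with columns `aa`, `pI`, `bulkiness`, `cf_helix`,
#'   `cf_strand`, one row per amino acid, ordered alphabetically.
#' @examples
#' aa_scales()
#' @export
aa_scales <- function() {
  tibble::as_tibble(.aa_scales_tbl)
}

scale_lookup <- function(scale = c("pI", "bulkiness", "cf_helix", "cf_strand")) {
  scale <- match.arg(scale)
  stats::setNames(.aa_scales_tbl[[scale]], .aa_scales_tbl$aa)
}

#' Mean scale value of a peptide
#'
#' Arithmetic mean of per-residue values of one physicochemical scale
#' over a peptide.
#'
#' @param peptide Character vector of peptides (standard amino acids only).
#' @param scale One of `"pI"`, `"bulkiness"`, `"cf_helix"`, `"cf_strand"`.
#' @return Numeric vector of means, one per input peptide.
#' @examples
#' mean_scale("VK", "pI")
#' @export
mean_scale <- function(peptide, scale = c("pI", "bulkiness", "cf_helix", "cf_strand")) {
  scale <- match.arg(scale)
  lut <- scale_lookup(scale)
  vapply(peptide, function(p) {
    if (is.na(p) || !nzchar(p)) stop("peptide must be non-empty", call. = FALSE)
    aa <- strsplit(toupper(p), "")[[1]]
    v <- lut[aa]
    if (anyNA(v)) {
      bad <- unique(aa[is.na(v)])
      stop("non-standard residue(s) in peptide: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mean(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bulky amino acids
#'
#' Residues whose Zimmerman bulkiness (side-chain volume/length) exceeds
#' a threshold; the conventional cutoff of 18 A^2 selects I, L, F, W, Y,
#' and V.
#'
#' @param threshold Bulkiness cutoff; strictly exceeded.
#' @return Character vector of one-letter codes.
#' @export
bulky_amino_acids <- function(threshold = 18) {
  tbl <- .aa_scales_tbl
  sort(tbl$aa[tbl$bulkiness > threshold])
}

#' Construct a per-residue secondary-structure profile
#'
#' Holds three-state (helix/strand/coil) per-residue probabilities for a
#' peptide, as produced by sequence-based secondary-structure predictors.
#' Two-state input (helix and strand only) is accepted; the remainder is
#' assigned to coil.
#'
#' @param peptide Amino-acid string.
#' @param p_helix,p_strand Numeric vectors of per-residue probabilities,
#'   same length as the peptide.
#' @param p_coil Optional; defaults to `1 - p_helix - p_strand`.
#' @param tol Tolerance on the per-residue sum-to-one check.
#' @return An object of class `structure_profile`.
#' @export
structure_profile <- function(peptide, p_helix, p_strand, p_coil = NULL,
                              tol = 1e-6) {
  n <- nchar(peptide)
  if (length(p_helix) != n || length(p_strand) != n) {
    stop("probability vectors must have one entry per residue", call. = FALSE)
  }
  if (is.null(p_coil)) p_coil <- 1 - p_helix - p_strand
  if (length(p_coil) != n) {
    stop("p_coil must have one entry per residue", call. = FALSE)
  }
  probs <- cbind(p_helix, p_strand, p_coil)
  if (any(probs < -tol) || any(probs > 1 + tol)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(probs) - 1) > tol)) {
    stop("per-residue probabilities must sum to 1", call. = FALSE)
  }
  structure(
    list(peptide = peptide, p_helix = as.numeric(p_helix),
         p_strand = as.numeric(p_strand), p_coil = as.numeric(p_coil)),
    class = "structure_profile"
  )
}

#' @export
print.structure_profile <- function(x, ...) {
  cat("<structure_profile> ", x$peptide, "\n",
      "  mean p_helix = ", signif(mean(x$p_helix), 3),
      ", mean p_strand = ", signif(mean(x$p_strand), 3), "\n", sep = "")
  invisible(x)
}

#' Read a per-residue structure profile from TSV
#'
#' Expects columns `position`, `residue`, `p_helix`, `p_strand` and
#' optionally `p_coil` (assigned the remainder when absent), i.e. the
#' tabular output of an external secondary-structure predictor.
#'
#' @param path Path to a tab-separated file.
#' @return A `structure_profile`.
#' @export
read_structure_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "residue", "p_helix", "p_strand")
  if (!all(need %in% names(df))) {
    stop("profile TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$position), ]
  structure_profile(
    peptide = paste(df$residue, collapse = ""),
    p_helix = df$p_helix, p_strand = df$p_strand,
    p_coil = if ("p_coil" %in% names(df)) df$p_coil else NULL
  )
}

#' Classify a peptide's predicted secondary structure
#'
#' A peptide is called `helix` (or `strand`) when its mean per-residue
#' helix (or strand) probability strictly exceeds 0.5; everything else is
#' `other`. Given per-residue normalization the two calls are mutually
#' exclusive.
#'
#' @param profile A `structure_profile`.
#' @return One of `"helix"`, `"strand"`, `"other"`.
#' @export
classify_structure <- function(profile) {
  stopifnot(inherits(profile, "structure_profile"))
  if (mean(profile$p_helix) > 0.5) return("helix")
  if (mean(profile$p_strand) > 0.5) return("strand")
  "other"
}
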