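# Destabilizing-dipeptide scoring and proteome-wide window scan.
#
# A dipeptide scores when a positively charged residue (K or R) is
# adjacent to a bulky one (L, V, I, Y or F), in either order; pairs
# within one set (K-R, L-V, ...) score nothing. Overlapping scoring
# dipeptides earn a bonus. The per-CDS motif is the 16-residue window
# with the maximum score.

CHARGED_SET <- c("K", "R")
BULKY_SCAN_SET <- c("L", "V", "I", "Y", "F")

# Indicator of scoring dipeptides at positions (i, i+1) of a peptide,
# as a logical vector of length nchar - 1.
destabilizing_dipeptides <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(logical(0))
  a <- aa[-n]; b <- aa[-1L]
  (a %in% CHARGED_SET & b %in% BULKY_SCAN_SET) |
    (a %in% BULKY_SCAN_SET & b %in% CHARGED_SET)
}

#' Destabilization score of a peptide window
#'
#' Each adjacent charged-bulky dipeptide (K/R next to L/V/I/Y/F, either
#' order) scores 1; overlapping scoring dipeptides earn a bonus. Under
#' the default `overlap = "pair"` mode each adjacent overlapping pair
#' adds 1 (a run of L consecutive scoring dipeptides contributes
#' L + (L - 1)); under `overlap = "run"` each maximal run of two or
#' more scoring dipeptides adds a single 1.
#'
#' @param window Character vector of peptides (standard amino acids
#'   only).
#' @param overlap Overlap-bonus mode, `"pair"` (default) or `"run"`.
#' @return Integer vector of scores.
#' @examples
#' peptide_score("KV")            # 1
#' peptide_score("VKV")           # 3
#' peptide_score(strrep("VK", 8)) # 29
#' @export
peptide_score <- function(window, overlap = c("pair", "run")) {
  overlap <- match.arg(overlap)
  vapply(window, function(w) {
    aa <- strsplit(w, "")[[1]]
    if (!all(aa %in% standard_aa)) {
      bad <- unique(aa[!aa %in% standard_aa])
      stop("non-standard residue(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    d <- destabilizing_dipeptides(w)
    base <- sum(d)
    bonus <- if (length(d) >= 2L) {
      both <- d[-length(d)] & d[-1L]
      if (overlap == "pair") {
        sum(both)
      } else {
        # number of maximal runs of >= 2 consecutive scoring dipeptides
        r <- rle(d)
        sum(r$values & r$lengths >= 2L)
      }
    } else 0L
    as.integer(base + bonus)
  }, integer(1), USE.NAMES = FALSE)
}

# Window scores along one peptide via cumulative sums; returns integer
# vector over start positions 1..(n - window + 1).
window_scores <- function(peptide, window = 16L, overlap = "pair") {
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  d <- destabilizing_dipeptides(peptide)
  if (overlap == "pair") {
    o <- if (length(d) >= 2L) as.integer(d[-length(d)] & d[-1L]) else integer(0)
    cs_d <- c(0L, cumsum(as.integer(d)))
    cs_o <- c(0L, cumsum(o))
    starts <- seq_len(n - window + 1L)
    # window [p, p + window - 1] spans dipeptides p..p+window-2 and
    # overlaps p..p+window-3
    cs_d[starts + window - 1L] - cs_d[starts] +
      cs_o[pmin(starts + window - 2L, length(cs_o))] - cs_o[starts]
  } else {
    starts <- seq_len(n - window + 1L)
    vapply(starts, function(p) {
      peptide_score(substring(peptide, p, p + window - 1L), overlap = "run")
    }, integer(1))
  }
}

#' Scan protein sequences for maximal destabilizing windows
#'
#' For each sequence, finds the `window`-residue stretch with the
#' maximum destabilization score (leftmost on ties) and classifies it
#' as `destabilizing` (score > 9), `control` (score < 3) or `neither`.
#' Terminal stop symbols are stripped; sequences shorter than the
#' window are skipped and counted. Nucleotide input (A/C/G/T only,
#' length divisible by 3) is translated first.
#'
#' @param sequences Named character vector of protein (or CDS) strings,
#'   an `AAStringSet`, or a FASTA path.
#' @param window Window width in residues (default 16).
#' @param overlap Overlap-bonus mode passed to [peptide_score()].
#' @return Tibble with `gene_id`, `window_start` (1-based inclusive),
#'   `window_seq`, `score`, `class`; attribute `skipped` counts
#'   too-short sequences.
#' @export
scan_proteome <- function(sequences, window = 16L,
                          overlap = c("pair", "run")) {
  overlap <- match.arg(overlap)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    ss <- Biostrings::readBStringSet(sequences)
    sequences <- stats::setNames(as.character(ss), names(ss))
  } else if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) stop("no sequences supplied", call. = FALSE)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(sequences)
  is_nt <- !grepl("[^ACGT]", sequences) & nchar(sequences) %% 3L == 0L &
    nchar(sequences) >= 3L
  sequences[is_nt] <- translate_dna(sequences[is_nt])
  sequences <- sub("\\*+$", "", sequences)
  skipped <- 0L
  rows <- lapply(names(sequences), function(id) {
    p <- sequences[[id]]
    if (nchar(p) < window) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    sc <- window_scores(p, window, overlap)
    best <- which.max(sc)  # leftmost maximum
    tibble::tibble(gene_id = id, window_start = as.integer(best),
                   window_seq = substring(p, best, best + window - 1L),
                   score = sc[best])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all sequences shorter than the window",
                         call. = FALSE)
  out$class <- ifelse(out$score > 9L, "destabilizing",
                      ifelse(out$score < 3L, "control", "neither"))
  attr(out, "skipped") <- skipped
  out
}

#' Design the amino-acid-reordering mutant of a motif
#'
#' Disrupts charged-bulky dipeptides without changing amino-acid (or
#' codon) composition: all codons encoding K or R move to the 5' end,
#' all codons encoding L, V, I, Y or F move to the 3' end, and the
#' remaining codons stay in the middle, each block preserving its
#' internal order (a stable three-way partition).
#'
#' @param codons Character vector of 3-nt codons, or a single
#'   nucleotide string with length divisible by 3.
#' @return List of class `reordered_mutant` with `wt_codons`,
#'   `mut_codons`, `peptide_wt`, `peptide_mut`.
#' @examples
#' design_reordered_mutant(c("GCC", "AAG", "GTG", "AGA", "TTC", "AGC"))
#' @export
design_reordered_mutant <- function(codons) {
  if (length(codons) == 1L && nchar(codons) > 3L) {
    codons <- split_codons(codons)
  }
  codons <- toupper(codons)
  aa <- genetic_code[codons]
  if (anyNA(aa)) stop("invalid codon(s) in input", call. = FALSE)
  if (any(aa == "*")) stop("stop codon in motif", call. = FALSE)
  charged <- aa %in% CHARGED_SET
  bulky <- aa %in% BULKY_SCAN_SET
  mut <- c(codons[charged], codons[!charged & !bulky], codons[bulky])
  structure(
    list(wt_codons = unname(codons), mut_codons = unname(mut),
         peptide_wt = paste(aa, collapse = ""),
         peptide_mut = paste(genetic_code[mut], collapse = "")),
    class = "reordered_mutant"
  )
}

#' @export
print.reordered_mutant <- function(x, ...) {
  cat("<reordered_mutant>\n  wt : ", x$peptide_wt,
      "\n  mut: ", x$peptide_mut, "\n", sep = "")
  invisible(x)
}

#' Write a proteome scan result as TSV
#'
#' @param scan Tibble from [scan_proteome()].
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
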