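# Independent oracles used to verify package operations. These are
# deliberately naive (loops, brute force) and share no code with the
# implementation.

# Translation oracle driven by the Biostrings genetic-code table
# (which is keyed by DNA codons).
oracle_translate <- function(nt) {
  vapply(nt, function(x) {
    x <- toupper(x)
    codons <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_is_destab_pair <- function(a, b) {
  charged <- c("K", "R"); bulky <- c("L", "V", "I", "Y", "F")
  (a %in% charged && b %in% bulky) || (a %in% bulky && b %in% charged)
}

# Brute-force destabilization score: explicit loops over dipeptides and
# overlapping pairs.
oracle_score <- function(window, overlap = "pair") {
  aa <- strsplit(window, "")[[1]]
  n <- length(aa)
  d <- logical(max(n - 1, 0))
  for (i in seq_len(n - 1)) d[i] <- oracle_is_destab_pair(aa[i], aa[i + 1])
  score <- sum(d)
  if (overlap == "pair") {
    for (i in seq_len(n - 2)) if (d[i] && d[i + 1]) score <- score + 1
  } else if (n >= 3) {
    in_run <- FALSE
    for (i in seq_len(n - 2)) {
      if (d[i] && d[i + 1]) {
        if (!in_run) score <- score + 1
        in_run <- TRUE
      } else if (!d[i + 1]) {
        in_run <- FALSE
      }
    }
  }
  as.integer(score)
}

# Brute-force max-window scan of a single protein.
oracle_scan_one <- function(protein, window = 16) {
  n <- nchar(protein)
  best_score <- -1L; best_start <- NA_integer_
  for (p in seq_len(n - window + 1)) {
    s <- oracle_score(substr(protein, p, p + window - 1))
    if (s > best_score) {
      best_score <- s; best_start <- p
    }
  }
  list(start = best_start, score = best_score)
}

# Brute-force Hamming nearest-insert matcher with the uniqueness rule.
oracle_match <- function(region, library, m = 2) {
  d <- vapply(library$nt_seq, function(s) {
    sum(strsplit(region, "")[[1]] != strsplit(s, "")[[1]])
  }, numeric(1))
  ok <- d <= m
  if (!any(ok)) return(NA_character_)
  dmin <- min(d[ok])
  hits <- library$insert_id[ok & d == dmin]
  if (length(hits) == 1) hits else NA_character_
}

# Exact bootstrap distribution for two barcodes: the three distinct
# resample multisets {AA}, {AB}, {BB} with weights 1/4, 1/2, 1/4.
oracle_boot_sd_2 <- function(m, g) {
  vals <- c(log2(2 * m[1] / (2 * g[1])),
            log2((m[1] + m[2]) / (g[1] + g[2])),
            log2(2 * m[2] / (2 * g[2])))
  w <- c(0.25, 0.5, 0.25)
  mu <- sum(w * vals)
  sqrt(sum(w * (vals - mu)^2))
}

random_peptides <- function(n, len, alphabet = stallmpra::standard_aa) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

small_library <- function(n = 40, seed = 99) {
  set.seed(seed)
  lib <- enumerate_codon_pairs()
  lib[sample.int(nrow(lib), n), ]
}
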