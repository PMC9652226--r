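# Synthetic-data generator.
#
# Every sequencing input the pipeline consumes can be produced here
# under an explicit generative model, together with ground-truth sidecar
# tables, so the downstream stages are testable end to end without any
# external data. Insert-level log2 mRNA effects are generated from the
# dipeptide's physicochemical features (mean pI, mean bulkiness, their
# interaction, and mean beta-strand propensity), counts follow a
# Dirichlet-multinomial law, and reads carry uniform substitution
# errors.

#' Generative model for insert-level mRNA effects
#'
#' The true log2 mRNA level of an insert is a linear function of its
#' dipeptide's mean isoelectric point, mean bulkiness, their product,
#' and mean Chou-Fasman beta-strand propensity, plus a fixed penalty for
#' stop-containing inserts and Gaussian noise. The default coefficients
#' are 0.31 (pI), 0.20 (bulkiness), -0.03 (interaction) and -0.52
#' (strand propensity) on the log2 scale.
#'
#' @param beta_pI,beta_bulk,beta_inter,beta_strand Regression
#'   coefficients (log2 units per feature unit).
#' @param noise_sd Insert-level Gaussian noise SD (log2 units).
#' @param stop_penalty Additive log2 penalty for inserts whose peptide
#'   contains a stop, mimicking nonsense-mediated decay.
#' @param term_prob_stop,term_prob_base Premature-termination
#'   probabilities for stop-containing and stop-free inserts (used by
#'   the sorting simulator).
#' @param halflife_base Baseline mRNA half-life in hours; an insert's
#'   half-life scales as `halflife_base * 2^(level/2)` so destabilized
#'   inserts also decay faster.
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(beta_pI = 0.31, beta_bulk = 0.20,
                             beta_inter = -0.03, beta_strand = -0.52,
                             noise_sd = 0.3, stop_penalty = -2.0,
                             term_prob_stop = 0.8, term_prob_base = 0.05,
                             halflife_base = 4) {
  stopifnot(noise_sd >= 0, halflife_base > 0,
            term_prob_stop >= 0, term_prob_stop <= 1,
            term_prob_base >= 0, term_prob_base <= 1)
  structure(
    list(beta_pI = beta_pI, beta_bulk = beta_bulk, beta_inter = beta_inter,
         beta_strand = beta_strand, noise_sd = noise_sd,
         stop_penalty = stop_penalty, term_prob_stop = term_prob_stop,
         term_prob_base = term_prob_base, halflife_base = halflife_base),
    class = "generative_model"
  )
}

# Mean scale value over the standard residues of the encoded dipeptide;
# stop symbols are excluded from the mean (stop effects enter through
# the explicit stop penalty). Returns 0 when no standard residue exists
# (the double-stop dipeptide).
dipeptide_feature <- function(peptide, scale) {
  lut <- scale_lookup(scale)
  vapply(substring(peptide, 1L, 2L), function(dp) {
    aa <- strsplit(dp, "")[[1]]
    v <- lut[aa[aa != "*"]]
    if (length(v) == 0L) 0 else mean(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Simulate true insert-level log2 mRNA effects
#'
#' @param library Library tibble with `insert_id` and `peptide`.
#' @param model A [generative_model()].
#' @param seed Optional integer seed for the noise draw.
#' @return A tibble with `insert_id`, the dipeptide features, and
#'   `true_level` (log2 units).
#' @export
simulate_true_levels <- function(library, model = generative_model(),
                                 seed = NULL) {
  stopifnot(inherits(model, "generative_model"))
  if (!is.null(seed)) set.seed(seed)
  pI <- dipeptide_feature(library$peptide, "pI")
  bulk <- dipeptide_feature(library$peptide, "bulkiness")
  strand <- dipeptide_feature(library$peptide, "cf_strand")
  has_stop <- grepl("*", library$peptide, fixed = TRUE)
  level <- model$beta_pI * pI + model$beta_bulk * bulk +
    model$beta_inter * pI * bulk + model$beta_strand * strand +
    model$stop_penalty * has_stop +
    stats::rnorm(nrow(library), 0, model$noise_sd)
  tibble::tibble(insert_id = library$insert_id, mean_pI = pI,
                 mean_bulkiness = bulk, mean_cf_strand = strand,
                 has_stop = has_stop, true_level = level)
}

# Truncated-geometric barcode-per-insert counts with median 15, min 1.
# P(N >= k) = q^(k-1) with q chosen so the median is exactly 15.
rbarcodes_per_insert <- function(n, median_target = 15L) {
  q <- 0.5^(1 / (median_target - 0.3))
  pmax(1L, stats::rgeom(n, prob = 1 - q) + 1L)
}

default_layout <- function() {
  list(insert_start = 1L, insert_len = 48L,
       barcode_start = 49L, barcode_len = 24L)
}

read_set <- function(reads, sample_id, layout, truth = NULL) {
  structure(list(reads = reads, sample_id = sample_id, layout = layout,
                 truth = truth),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> sample ", x$sample_id, ": ", length(x$reads),
      " reads of width ", if (length(x$reads)) nchar(x$reads[1]) else 0,
      "\n", sep = "")
  invisible(x)
}

# Apply uniform per-base substitution errors to a character vector of
# equal-length reads.
add_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  width <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), width, error_rate)
  idx <- which(n_err > 0L)
  if (length(idx) == 0L) return(reads)
  mat <- matrix(unlist(strsplit(reads[idx], ""), use.names = FALSE),
                nrow = length(idx), byrow = TRUE)
  total <- sum(n_err[idx])
  rows <- rep.int(seq_along(idx), n_err[idx])
  cols <- unlist(lapply(n_err[idx], function(k) sample.int(width, k)))
  pos <- cbind(rows, cols)
  old <- mat[pos]
  # substitute with a uniformly chosen different base
  repl <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L),
                 character(1), USE.NAMES = FALSE)
  mat[pos] <- repl
  reads[idx] <- apply(mat, 1L, paste, collapse = "")
  reads
}

#' Simulate insert-barcode linkage reads
#'
#' Each insert receives a number of distinct random VNN barcodes drawn
#' from a truncated geometric distribution with median
#' `median_barcodes`; reads cover the insert followed by its barcode at
#' fixed offsets, with uniform per-base substitution errors. The
#' ground-truth barcode-to-insert table is attached as `$truth`.
#'
#' @param library Library tibble (`insert_id`, `nt_seq`).
#' @param depth Total number of linkage reads (allocated uniformly over
#'   barcodes via multinomial sampling).
#' @param median_barcodes Target median barcodes per insert.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @return A `read_set` with `layout` describing the insert and barcode
#'   offsets and `truth` a tibble (`barcode`, `insert_id`).
#' @export
simulate_linkage_reads <- function(library, depth = 20L * 15L * nrow(library),
                                   median_barcodes = 15L, error_rate = 0.001,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_bc <- rbarcodes_per_insert(nrow(library), median_barcodes)
  barcodes <- generate_barcode(sum(n_bc))
  truth <- tibble::tibble(
    barcode = barcodes,
    insert_id = rep(library$insert_id, n_bc)
  )
  insert_seq <- rep(library$nt_seq, n_bc)
  counts <- as.integer(stats::rmultinom(1L, depth,
                                        rep(1, length(barcodes))))
  reads <- paste0(rep(insert_seq, counts), rep(barcodes, counts))
  reads <- add_substitution_errors(reads, error_rate)
  read_set(reads, "linkage", default_layout(), truth = truth)
}

# Dirichlet weights with common concentration 1/dispersion; dispersion
# 0 gives exactly equal weights.
dirichlet_weights <- function(n, dispersion) {
  if (dispersion <= 0) return(rep(1 / n, n))
  g <- stats::rgamma(n, shape = 1 / dispersion, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

barcode_read_set <- function(barcodes, counts, sample_id, error_rate = 0) {
  reads <- rep(barcodes, counts)
  reads <- add_substitution_errors(reads, error_rate)
  layout <- list(insert_start = NA_integer_, insert_len = NA_integer_,
                 barcode_start = 1L, barcode_len = nchar(barcodes[1]))
  read_set(reads, sample_id, layout)
}

#' Simulate genomic-DNA and mRNA barcode-count reads
#'
#' Genomic-DNA barcode abundances are drawn Dirichlet-multinomial around
#' equal representation (integration-site and amplification
#' variability); mRNA abundances are proportional to the gDNA abundance
#' times `2^true_level` of the linked insert. Reads are barcode-only.
#'
#' @param truth_levels Tibble from [simulate_true_levels()].
#' @param barcode_truth Tibble (`barcode`, `insert_id`), typically the
#'   `$truth` of [simulate_linkage_reads()].
#' @param gdna_depth,mrna_depth Total reads per sample.
#' @param dispersion Dirichlet-multinomial dispersion (0 = multinomial
#'   around equal weights).
#' @param error_rate Per-base substitution probability on the reads.
#' @param seed Optional integer seed.
#' @return List with `read_set`s `gdna` and `mrna` and the per-barcode
#'   ground-truth tibble `truth`.
#' @export
simulate_count_reads <- function(truth_levels, barcode_truth,
                                 gdna_depth = 2e6, mrna_depth = 2e6,
                                 dispersion = 0.2, error_rate = 0.001,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lvl <- truth_levels$true_level[match(barcode_truth$insert_id,
                                       truth_levels$insert_id)]
  stopifnot(!anyNA(lvl))
  w_g <- dirichlet_weights(nrow(barcode_truth), dispersion)
  w_m <- w_g * 2^lvl
  w_m <- w_m / sum(w_m)
  g_counts <- if (gdna_depth > 0) {
    as.integer(stats::rmultinom(1L, gdna_depth, w_g))
  } else integer(nrow(barcode_truth))
  m_counts <- if (mrna_depth > 0) {
    as.integer(stats::rmultinom(1L, mrna_depth, w_m))
  } else integer(nrow(barcode_truth))
  list(
    gdna = barcode_read_set(barcode_truth$barcode, g_counts, "gdna",
                            error_rate),
    mrna = barcode_read_set(barcode_truth$barcode, m_counts, "mrna",
                            error_rate),
    truth = tibble::tibble(barcode = barcode_truth$barcode,
                           insert_id = barcode_truth$insert_id,
                           gdna_weight = w_g, true_level = lvl)
  )
}

#' Simulate sorted (low-YFP) and unsorted barcode reads
#'
#' The unsorted sample reflects baseline barcode abundances; the
#' low-YFP sample reweights each insert by its premature-termination
#' probability, so inserts that terminate translation early are
#' enriched after sorting.
#'
#' @param truth_levels Tibble from [simulate_true_levels()] (the
#'   `has_stop` column selects the high-termination class).
#' @param barcode_truth Tibble (`barcode`, `insert_id`).
#' @param model A [generative_model()] supplying the termination
#'   probabilities, or a named numeric `term_prob` vector per insert.
#' @param depth Reads per sample.
#' @param dispersion Dirichlet-multinomial dispersion.
#' @param seed Optional integer seed.
#' @return List of `read_set`s `sorted` and `unsorted` plus the
#'   per-insert termination probabilities used.
#' @export
simulate_sorted_reads <- function(truth_levels, barcode_truth,
                                  model = generative_model(),
                                  depth = 1e6, dispersion = 0.2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "generative_model")) {
    term_prob <- ifelse(truth_levels$has_stop, model$term_prob_stop,
                        model$term_prob_base)
    names(term_prob) <- truth_levels$insert_id
  } else {
    term_prob <- model
  }
  tp <- term_prob[barcode_truth$insert_id]
  stopifnot(!anyNA(tp), all(tp >= 0), all(tp <= 1))
  w <- dirichlet_weights(nrow(barcode_truth), dispersion)
  w_sort <- w * tp
  w_sort <- w_sort / sum(w_sort)
  uns <- as.integer(stats::rmultinom(1L, depth, w))
  srt <- as.integer(stats::rmultinom(1L, depth, w_sort))
  list(
    sorted = barcode_read_set(barcode_truth$barcode, srt, "low_yfp"),
    unsorted = barcode_read_set(barcode_truth$barcode, uns, "unsorted"),
    term_prob = term_prob
  )
}

#' Simulate a transcription-shutoff decay timecourse with spike-ins
#'
#' Per-insert abundances decay exponentially with insert-specific
#' half-lives while a set of spike-in barcodes (distinct from the
#' library's) stays at constant abundance, emulating a fixed aliquot of
#' spike-in cells added to every harvested timepoint.
#'
#' @param truth_levels Tibble from [simulate_true_levels()].
#' @param barcode_truth Tibble (`barcode`, `insert_id`).
#' @param model A [generative_model()]; half-life of insert i is
#'   `halflife_base * 2^(true_level/2)`. Alternatively a named numeric
#'   vector of half-lives (hours) per insert.
#' @param timepoints Hours after shutoff; must start at 0.
#' @param spikein_size Number of spike-in barcodes.
#' @param depth Reads per timepoint.
#' @param seed Optional integer seed.
#' @return List with `read_sets` (one per timepoint, named by hour),
#'   `spikein_barcodes`, and the per-insert `halflife` used.
#' @export
simulate_timecourse_reads <- function(truth_levels, barcode_truth,
                                      model = generative_model(),
                                      timepoints = c(0, 0.5, 1, 2, 4, 6),
                                      spikein_size = 500L, depth = 1e6,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE))
  if (inherits(model, "generative_model")) {
    halflife <- model$halflife_base * 2^(truth_levels$true_level / 2)
    names(halflife) <- truth_levels$insert_id
  } else {
    halflife <- model
  }
  hl <- halflife[barcode_truth$insert_id]
  stopifnot(!anyNA(hl), all(hl > 0))
  spike <- generate_barcode(spikein_size)
  # reject astronomically unlikely clashes with library barcodes
  spike <- setdiff(spike, barcode_truth$barcode)[seq_len(spikein_size)]
  while (anyNA(spike)) {
    spike <- unique(c(spike[!is.na(spike)],
                      setdiff(generate_barcode(spikein_size),
                              barcode_truth$barcode)))[seq_len(spikein_size)]
  }
  w0 <- c(rep(1, nrow(barcode_truth)), rep(1, spikein_size))
  all_bc <- c(barcode_truth$barcode, spike)
  sets <- lapply(timepoints, function(t) {
    decay <- c(2^(-t / hl), rep(1, spikein_size))
    w <- w0 * decay
    counts <- as.integer(stats::rmultinom(1L, depth, w / sum(w)))
    barcode_read_set(all_bc, counts, paste0("t", t))
  })
  names(sets) <- paste0("t", timepoints)
  list(read_sets = sets, spikein_barcodes = spike, halflife = halflife,
       timepoints = timepoints)
}

#' Simulate a continuous luminescence translation trace
#'
#' Signal is zero until the first ribosomes complete the transcript at
#' `transit_time_s`, then rises linearly at `rate`; Gaussian noise is
#' added pointwise. Default sampling is every 10 s over 25 min.
#'
#' @param transit_time_s Ribosome transit time (seconds).
#' @param rate Slope of the linear rise (RLU/s).
#' @param noise_sd Noise SD (RLU).
#' @param t_grid Increasing time grid in seconds.
#' @param replicates Number of technical replicates.
#' @param seed Optional integer seed.
#' @return Tibble with `replicate_id`, `time_s`, `signal`.
#' @export
simulate_luminescence <- function(transit_time_s, rate = 1, noise_sd = 0,
                                  t_grid = seq(0, 1500, by = 10),
                                  replicates = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.unsorted(t_grid, strictly = TRUE))
  do.call(rbind, lapply(seq_len(replicates), function(r) {
    signal <- pmax(0, rate * (t_grid - transit_time_s)) +
      stats::rnorm(length(t_grid), 0, noise_sd)
    tibble::tibble(replicate_id = r, time_s = t_grid, signal = signal)
  }))
}

#' Write a read set to FASTQ
#'
#' Constant quality (Phred 40, "I") is used; the simulator models
#' substitution errors directly rather than through quality strings.
#'
#' @param rs A `read_set`.
#' @param path Output path (plain or `.gz`).
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  seqs <- Biostrings::DNAStringSet(rs$reads)
  names(seqs) <- sprintf("%s_%07d", rs$sample_id, seq_along(rs$reads))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(rs$reads))))
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @param sample_id Sample label.
#' @param layout Read layout (offsets of insert and barcode regions);
#'   defaults to the simulator's linkage layout.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, sample_id = basename(path),
                       layout = default_layout()) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  read_set(unname(as.character(seqs)), sample_id, layout)
}
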