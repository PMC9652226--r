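# Barcode counting and per-insert mRNA quantification.

#' Count kept barcodes in a sample
#'
#' Reads are tallied against the kept barcodes of a barcode map by
#' exact match; optionally, a read matching no barcode exactly is
#' rescued to a kept barcode at Hamming distance 1 when that barcode is
#' unique (reads equidistant from two kept barcodes stay unmatched).
#'
#' @param reads A `read_set` (its barcode region is used), a character
#'   vector of barcode reads, or a FASTQ path.
#' @param map A `barcode_map`.
#' @param sample_id Sample label (defaults to the read set's).
#' @param rescue Logical; perform 1-mismatch rescue (default TRUE).
#' @return A tibble of class `count_table` with columns `barcode`,
#'   `insert_id`, `count` covering every kept barcode (zeros included);
#'   attributes `sample_id` and `unmatched`.
#' @export
count_barcodes <- function(reads, map, sample_id = NULL, rescue = TRUE) {
  kept <- kept_barcodes(map)
  if (nrow(kept) == 0L) stop("barcode map has no kept barcodes", call. = FALSE)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (inherits(reads, "read_set")) {
    if (is.null(sample_id)) sample_id <- reads$sample_id
    bc_reads <- extract_region(reads, "barcode")
  } else {
    bc_reads <- as.character(reads)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  width <- nchar(kept$barcode[1])
  hit <- match(bc_reads, kept$barcode)
  counts <- tabulate(hit, nbins = nrow(kept))
  unmatched_reads <- bc_reads[is.na(hit)]
  unmatched_reads <- unmatched_reads[nchar(unmatched_reads) == width]
  n_unmatched <- sum(is.na(hit))
  if (rescue && length(unmatched_reads)) {
    tab <- table(unmatched_reads)
    uniq <- names(tab)
    n_u <- length(uniq)
    # enumerate all single-substitution neighbors of all reads at once:
    # one vectorized edit per (position, alternative-base) combination
    alt_mat <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                        character(3)))
    rownames(alt_mat) <- DNA_BASES
    hit_mat <- matrix(NA_integer_, nrow = n_u, ncol = 3L * width)
    col <- 0L
    for (p in seq_len(width)) {
      cur <- substr(uniq, p, p)
      pre <- substr(uniq, 1L, p - 1L)
      post <- substr(uniq, p + 1L, width)
      known <- cur %in% DNA_BASES
      for (k in 1:3) {
        col <- col + 1L
        repl <- rep(NA_character_, n_u)
        repl[known] <- alt_mat[cur[known], k]
        neigh <- paste0(pre, repl, post)
        neigh[!known] <- NA_character_
        hit_mat[, col] <- match(neigh, kept$barcode)
      }
    }
    rescue_hit <- vapply(seq_len(n_u), function(i) {
      m <- unique(hit_mat[i, ])
      m <- m[!is.na(m)]
      if (length(m) == 1L) m else 0L
    }, integer(1))
    ok <- rescue_hit > 0L
    if (any(ok)) {
      add <- tapply(as.integer(tab)[ok], rescue_hit[ok], sum)
      idx <- as.integer(names(add))
      counts[idx] <- counts[idx] + as.integer(add)
      n_unmatched <- n_unmatched - sum(as.integer(tab)[ok])
    }
  }
  out <- tibble::tibble(barcode = kept$barcode, insert_id = kept$insert_id,
                        count = as.integer(counts))
  attr(out, "sample_id") <- sample_id
  attr(out, "unmatched") <- as.integer(n_unmatched)
  class(out) <- c("count_table", class(out))
  out
}

#' Build a count table from pre-tabulated counts
#'
#' For counts already tallied outside the package (e.g. read from a
#' TSV). An unnamed vector must be parallel to the kept barcodes of the
#' map; a named vector is matched by barcode, with absent barcodes set
#' to zero and counts on unknown barcodes accumulated into the
#' `unmatched` attribute.
#'
#' @param map A `barcode_map`.
#' @param counts Integer vector, named by barcode or parallel to
#'   `kept_barcodes(map)`.
#' @param sample_id Sample label.
#' @return A `count_table`.
#' @export
count_table_from <- function(map, counts, sample_id = "sample") {
  kept <- kept_barcodes(map)
  if (is.null(names(counts))) {
    stopifnot(length(counts) == nrow(kept))
    cnt <- counts
    unmatched <- 0L
  } else {
    cnt <- counts[kept$barcode]
    cnt[is.na(cnt)] <- 0L
    unmatched <- sum(counts) - sum(cnt)
  }
  out <- tibble::tibble(barcode = kept$barcode, insert_id = kept$insert_id,
                        count = as.integer(cnt))
  attr(out, "sample_id") <- sample_id
  attr(out, "unmatched") <- as.integer(unmatched)
  class(out) <- c("count_table", class(out))
  out
}

sum_by_insert <- function(ct) {
  s <- tapply(ct$count, ct$insert_id, sum)
  n <- tapply(ct$count > 0L, ct$insert_id, sum)
  tibble::tibble(insert_id = names(s), sum = as.integer(s),
                 n_nonzero = as.integer(n))
}

#' Per-insert mRNA levels from mRNA and gDNA count tables
#'
#' Counts are summed over each insert's kept barcodes in both samples.
#' Inserts with fewer than `min_reads` total reads (mRNA + gDNA
#' combined), fewer than `min_barcodes` barcodes observed across the
#' two samples, or a zero gDNA sum are flagged `missing`. For the rest,
#' the level is `log2(mrna_sum / gdna_sum)`, median-normalized so the
#' median level of scoreable inserts is 0.
#'
#' @param mrna,gdna `count_table`s built against the same map.
#' @param min_reads Minimum combined read count (default 200).
#' @param min_barcodes Minimum observed barcodes (default 6).
#' @return Tibble with `insert_id`, `mrna_sum`, `gdna_sum`,
#'   `n_barcodes`, `level`, `status`; attribute `median_log2` records
#'   the subtracted median.
#' @export
insert_levels <- function(mrna, gdna, min_reads = 200L, min_barcodes = 6L) {
  stopifnot(inherits(mrna, "count_table"), inherits(gdna, "count_table"))
  if (!identical(mrna$barcode, gdna$barcode)) {
    stop("mRNA and gDNA tables were not counted against the same map",
         call. = FALSE)
  }
  nonzero <- tapply(mrna$count + gdna$count > 0L, mrna$insert_id, sum)
  m <- tapply(mrna$count, mrna$insert_id, sum)
  g <- tapply(gdna$count, gdna$insert_id, sum)
  ids <- names(m)
  m <- as.integer(m); g <- as.integer(g)
  n_bc <- as.integer(nonzero[ids])
  missing <- (m + g) < min_reads | n_bc < min_barcodes | g == 0L
  raw <- ifelse(missing, NA_real_, log2(m / g))
  if (all(missing)) stop("no insert passes the quantification filters",
                         call. = FALSE)
  med <- stats::median(raw, na.rm = TRUE)
  out <- tibble::tibble(
    insert_id = ids, mrna_sum = m, gdna_sum = g, n_barcodes = n_bc,
    level = raw - med,
    status = ifelse(missing, "missing", "ok")
  )
  attr(out, "median_log2") <- med
  out
}

#' Bootstrap SEM of an insert's log2 mRNA level over barcodes
#'
#' Barcodes are resampled with replacement, each draw carrying its
#' paired (mRNA, gDNA) counts jointly; the log2 ratio of the resampled
#' sums is recomputed per replicate and the standard deviation over
#' replicates returned. Replicates whose resampled gDNA sum is zero are
#' dropped (their number is attached as attribute `dropped`).
#'
#' @param mrna_counts,gdna_counts Integer vectors of per-barcode counts
#'   for one insert (parallel).
#' @param B Number of bootstrap replicates (default 100).
#' @return The bootstrap SEM (log2 units); `attr(, "dropped")` counts
#'   discarded replicates.
#' @export
bootstrap_sem <- function(mrna_counts, gdna_counts, B = 100L) {
  stopifnot(B >= 2L, length(mrna_counts) == length(gdna_counts),
            length(mrna_counts) >= 1L)
  n <- length(mrna_counts)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  ms <- colSums(matrix(mrna_counts[idx], nrow = n))
  gs <- colSums(matrix(gdna_counts[idx], nrow = n))
  ok <- gs > 0
  reps <- log2(ms[ok] / gs[ok])
  out <- if (sum(ok) >= 2L) stats::sd(reps) else NA_real_
  attr(out, "dropped") <- as.integer(sum(!ok))
  out
}

#' Add bootstrap SEMs to an insert-level table
#'
#' Runs [bootstrap_sem()] for every scoreable insert. The default
#' replicate count follows library size: 100 replicates for libraries
#' with more than 1000 inserts, 1000 otherwise.
#'
#' @param levels Output of [insert_levels()].
#' @param mrna,gdna The `count_table`s the levels were computed from.
#' @param B Replicates; `NULL` = automatic.
#' @param seed Optional integer seed.
#' @return `levels` with a `sem` column (NA for missing inserts).
#' @export
add_bootstrap_sem <- function(levels, mrna, gdna, B = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(B)) B <- if (nrow(levels) > 1000L) 100L else 1000L
  m_split <- split(mrna$count, mrna$insert_id)
  g_split <- split(gdna$count, gdna$insert_id)
  sem <- rep(NA_real_, nrow(levels))
  for (i in seq_len(nrow(levels))) {
    if (levels$status[i] != "ok") next
    id <- levels$insert_id[i]
    sem[i] <- as.numeric(bootstrap_sem(m_split[[id]], g_split[[id]], B))
  }
  levels$sem <- sem
  levels
}

#' Spike-in-normalized decay curves from a timecourse
#'
#' For each insert and timepoint, the summed insert counts are divided
#' by the total spike-in barcode counts at that timepoint, then the
#' ratio is normalized to its time-0 value, so every curve starts at 1.
#'
#' @param count_tables Named list of `count_table`s, one per timepoint.
#'   Spike-in reads are not part of the map, so each table's
#'   `unmatched` attribute cannot be used; pass spike-in totals via
#'   `spikein_totals` or raw reads via `timecourse_reads`.
#' @param timepoints Numeric hours, parallel to `count_tables`; must
#'   include 0.
#' @param spikein_totals Numeric vector of spike-in read totals per
#'   timepoint (all > 0).
#' @return Tibble with `insert_id`, `timepoint`, `norm_level`.
#' @export
decay_normalize <- function(count_tables, timepoints, spikein_totals) {
  stopifnot(length(count_tables) == length(timepoints),
            length(spikein_totals) == length(timepoints))
  if (!any(timepoints == 0)) stop("timecourse must include t = 0",
                                  call. = FALSE)
  if (any(spikein_totals <= 0)) stop("spike-in totals must be positive",
                                     call. = FALSE)
  ord <- order(timepoints)
  count_tables <- count_tables[ord]
  timepoints <- timepoints[ord]
  spikein_totals <- spikein_totals[ord]
  sums <- lapply(count_tables, function(ct) {
    s <- tapply(ct$count, ct$insert_id, sum)
    s[order(names(s))]
  })
  ids <- names(sums[[1]])
  norm <- mapply(function(s, sp) as.numeric(s[ids]) / sp, sums,
                 spikein_totals)
  baseline <- norm[, timepoints == 0]
  ok <- baseline > 0  # inserts unobserved at t = 0 cannot be normalized
  do.call(rbind, lapply(seq_along(timepoints), function(k) {
    tibble::tibble(insert_id = ids[ok], timepoint = timepoints[k],
                   norm_level = norm[ok, k] / baseline[ok])
  }))
}

#' Count spike-in barcode reads per timecourse sample
#'
#' @param read_sets List of `read_set`s (one per timepoint).
#' @param spikein_barcodes Character vector of spike-in barcodes.
#' @return Integer vector of spike-in read totals.
#' @export
spikein_totals <- function(read_sets, spikein_barcodes) {
  vapply(read_sets, function(rs) {
    sum(extract_region(rs, "barcode") %in% spikein_barcodes)
  }, integer(1))
}

#' Sort-seq enrichment per insert
#'
#' Log2 ratio of the summed barcode counts in the sorted (low-YFP)
#' sample over the unsorted sample; inserts with a zero sum in either
#' sample are flagged `excluded` with an `NA` enrichment. Raw summed
#' counts are used (no library-size normalization) unless
#' `size_normalize = TRUE`, which divides each sum by its sample total
#' first.
#'
#' @param sorted,unsorted `count_table`s built against the same map.
#' @param size_normalize Logical (default FALSE).
#' @return Tibble with `insert_id`, `sorted_sum`, `unsorted_sum`,
#'   `enrichment`, `status`.
#' @export
facs_enrichment <- function(sorted, unsorted, size_normalize = FALSE) {
  stopifnot(inherits(sorted, "count_table"), inherits(unsorted, "count_table"))
  if (!identical(sorted$barcode, unsorted$barcode)) {
    stop("tables were not counted against the same map", call. = FALSE)
  }
  s <- tapply(sorted$count, sorted$insert_id, sum)
  u <- tapply(unsorted$count, unsorted$insert_id, sum)
  ids <- names(s)
  s <- as.numeric(s); u <- as.numeric(u[ids])
  ratio <- if (size_normalize) (s / sum(s)) / (u / sum(u)) else s / u
  bad <- s == 0 | u == 0
  tibble::tibble(
    insert_id = ids, sorted_sum = as.integer(s), unsorted_sum = as.integer(u),
    enrichment = ifelse(bad, NA_real_, log2(ratio)),
    status = ifelse(bad, "excluded", "ok")
  )
}
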