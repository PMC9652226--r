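# Barcode-to-insert assignment.
#
# Insert regions of linkage reads are matched to the library allowing
# up to m substitutions (no indels; the synthesized regions are fixed
# length). Matching uses an exact-hash fast path plus a pigeonhole
# k-mer index: a read within m substitutions of a library insert must
# match at least one of m+1 equal chunks exactly, so candidate inserts
# are found by hash lookups and verified by Hamming distance. A read is
# unassigned when no insert lies within m substitutions or when two
# inserts tie at the minimum distance.

build_insert_index <- function(library, max_mismatch = 2L) {
  width <- nchar(library$nt_seq[1])
  stopifnot(all(nchar(library$nt_seq) == width))
  n_chunk <- max_mismatch + 1L
  bounds <- floor(seq(0L, width, length.out = n_chunk + 1L))
  chunk_env <- new.env(parent = emptyenv(), size = nrow(library) * n_chunk)
  for (ci in seq_len(n_chunk)) {
    keys <- substring(library$nt_seq, bounds[ci] + 1L, bounds[ci + 1L])
    for (i in seq_along(keys)) {
      k <- paste0(ci, ":", keys[i])
      chunk_env[[k]] <- c(chunk_env[[k]], i)
    }
  }
  exact <- new.env(parent = emptyenv(), size = nrow(library))
  for (i in seq_len(nrow(library))) exact[[library$nt_seq[i]]] <- i
  list(library = library, width = width, max_mismatch = max_mismatch,
       bounds = bounds, chunks = chunk_env, exact = exact)
}

#' Match read insert regions to library inserts
#'
#' Returns, for each region, the unique library insert within at most
#' `max_mismatch` substitutions, or `NA` when none exists, when two
#' inserts tie at the minimum distance, or when the region is shorter
#' than the insert width.
#'
#' @param regions Character vector of read insert regions.
#' @param library Library tibble (`insert_id`, `nt_seq`), all inserts of
#'   equal width.
#' @param max_mismatch Maximum substitution count (default 2).
#' @return Character vector of insert ids (`NA` = unassigned).
#' @export
match_insert <- function(regions, library, max_mismatch = 2L) {
  idx <- build_insert_index(library, max_mismatch)
  out <- rep(NA_character_, length(regions))
  too_short <- is.na(regions) | nchar(regions) != idx$width
  # exact fast path
  hit <- match(regions, library$nt_seq)
  exact_ok <- !too_short & !is.na(hit)
  out[exact_ok] <- library$insert_id[hit[exact_ok]]
  todo <- which(!exact_ok & !too_short)
  if (length(todo)) {
    n_chunk <- max_mismatch + 1L
    bounds <- idx$bounds
    for (j in todo) {
      r <- regions[j]
      cand <- integer(0)
      for (ci in seq_len(n_chunk)) {
        k <- paste0(ci, ":", substring(r, bounds[ci] + 1L, bounds[ci + 1L]))
        hit_ci <- idx$chunks[[k]]
        if (!is.null(hit_ci)) cand <- c(cand, hit_ci)
      }
      if (length(cand) == 0L) next
      cand <- unique(cand)
      d <- hamming(rep(r, length(cand)), library$nt_seq[cand])
      ok <- d <= max_mismatch
      if (!any(ok)) next
      dmin <- min(d[ok])
      best <- cand[ok][d[ok] == dmin]
      if (length(best) == 1L) out[j] <- library$insert_id[best]
    }
  }
  out
}

extract_region <- function(rs, what = c("insert", "barcode")) {
  what <- match.arg(what)
  start <- rs$layout[[paste0(what, "_start")]]
  len <- rs$layout[[paste0(what, "_len")]]
  if (is.na(start)) stop("read layout has no ", what, " region", call. = FALSE)
  substring(rs$reads, start, start + len - 1L)
}

# Greedy same-insert near-duplicate collapse: barcodes are visited in
# decreasing count (ties broken lexicographically, the greater barcode
# discarded first), and a barcode is kept only if it is farther than
# `collision_distance` from every barcode already kept for the insert.
collapse_duplicates <- function(barcodes, counts, collision_distance) {
  ord <- order(-counts, barcodes)
  kept <- logical(length(barcodes))
  kept_idx <- integer(0)
  for (i in ord) {
    if (length(kept_idx) == 0L ||
        all(hamming(rep(barcodes[i], length(kept_idx)),
                    barcodes[kept_idx]) > collision_distance)) {
      kept[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  kept
}

#' Build a filtered barcode-to-insert map from linkage reads
#'
#' Assigns each read's insert region to the library, tallies
#' (barcode, insert) pairs, then applies three filters in order:
#' barcodes seen fewer than `min_count` times in total are dropped
#' (`below_min_count`); barcodes linked to two or more distinct inserts
#' are dropped entirely (`multi_insert`); among barcodes of the same
#' insert lying within Hamming distance `collision_distance` of each
#' other, the lower-count member is dropped (`duplicate_collapsed`,
#' ties resolved against the lexicographically greater barcode). Reads
#' whose insert region cannot be uniquely assigned are discarded before
#' tallying.
#'
#' @param reads A `read_set` from [simulate_linkage_reads()] /
#'   [read_fastq()], or a tibble with columns `insert_region` and
#'   `barcode`.
#' @param library Library tibble.
#' @param min_count Minimum total observations of a barcode (default 4).
#' @param collision_distance Near-duplicate Hamming radius (default 2).
#' @param max_mismatch Insert-matching substitution allowance.
#' @return A tibble of class `barcode_map` with columns `barcode`,
#'   `insert_id`, `count`, `disposition`; kept entries have
#'   `disposition == "kept"`. The number of discarded ambiguous reads is
#'   attached as attribute `ambiguous_reads`.
#' @export
build_barcode_map <- function(reads, library, min_count = 4L,
                              collision_distance = 2L, max_mismatch = 2L) {
  stopifnot(min_count >= 1L, collision_distance >= 0L)
  if (inherits(reads, "read_set")) {
    pairs <- tibble::tibble(insert_region = extract_region(reads, "insert"),
                            barcode = extract_region(reads, "barcode"))
  } else {
    stopifnot(all(c("insert_region", "barcode") %in% names(reads)))
    pairs <- tibble::as_tibble(reads[c("insert_region", "barcode")])
  }
  if (nrow(pairs) == 0L) {
    warning("empty read set: returning an empty barcode map")
    out <- tibble::tibble(barcode = character(), insert_id = character(),
                          count = integer(), disposition = character())
    attr(out, "ambiguous_reads") <- 0L
    class(out) <- c("barcode_map", class(out))
    return(out)
  }
  pairs$insert_id <- match_insert(pairs$insert_region, library, max_mismatch)
  n_ambiguous <- sum(is.na(pairs$insert_id))
  pairs <- pairs[!is.na(pairs$insert_id), ]
  tally <- dplyr::count(pairs, .data$barcode, .data$insert_id,
                        name = "count")
  tally <- dplyr::arrange(tally, .data$barcode, .data$insert_id)
  bc_total <- tapply(tally$count, tally$barcode, sum)
  disposition <- rep("kept", nrow(tally))
  disposition[bc_total[tally$barcode] < min_count] <- "below_min_count"
  multi <- names(which(table(tally$barcode[disposition == "kept"]) > 1L))
  disposition[disposition == "kept" & tally$barcode %in% multi] <-
    "multi_insert"
  live <- disposition == "kept"
  if (any(live)) {
    for (ins in unique(tally$insert_id[live])) {
      sel <- which(live & tally$insert_id == ins)
      if (length(sel) < 2L) next
      keep <- collapse_duplicates(tally$barcode[sel], tally$count[sel],
                                  collision_distance)
      disposition[sel[!keep]] <- "duplicate_collapsed"
    }
  }
  out <- tibble::tibble(barcode = tally$barcode, insert_id = tally$insert_id,
                        count = as.integer(tally$count),
                        disposition = disposition)
  out <- out[order(out$insert_id, out$barcode), ]
  attr(out, "ambiguous_reads") <- n_ambiguous
  class(out) <- c("barcode_map", class(out))
  out
}

#' Kept entries of a barcode map
#'
#' @param map A `barcode_map`.
#' @return Tibble of the kept (barcode, insert, count) rows.
#' @export
kept_barcodes <- function(map) {
  stopifnot(inherits(map, "barcode_map"))
  out <- map[map$disposition == "kept",
             c("barcode", "insert_id", "count")]
  tibble::as_tibble(out)
}

#' Write a barcode map as gzip-compressed TSV
#'
#' @param map A `barcode_map`.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @export
write_barcode_map <- function(map, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(map), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
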