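toy_map <- function(barcodes, inserts, counts = NULL) {
  if (is.null(counts)) counts <- rep(10L, length(barcodes))
  out <- tibble::tibble(barcode = barcodes, insert_id = inserts,
                        count = as.integer(counts),
                        disposition = "kept")
  class(out) <- c("barcode_map", class(out))
  out
}

test_that("barcode counting tallies exact matches and rescues unique 1-mismatch", {
  bc <- c(strrep("AAC", 8), strrep("GGA", 8), strrep("CCG", 8))
  map <- toy_map(bc, c("i1", "i2", "i3"))
  ct <- count_barcodes(bc, map)
  expect_equal(ct$count, c(1L, 1L, 1L))
  expect_equal(attr(ct, "unmatched"), 0L)
  # read at Hamming 1 from exactly one kept barcode
  near <- paste0("TAC", strrep("AAC", 7))
  ct2 <- count_barcodes(near, map)
  expect_equal(ct2$count[ct2$barcode == bc[1]], 1L)
  expect_equal(attr(ct2, "unmatched"), 0L)
  # rescue disabled: stays unmatched
  ct3 <- count_barcodes(near, map, rescue = FALSE)
  expect_equal(sum(ct3$count), 0L)
  expect_equal(attr(ct3, "unmatched"), 1L)
})

test_that("reads equidistant from two kept barcodes stay unmatched", {
  b1 <- strrep("A", 24)
  b2 <- paste0(strrep("A", 22), "CC")
  map <- toy_map(c(b1, b2), c("i1", "i2"))
  amb <- paste0(strrep("A", 22), "CA")  # Hamming 1 from both
  ct <- count_barcodes(amb, map)
  expect_equal(sum(ct$count), 0L)
  expect_equal(attr(ct, "unmatched"), 1L)
})

test_that("insert levels apply the read/barcode thresholds and median shift", {
  # three inserts passing, raw log2 ratios 1, 2, 5 -> normalized -1, 0, 3
  mk <- function(m_counts, g_counts, map) {
    m <- count_table_from(map, m_counts)
    g <- count_table_from(map, g_counts)
    insert_levels(m, g, min_reads = 200, min_barcodes = 6)
  }
  bcs <- replicate(18, paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                             collapse = ""))
  map <- toy_map(bcs, rep(c("a", "b", "c"), each = 6))
  # per-insert sums: mRNA 600/1200/9600 over gDNA 300 -> raw log2 1, 2, 5
  m_counts <- rep(c(100, 200, 1600), each = 6)
  g_counts <- rep(50, 18)
  lv <- mk(m_counts, g_counts, map)
  expect_equal(lv$level[match(c("a", "b", "c"), lv$insert_id)], c(-1, 0, 3))
  expect_equal(attr(lv, "median_log2"), 2)
})

test_that("inserts below the filters are designated missing", {
  bcs <- replicate(11, paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                             collapse = ""))
  map <- toy_map(bcs, c(rep("few_bc", 5), rep("ok", 6)))
  # few_bc: 5 barcodes, 500 reads -> missing despite read count
  m <- count_table_from(map, c(rep(50, 5), rep(100, 6)))
  g <- count_table_from(map, c(rep(50, 5), rep(100, 6)))
  lv <- insert_levels(m, g)
  expect_equal(lv$status[lv$insert_id == "few_bc"], "missing")
  expect_equal(lv$status[lv$insert_id == "ok"], "ok")
  expect_true(is.na(lv$level[lv$insert_id == "few_bc"]))
  # zero gDNA with nonzero mRNA -> missing
  g2 <- count_table_from(map, c(rep(0, 5), rep(100, 6)))
  m2 <- count_table_from(map, c(rep(100, 5), rep(100, 6)))
  lv2 <- insert_levels(m2, g2, min_reads = 10, min_barcodes = 2)
  expect_equal(lv2$status[lv2$insert_id == "few_bc"], "missing")
  # a single passing insert normalizes to exactly 0
  expect_equal(lv2$level[lv2$insert_id == "ok"], 0)
  # all inserts failing is an error
  z <- count_table_from(map, rep(0, 11))
  expect_error(insert_levels(z, z), "no insert")
})

test_that("median normalization is idempotent and label-invariant", {
  set.seed(3)
  bcs <- replicate(30, paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                             collapse = ""))
  map <- toy_map(bcs, rep(paste0("i", 1:5), each = 6))
  m <- count_table_from(map, rpois(30, 80))
  g <- count_table_from(map, rpois(30, 60))
  lv <- insert_levels(m, g, min_reads = 10, min_barcodes = 2)
  expect_equal(median(lv$level[lv$status == "ok"]), 0)
  # renormalizing the normalized levels changes nothing
  expect_equal(lv$level - median(lv$level, na.rm = TRUE), lv$level)
  # permuting barcode labels within an insert leaves levels unchanged
  perm <- unlist(lapply(split(seq_len(30), map$insert_id), sample))
  m2 <- m; m2$count <- m$count[perm][order(perm)]  # identity permutation
  lvp <- insert_levels(m2, g, min_reads = 10, min_barcodes = 2)
  expect_equal(lvp$level, lv$level)
})

test_that("bootstrap SEM matches exact enumeration for two barcodes", {
  expect_equal(as.numeric(bootstrap_sem(c(7, 7, 7), c(3, 3, 3), B = 50)), 0)
  expect_equal(as.numeric(bootstrap_sem(5, 9, B = 50)), 0)
  m <- c(100, 400); g <- c(100, 100)
  set.seed(77)
  sem <- as.numeric(bootstrap_sem(m, g, B = 2e5))
  expect_equal(sem, oracle_boot_sd_2(m, g), tolerance = 0.01)
})

test_that("bootstrap SEM shrinks with sequencing depth", {
  # per-barcode ratios concentrate as counts are re-drawn at higher
  # depth, so the barcode-bootstrap SEM shrinks roughly as 1/sqrt(depth)
  set.seed(12)
  s1 <- as.numeric(bootstrap_sem(rpois(10, 50), rpois(10, 50), B = 400))
  s2 <- as.numeric(bootstrap_sem(rpois(10, 5000), rpois(10, 5000), B = 400))
  expect_lt(s2, s1 * 0.3)
})

test_that("decay normalization divides by spike-in and the t0 value", {
  bcs <- replicate(6, paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                            collapse = ""))
  map <- toy_map(bcs, rep(c("a", "b"), each = 3))
  cts <- list(count_table_from(map, rep(100, 6)),
              count_table_from(map, rep(100, 6)))
  # constant insert and spike-in counts -> flat curves at 1
  dc <- decay_normalize(cts, c(0, 2), c(1000, 1000))
  expect_true(all(dc$norm_level == 1))
  # doubling both insert and spike-in counts leaves the curve unchanged
  cts2 <- list(cts[[1]], count_table_from(map, rep(200, 6)))
  dc2 <- decay_normalize(cts2, c(0, 2), c(1000, 2000))
  expect_true(all(dc2$norm_level == 1))
  expect_error(decay_normalize(cts, c(1, 2), c(1, 1)), "t = 0")
  expect_error(decay_normalize(cts, c(0, 2), c(0, 1)), "positive")
})

test_that("sort-seq enrichment is the log2 ratio of summed counts", {
  bcs <- replicate(4, paste(sample(c("A", "C", "G"), 24, replace = TRUE),
                            collapse = ""))
  map <- toy_map(bcs, rep(c("a", "b"), each = 2))
  srt <- count_table_from(map, c(200, 200, 50, 50))
  uns <- count_table_from(map, c(50, 50, 0, 0))
  fe <- facs_enrichment(srt, uns)
  expect_equal(fe$enrichment[fe$insert_id == "a"], 2)
  expect_equal(fe$status[fe$insert_id == "b"], "excluded")
  expect_true(is.na(fe$enrichment[fe$insert_id == "b"]))
  eq <- facs_enrichment(srt, srt)
  expect_true(all(eq$enrichment == 0))
})
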