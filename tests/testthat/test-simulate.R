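test_that("true levels follow the physicochemical formula exactly", {
  lib <- enumerate_codon_pairs()
  m0 <- generative_model(beta_pI = 0, beta_bulk = 0, beta_inter = 0,
                         beta_strand = 0, noise_sd = 0, stop_penalty = 0)
  expect_true(all(simulate_true_levels(lib, m0)$true_level == 0))

  m <- generative_model(beta_pI = 0.31, beta_bulk = 0.20,
                        beta_inter = -0.03, beta_strand = 0,
                        noise_sd = 0, stop_penalty = 0)
  tl <- simulate_true_levels(lib, m)
  dp <- substring(lib$peptide, 1, 2)
  sel <- which(!grepl("*", dp, fixed = TRUE))[1:50]
  for (i in sel) {
    pI <- mean_scale(dp[i], "pI")
    bulk <- mean_scale(dp[i], "bulkiness")
    expect_equal(tl$true_level[i], 0.31 * pI + 0.20 * bulk - 0.03 * pI * bulk)
  }
  # identical dipeptide composition -> identical noiseless level
  same <- tl$true_level[dp == "VK"]
  expect_true(all(same == same[1]))
})

test_that("linkage simulation is reproducible and lossless without errors", {
  lib <- small_library(25)
  a <- simulate_linkage_reads(lib, depth = 5000, error_rate = 0, seed = 21)
  b <- simulate_linkage_reads(lib, depth = 5000, error_rate = 0, seed = 21)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  # every read is exactly insert followed by its barcode
  ins <- substring(a$reads, 1, 48)
  bc <- substring(a$reads, 49, 72)
  truth_of <- setNames(a$truth$insert_id, a$truth$barcode)
  lib_seq <- setNames(lib$nt_seq, lib$insert_id)
  expect_true(all(ins == lib_seq[truth_of[bc]]))
})

test_that("fixing barcodes per insert to one yields one barcode each", {
  lib <- small_library(15)
  set.seed(4)
  rs <- simulate_linkage_reads(lib, depth = 2000, median_barcodes = 1,
                               error_rate = 0)
  n_bc <- table(rs$truth$insert_id)
  expect_true(all(n_bc >= 1))
  # median-1 truncated geometric is degenerate at 1
  expect_equal(median(as.integer(n_bc)), 1)
})

test_that("barcode-per-insert distribution has median 15", {
  set.seed(8)
  lib <- enumerate_codon_pairs()[1:2000, ]
  rs <- simulate_linkage_reads(lib, depth = 10, error_rate = 0)
  expect_equal(median(as.integer(table(rs$truth$insert_id))), 15)
})

test_that("count simulation inverts to the true levels at high depth", {
  lib <- small_library(30)
  model <- generative_model(noise_sd = 0)
  truth <- simulate_true_levels(lib, model, seed = 2)
  set.seed(2)
  bc <- tibble::tibble(barcode = generate_barcode(30 * 10),
                       insert_id = rep(lib$insert_id, each = 10))
  sim <- simulate_count_reads(truth, bc, gdna_depth = 1e6, mrna_depth = 1e6,
                              dispersion = 0, error_rate = 0, seed = 3)
  g <- tapply(tabulate(match(sim$gdna$reads, bc$barcode), nrow(bc)),
              bc$insert_id, sum)
  m <- tapply(tabulate(match(sim$mrna$reads, bc$barcode), nrow(bc)),
              bc$insert_id, sum)
  est <- log2(m / g)
  resid <- (est - mean(est)) - (truth$true_level[match(names(g), truth$insert_id)] -
                                  mean(truth$true_level))
  expect_lt(max(abs(resid)), 0.1)
})

test_that("empty mRNA depth gives an empty read set", {
  lib <- small_library(5)
  truth <- simulate_true_levels(lib, generative_model(noise_sd = 0))
  bc <- tibble::tibble(barcode = generate_barcode(5),
                       insert_id = lib$insert_id)
  sim <- simulate_count_reads(truth, bc, gdna_depth = 1000, mrna_depth = 0,
                              dispersion = 0, seed = 1)
  expect_equal(length(sim$mrna$reads), 0)
  expect_equal(length(sim$gdna$reads), 1000)
})

test_that("uniform termination probability gives near-zero enrichment", {
  lib <- small_library(20)
  truth <- simulate_true_levels(lib, generative_model(noise_sd = 0), seed = 5)
  set.seed(5)
  bc <- tibble::tibble(barcode = generate_barcode(20 * 5),
                       insert_id = rep(lib$insert_id, each = 5))
  tp <- setNames(rep(0.5, 20), lib$insert_id)
  sim <- simulate_sorted_reads(truth, bc, model = tp, depth = 5e5,
                               dispersion = 0, seed = 6)
  s <- tapply(tabulate(match(sim$sorted$reads, bc$barcode), nrow(bc)),
              bc$insert_id, sum)
  u <- tapply(tabulate(match(sim$unsorted$reads, bc$barcode), nrow(bc)),
              bc$insert_id, sum)
  expect_lt(max(abs(log2(s / u))), 0.15)
})

test_that("timecourse decays by half at one half-life with constant spike-in", {
  lib <- small_library(10)
  truth <- simulate_true_levels(lib, generative_model(noise_sd = 0), seed = 9)
  set.seed(9)
  bc <- tibble::tibble(barcode = generate_barcode(10 * 5),
                       insert_id = rep(lib$insert_id, each = 5))
  hl <- setNames(rep(2, 10), lib$insert_id)
  tc <- simulate_timecourse_reads(truth, bc, model = hl,
                                  timepoints = c(0, 2), spikein_size = 200,
                                  depth = 1e6, seed = 10)
  expect_equal(length(tc$read_sets), 2)
  counts <- function(rs) {
    ins <- sum(rs$reads %in% bc$barcode)
    spk <- sum(rs$reads %in% tc$spikein_barcodes)
    ins / spk
  }
  ratio <- counts(tc$read_sets[["t2"]]) / counts(tc$read_sets[["t0"]])
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("luminescence traces are piecewise linear with the set intercept", {
  tr <- simulate_luminescence(600, rate = 2, noise_sd = 0)
  expect_true(all(tr$signal[tr$time_s <= 600] == 0))
  expect_equal(tr$signal[tr$time_s > 600],
               2 * (tr$time_s[tr$time_s > 600] - 600))
  flat <- simulate_luminescence(600, rate = 0, noise_sd = 0)
  expect_true(all(flat$signal == 0))
})

test_that("read sets round-trip through FASTQ", {
  lib <- small_library(8)
  rs <- simulate_linkage_reads(lib, depth = 200, error_rate = 0, seed = 13)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_fastq(fq, sample_id = "linkage")
  expect_equal(back$reads, rs$reads)
})
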