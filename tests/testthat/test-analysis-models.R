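dicodon_levels <- function(level_fun, lib = enumerate_codon_pairs()) {
  tibble::tibble(insert_id = lib$insert_id, level = level_fun(lib))
}

test_that("positional effects reproduce a group-by oracle", {
  lib <- enumerate_codon_pairs()
  set.seed(2)
  lv <- dicodon_levels(function(l) rnorm(nrow(l)))
  eff <- positional_effects(lv)
  # oracle: direct mean over rows with the codon at the position
  codon1 <- substring(lv$insert_id, 1, 3)
  codon2 <- substring(lv$insert_id, 5, 7)
  for (cdn in c("AAA", "TGA", "GTG", "CCC")) {
    expect_equal(
      eff$mean_level[eff$unit_type == "codon" & eff$unit == cdn &
                       eff$position == 1],
      mean(lv$level[codon1 == cdn]))
    expect_equal(
      eff$mean_level[eff$unit_type == "codon" & eff$unit == cdn &
                       eff$position == 2],
      mean(lv$level[codon2 == cdn]))
  }
  # every codon appears exactly once per position
  codon_rows <- eff[eff$unit_type == "codon", ]
  expect_equal(nrow(codon_rows), 128)
  # amino-acid level: 20 aa + stop, both positions
  aa_rows <- eff[eff$unit_type == "aa", ]
  expect_equal(nrow(aa_rows), 42)
  # aa effect pools synonymous codons
  lut <- genetic_code
  expect_equal(
    aa_rows$mean_level[aa_rows$unit == "K" & aa_rows$position == 1],
    mean(lv$level[lut[codon1] == "K"]))
})

test_that("constant and stop-penalized levels give the expected effects", {
  lv <- dicodon_levels(function(l) rep(1.5, nrow(l)))
  eff <- positional_effects(lv)
  expect_true(all(eff$mean_level == 1.5))
  # stop-containing pairs at -1, rest 0: stop class below every aa
  lv2 <- dicodon_levels(function(l) {
    ifelse(grepl("*", l$peptide, fixed = TRUE), -1, 0)
  })
  eff2 <- positional_effects(lv2)
  aa2 <- eff2[eff2$unit_type == "aa", ]
  stop_eff <- aa2$mean_level[aa2$unit == "*"]
  other <- aa2$mean_level[aa2$unit != "*"]
  expect_true(all(stop_eff < other))
})

test_that("OLS recovers generative coefficients on noiseless data", {
  lib <- enumerate_codon_pairs()
  model <- generative_model(noise_sd = 0)
  truth <- simulate_true_levels(lib, model)
  keep <- !truth$has_stop
  dat <- tibble::tibble(dipeptide = substring(lib$peptide[keep], 1, 2),
                        level = truth$true_level[keep])
  fit <- fit_physicochemical_model(
    dat, features = c("pI", "bulkiness", "pI:bulkiness", "cf_strand"))
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(unname(est["pI"]), 0.31, tolerance = 1e-7)
  expect_equal(unname(est["bulkiness"]), 0.20, tolerance = 1e-7)
  expect_equal(unname(est["pI:bulkiness"]), -0.03, tolerance = 1e-7)
  expect_equal(unname(est["cf_strand"]), -0.52, tolerance = 1e-7)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
  expect_setequal(fit$retained$term,
                  c("pI", "bulkiness", "pI:bulkiness", "cf_strand"))
})

test_that("degenerate model inputs are handled explicitly", {
  # constant response: zero slopes, non-positive adjusted R^2, nothing retained
  dat <- tibble::tibble(dipeptide = c("VK", "KV", "SF", "RH", "AA", "GG"),
                        level = rep(2, 6))
  fit <- fit_physicochemical_model(dat, features = c("pI", "bulkiness"))
  expect_equal(unname(fit$terms$estimate[fit$terms$term != "(Intercept)"]),
               c(0, 0), tolerance = 1e-12)
  expect_lte(fit$adjusted_r2, 0)
  expect_equal(nrow(fit$retained), 0)
  # collinear features: error naming the offending term
  dat2 <- tibble::tibble(dipeptide = rep("VK", 8),
                         level = rnorm(8))
  expect_error(fit_physicochemical_model(dat2, features = c("pI", "bulkiness")),
               "collinear")
  expect_error(fit_physicochemical_model(dat[1:3, ],
                                         features = c("pI", "bulkiness")),
               "observation")
})

test_that("rotation-invariant levels give r = 1 for all frame shifts", {
  # level = base composition of the hexamer, invariant under rotation,
  # so each pair and its partner always share the same level
  lv <- dicodon_levels(function(l) {
    vapply(paste0(l$codon1, l$codon2), function(h) {
      sum(strsplit(h, "")[[1]] == "A") + 0.1 * sum(strsplit(h, "")[[1]] == "C")
    }, numeric(1))
  })
  fc <- frame_correlations(lv)
  expect_equal(fc$r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(fc$n_classes > 150))
})

test_that("independent levels give near-zero frame correlations", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    lv <- dicodon_levels(function(l) rnorm(nrow(l)))
    fc <- frame_correlations(lv)
    hits <- hits + all(abs(fc$r) < 0.2)
  }
  expect_gte(hits, 18)
})

test_that("peptide-determined levels rank the codon-matched +3 frame highest", {
  lib <- enumerate_codon_pairs()
  truth <- simulate_true_levels(lib, generative_model(noise_sd = 0))
  lv <- tibble::tibble(insert_id = truth$insert_id,
                       level = truth$true_level)
  fc <- frame_correlations(lv)
  expect_gt(fc$r[fc$shift == 3], fc$r[fc$shift == 1])
  expect_gt(fc$r[fc$shift == 3], fc$r[fc$shift == 2])
})

test_that("propensity correlations detect monotone relations", {
  aa <- setdiff(standard_aa, "C")
  prop <- aa_scales()
  strand <- setNames(prop$cf_strand, prop$aa)[aa]
  # strictly decreasing in propensity -> rho = -1
  res <- propensity_correlation(-rank(strand), aa, "cf_strand")
  expect_equal(res$rho, -1)
  expect_lt(res$p_value, 1e-6)
  expect_error(propensity_correlation(rnorm(4), rep("G", 4), "cf_strand"),
               "constant")
  expect_error(propensity_correlation(rnorm(3), c("A", "V", "K"),
                                      "cf_strand"), "4 points")
})

test_that("null propensity p-values are roughly uniform", {
  set.seed(41)
  aa <- standard_aa
  p <- replicate(200, {
    propensity_correlation(rnorm(20), aa, "cf_strand")$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("group comparisons use exact Mann-Whitney where applicable", {
  expect_equal(group_compare(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$p_value, 1)
  res <- group_compare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  # three groups -> three pairwise tests
  res3 <- group_compare(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_equal(nrow(res3), 3)
  expect_error(group_compare(1:3, rep("a", 3)), "two groups")
})
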