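# Statistical analyses over quantified insert levels: positional
# codon/amino-acid averaging, physicochemical linear models, reading
# frame correlations, propensity correlations, and group comparisons.

dicodon_levels_frame <- function(levels) {
  # expects insert_id of the form "<codon1>_<codon2>"
  parts <- strsplit(levels$insert_id, "_", fixed = TRUE)
  stopifnot(all(lengths(parts) == 2L))
  tibble::tibble(
    insert_id = levels$insert_id,
    codon1 = vapply(parts, `[`, character(1), 1L),
    codon2 = vapply(parts, `[`, character(1), 2L),
    level = levels$level
  )
}

#' Positional codon and amino-acid effects
#'
#' For each codon and each position of the codon pair, the mean level
#' over all partners at the other position; amino-acid effects pool
#' synonymous codons, with stop treated as a 21st class. The SEM is the
#' standard error of that mean.
#'
#' @param levels Tibble with `insert_id` (`"<codon1>_<codon2>"`) and
#'   `level` for the dicodon pool; rows with `NA` level are ignored.
#' @return Tibble with `unit_type` (`"codon"`/`"aa"`), `unit`,
#'   `position` (1 or 2), `mean_level`, `sem`, `n`.
#' @export
positional_effects <- function(levels) {
  df <- dicodon_levels_frame(levels)
  df <- df[!is.na(df$level), ]
  long <- rbind(
    data.frame(unit = df$codon1, position = 1L, level = df$level),
    data.frame(unit = df$codon2, position = 2L, level = df$level)
  )
  summarise_units <- function(d, type) {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$unit, .data$position),
      mean_level = mean(.data$level),
      sem = stats::sd(.data$level) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
    out$unit_type <- type
    out
  }
  codon_eff <- summarise_units(long, "codon")
  long_aa <- long
  long_aa$unit <- unname(genetic_code[long_aa$unit])
  aa_eff <- summarise_units(long_aa, "aa")
  out <- rbind(codon_eff, aa_eff)
  tibble::as_tibble(out[c("unit_type", "unit", "position", "mean_level",
                          "sem", "n")])
}

#' Fit the physicochemical linear model of mRNA level
#'
#' Ordinary least squares (with intercept) of the level on mean pI,
#' mean bulkiness, their product, and optionally mean beta-strand
#' propensity of the dipeptide. Coefficients with two-sided p < 0.05
#' form the retained set, mirroring the convention of reporting only
#' significant terms.
#'
#' @param data Tibble with a `dipeptide` (2-letter) or `peptide` column
#'   and a `level` column; rows with `NA` level are dropped.
#' @param features Character subset of
#'   `c("pI", "bulkiness", "pI:bulkiness", "cf_strand")`.
#' @param alpha Retention threshold on the coefficient p-value.
#' @return List of class `physicochem_fit` with `terms` (tibble: term,
#'   estimate, p_value), `retained`, `adjusted_r2`, and the underlying
#'   `lm` fit.
#' @export
fit_physicochemical_model <- function(data,
                                      features = c("pI", "bulkiness",
                                                   "pI:bulkiness"),
                                      alpha = 0.05) {
  allowed <- c("pI", "bulkiness", "pI:bulkiness", "cf_strand")
  stopifnot(all(features %in% allowed))
  pep <- if ("dipeptide" %in% names(data)) data$dipeptide else data$peptide
  keep <- !is.na(data$level)
  df <- data.frame(level = data$level[keep])
  pep <- pep[keep]
  if ("pI" %in% features || "pI:bulkiness" %in% features) {
    df$pI <- mean_scale(pep, "pI")
  }
  if ("bulkiness" %in% features || "pI:bulkiness" %in% features) {
    df$bulkiness <- mean_scale(pep, "bulkiness")
  }
  if ("cf_strand" %in% features) df$cf_strand <- mean_scale(pep, "cf_strand")
  rhs <- gsub("pI:bulkiness", "I(pI * bulkiness)", features, fixed = TRUE)
  form <- stats::as.formula(paste("level ~", paste(rhs, collapse = " + ")))
  if (nrow(df) < length(features) + 2L) {
    stop("need at least one observation per parameter plus two",
         call. = FALSE)
  }
  fit <- stats::lm(form, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear feature matrix; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      # zero-residual fits are detected and handled below
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- sm$coefficients
  term_names <- gsub("I\\(pI \\* bulkiness\\)", "pI:bulkiness",
                     rownames(co))
  terms <- tibble::tibble(term = term_names,
                          estimate = co[, "Estimate"],
                          p_value = co[, "Pr(>|t|)"])
  # degenerate cases: a constant response carries no signal (nothing
  # retained, R^2 pinned at 0); a perfect zero-residual fit of a
  # non-constant response has no valid t statistics, so every slope is
  # trivially "retained"
  const_y <- stats::var(df$level) <= 1e-20 * max(1, mean(df$level)^2)
  perfect <- !const_y && sm$sigma^2 < 1e-20 * stats::var(df$level)
  sel <- if (const_y) {
    rep(FALSE, nrow(terms))
  } else if (perfect) {
    terms$term != "(Intercept)"
  } else {
    !is.na(terms$p_value) & terms$p_value < alpha &
      terms$term != "(Intercept)"
  }
  adj_r2 <- if (const_y) 0 else sm$adj.r.squared
  if (!is.finite(adj_r2)) adj_r2 <- 0
  structure(list(terms = terms, retained = terms[sel, ],
                 adjusted_r2 = adj_r2, fit = fit),
            class = "physicochem_fit")
}

#' @export
print.physicochem_fit <- function(x, ...) {
  cat("<physicochem_fit> adjusted R^2 =", signif(x$adjusted_r2, 3), "\n")
  print(x$terms)
  invisible(x)
}

#' Reading-frame correlations of dipeptide-repeat levels
#'
#' For each frameshift (+1, +2, +3 nt), every stop-free codon pair is
#' matched to its frameshift partner (the left-rotation of its 6-mer);
#' pairs whose partner encodes a stop are dropped. The frame-0 side is
#' restricted to one orientation per unordered heterodipeptide class
#' (first residue alphabetically smaller; at most 190 classes after
#' excluding reversed repeats and homodipeptides), so that the +3
#' partner levels come from the reversed-repeat inserts rather than
#' from the same measurements. Levels are averaged within classes and
#' the Pearson correlation between frame-0 and partner class means is
#' reported per shift.
#'
#' @param levels Tibble with `insert_id` (`"<codon1>_<codon2>"`) and
#'   `level` over the dicodon pool.
#' @return Tibble with `shift`, `r`, `n_classes`; a shift with fewer
#'   than 3 complete classes gets `NA` with a warning.
#' @export
frame_correlations <- function(levels) {
  df <- dicodon_levels_frame(levels)
  aa1 <- unname(genetic_code[df$codon1])
  aa2 <- unname(genetic_code[df$codon2])
  level_by_id <- stats::setNames(df$level, df$insert_id)
  stop_free <- aa1 != "*" & aa2 != "*"
  hetero <- stop_free & aa1 < aa2  # one orientation per unordered class
  cls <- paste0(aa1, aa2)
  out <- lapply(1:3, function(shift) {
    partner <- frameshift_partner(df$codon1, df$codon2, shift)
    p_aa1 <- unname(genetic_code[partner$codon1])
    p_aa2 <- unname(genetic_code[partner$codon2])
    ok <- hetero & p_aa1 != "*" & p_aa2 != "*"
    p_level <- level_by_id[paste0(partner$codon1, "_", partner$codon2)]
    ok <- ok & !is.na(df$level) & !is.na(p_level)
    if (!any(ok)) {
      warning("no complete pairs for shift ", shift)
      return(tibble::tibble(shift = shift, r = NA_real_, n_classes = 0L))
    }
    f0 <- tapply(df$level[ok], cls[ok], mean)
    fs <- tapply(p_level[ok], cls[ok], mean)
    n <- length(f0)
    if (n < 3L) {
      warning("fewer than 3 complete classes for shift ", shift)
      return(tibble::tibble(shift = shift, r = NA_real_,
                            n_classes = as.integer(n)))
    }
    tibble::tibble(shift = shift,
                   r = stats::cor(as.numeric(f0), as.numeric(fs)),
                   n_classes = as.integer(n))
  })
  do.call(rbind, out)
}

#' Spearman correlation of levels with a structural propensity
#'
#' Two-sided Spearman rank correlation of insert levels against the
#' Chou-Fasman propensity of the variable residue, e.g. across all
#' Lys-X dipeptides. Exact p-values are used for n <= 10 (no ties),
#' the t-approximation otherwise.
#'
#' @param levels Numeric vector of levels.
#' @param residues Character vector of the variable residues (parallel
#'   to `levels`).
#' @param scale `"cf_strand"` or `"cf_helix"`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
propensity_correlation <- function(levels, residues,
                                   scale = c("cf_strand", "cf_helix")) {
  scale <- match.arg(scale)
  keep <- !is.na(levels)
  levels <- levels[keep]; residues <- residues[keep]
  if (length(levels) < 4L) stop("need at least 4 points", call. = FALSE)
  prop <- scale_lookup(scale)[residues]
  if (anyNA(prop)) stop("non-standard residue in input", call. = FALSE)
  if (stats::sd(prop) == 0) {
    stop("propensity vector is constant; correlation undefined",
         call. = FALSE)
  }
  n <- length(levels)
  ct <- suppressWarnings(
    stats::cor.test(levels, as.numeric(prop), method = "spearman",
                    alternative = "two.sided", exact = n <= 10L)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Pairwise Mann-Whitney U comparisons between groups
#'
#' All pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests
#' between the supplied groups. The exact distribution is used when the
#' two groups together hold at most 20 observations and have no ties;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector parallel to `values`.
#' @return Tibble with `group1`, `group2`, `n1`, `n2`, `p_value`.
#' @export
group_compare <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  pairs <- utils::combn(gl, 2L)
  out <- apply(pairs, 2L, function(p) {
    x <- values[groups == p[1]]
    y <- values[groups == p[2]]
    n_tot <- length(x) + length(y)
    exact <- n_tot <= 20L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = !exact)
    )
    tibble::tibble(group1 = p[1], group2 = p[2],
                   n1 = length(x), n2 = length(y), p_value = wt$p.value)
  })
  do.call(rbind, out)
}
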