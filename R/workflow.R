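# Configuration-driven end-to-end orchestration:
# design -> simulate -> link -> count -> quantify -> analyze.

#' Build a pipeline configuration
#'
#' Collects every tunable of the simulated end-to-end run. All
#' randomness derives from `seed`, which is mandatory.
#'
#' @param seed Integer seed (required).
#' @param design `"dicodon"` for the full 4096-pair pool, or a library
#'   tibble to use directly.
#' @param model A [generative_model()].
#' @param linkage_depth,gdna_depth,mrna_depth Read depths.
#' @param median_barcodes Median barcodes per insert.
#' @param error_rate Per-base substitution probability in all reads.
#' @param dispersion Dirichlet-multinomial count dispersion.
#' @param min_count,collision_distance,max_mismatch Linkage filters.
#' @param min_reads,min_barcodes Quantification filters.
#' @param bootstrap_B Bootstrap replicates (`NULL` = automatic).
#' @param run_analyses Logical; run the positional/model/frame analyses.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            design = "dicodon",
                            model = generative_model(),
                            linkage_depth = 1.2e6,
                            gdna_depth = 2e6,
                            mrna_depth = 2e6,
                            median_barcodes = 15L,
                            error_rate = 0.001,
                            dispersion = 0.2,
                            min_count = 4L,
                            collision_distance = 2L,
                            max_mismatch = 2L,
                            min_reads = 200L,
                            min_barcodes = 6L,
                            bootstrap_B = NULL,
                            run_analyses = TRUE,
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for simulation runs", call. = FALSE)
  }
  stopifnot(min_count >= 1L, collision_distance >= 0L, min_reads >= 0L,
            min_barcodes >= 1L, error_rate >= 0, error_rate < 1,
            dispersion >= 0)
  structure(
    list(seed = as.integer(seed), design = design, model = model,
         linkage_depth = linkage_depth, gdna_depth = gdna_depth,
         mrna_depth = mrna_depth, median_barcodes = median_barcodes,
         error_rate = error_rate, dispersion = dispersion,
         min_count = min_count, collision_distance = collision_distance,
         max_mismatch = max_mismatch, min_reads = min_reads,
         min_barcodes = min_barcodes, bootstrap_B = bootstrap_B,
         run_analyses = run_analyses, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; model coefficients
#' go under a `model:` mapping passed to [generative_model()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$model)) y$model <- do.call(generative_model, y$model)
  do.call(pipeline_config, y)
}

log_stage <- function(log_con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  if (!is.null(log_con)) writeLines(line, log_con)
  message(line)
  invisible(rec)
}

#' Run the simulated assay pipeline end to end
#'
#' Designs (or accepts) the reporter library, simulates true levels and
#' all sequencing read sets under the configured generative model,
#' builds the filtered barcode map, counts barcodes in the gDNA and
#' mRNA samples, quantifies insert levels with bootstrap SEMs, and
#' (optionally) runs the positional, physicochemical-model and
#' frame-correlation analyses. When `out_dir` is set, all tables are
#' written as TSV along with a JSON-lines run log.
#'
#' @param config A [pipeline_config()].
#' @return List with `library`, `truth`, `barcode_map`, `counts`,
#'   `levels`, and (if enabled) `analyses`; invisibly writes files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out_dir <- config$out_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run_log.jsonl"), "w")
    on.exit(close(log_con))
  }
  log_stage(log_con, "start", seed = config$seed,
            package_version = as.character(utils::packageVersion("stallmpra")))

  lib <- if (is.character(config$design) && config$design == "dicodon") {
    enumerate_codon_pairs()
  } else {
    config$design
  }
  log_stage(log_con, "design", n_inserts = nrow(lib))

  truth <- simulate_true_levels(lib, config$model)
  linkage <- simulate_linkage_reads(
    lib, depth = config$linkage_depth,
    median_barcodes = config$median_barcodes,
    error_rate = config$error_rate)
  log_stage(log_con, "simulate_linkage", n_reads = length(linkage$reads),
            n_true_barcodes = nrow(linkage$truth))

  map <- build_barcode_map(linkage, lib, min_count = config$min_count,
                           collision_distance = config$collision_distance,
                           max_mismatch = config$max_mismatch)
  kept <- kept_barcodes(map)
  log_stage(log_con, "link", n_kept = nrow(kept),
            n_filtered = nrow(map) - nrow(kept),
            ambiguous_reads = attr(map, "ambiguous_reads"))

  sim_counts <- simulate_count_reads(
    truth, kept[c("barcode", "insert_id")],
    gdna_depth = config$gdna_depth, mrna_depth = config$mrna_depth,
    dispersion = config$dispersion, error_rate = config$error_rate)
  gdna_ct <- count_barcodes(sim_counts$gdna, map)
  mrna_ct <- count_barcodes(sim_counts$mrna, map)
  log_stage(log_con, "count",
            gdna_reads = length(sim_counts$gdna$reads),
            mrna_reads = length(sim_counts$mrna$reads),
            gdna_unmatched = attr(gdna_ct, "unmatched"),
            mrna_unmatched = attr(mrna_ct, "unmatched"))

  levels <- insert_levels(mrna_ct, gdna_ct, min_reads = config$min_reads,
                          min_barcodes = config$min_barcodes)
  levels <- add_bootstrap_sem(levels, mrna_ct, gdna_ct, B = config$bootstrap_B)
  log_stage(log_con, "quantify",
            n_ok = sum(levels$status == "ok"),
            n_missing = sum(levels$status == "missing"))

  analyses <- NULL
  if (isTRUE(config$run_analyses) && all(grepl("^[ACGT]{3}_[ACGT]{3}$",
                                               lib$insert_id))) {
    pos <- positional_effects(levels)
    dipep <- merge_levels_truth(levels, truth)
    stop_free <- dipep[!dipep$has_stop & dipep$status == "ok", ]
    fit <- fit_physicochemical_model(
      tibble::tibble(dipeptide = substring(stop_free$peptide, 1L, 2L),
                     level = stop_free$level),
      features = c("pI", "bulkiness", "pI:bulkiness", "cf_strand"))
    frames <- frame_correlations(levels)
    recovery <- stats::cor(dipep$true_level[dipep$status == "ok"],
                           dipep$level[dipep$status == "ok"],
                           method = "spearman")
    analyses <- list(positional = pos, model = fit, frames = frames,
                     spearman_truth = recovery)
    log_stage(log_con, "analyze",
              spearman_truth = round(recovery, 4),
              adjusted_r2 = round(fit$adjusted_r2, 4))
  }

  if (!is.null(out_dir)) {
    write_library_manifest(lib, file.path(out_dir, "library_manifest.tsv"))
    write_barcode_map(map, file.path(out_dir, "barcode_map.tsv.gz"))
    utils::write.table(levels, file.path(out_dir, "insert_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(analyses)) {
      utils::write.table(analyses$positional,
                         file.path(out_dir, "positional_effects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(analyses$frames,
                         file.path(out_dir, "frame_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_stage(log_con, "write", out_dir = out_dir)
  }
  log_stage(log_con, "done")
  list(library = lib, truth = truth, barcode_map = map,
       counts = list(gdna = gdna_ct, mrna = mrna_ct),
       levels = levels, analyses = analyses)
}

# Join quantified levels with simulator truth and library peptides.
merge_levels_truth <- function(levels, truth) {
  lib <- enumerate_codon_pairs()
  out <- dplyr::left_join(levels, truth, by = "insert_id")
  dplyr::left_join(out, lib[c("insert_id", "peptide")], by = "insert_id")
}
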