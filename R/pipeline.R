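#' Build a validated pipeline configuration
#'
#' Collects the parameters of the scaffold-binning pipeline and validates
#' them before any computation. Exactly one input source must be given:
#' `simulate` (a list of simulator parameters), `count_matrix` (path to a
#' matrix TSV written by [write_count_matrix()]), or `sam_files` plus
#' `scaffold_lengths` (named vector of per-well SAM paths and a lengths
#' file).
#'
#' @param simulate Optional list with elements among `n_chromosomes`,
#'   `n_wells`, `per_well_min`, `per_well_max`, `n_empty_wells`,
#'   `scaffolds_per_chromosome`, `mean_chromosome_length`, `depth`,
#'   `background_rate`, `require_distinct`, `noise`.
#' @param count_matrix Optional path to a count-matrix TSV.
#' @param sam_files Optional named character vector (names = well ids) of
#'   SAM files.
#' @param scaffold_lengths Path to a FASTA or two-column length table
#'   (required with `sam_files`).
#' @param min_mapq,min_scaffold_length,insert_min,insert_max,read_length
#'   Alignment filtering and tallying parameters.
#' @param k_min,k_max,restarts Clustering sweep parameters.
#' @param mode Clustering space: `"standardized"` profiles (default) or
#'   rows of the `"correlation"` matrix.
#' @param relative_threshold Occupancy binarization threshold (used by the
#'   `"relative"` peak rule).
#' @param binarize_method Peak rule for [binarize_configuration()]:
#'   `"split"` (default, robust to well crowding) or `"relative"`.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param output_dir Directory where [run_pipeline()] writes artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL,
                            count_matrix = NULL,
                            sam_files = NULL,
                            scaffold_lengths = NULL,
                            min_mapq = 30,
                            min_scaffold_length = 7000,
                            insert_min = NULL,
                            insert_max = NULL,
                            read_length = 100,
                            k_min = 2,
                            k_max = 20,
                            restarts = 10,
                            mode = c("standardized", "correlation"),
                            relative_threshold = 0.5,
                            binarize_method = c("split", "relative"),
                            seed = 1L,
                            output_dir = tempfile("chrompool_")) {
  mode <- match.arg(mode)
  binarize_method <- match.arg(binarize_method)
  sources <- c(!is.null(simulate), !is.null(count_matrix),
               !is.null(sam_files))
  if (sum(sources) != 1)
    stop("give exactly one input source: `simulate`, `count_matrix`, or ",
         "`sam_files`", call. = FALSE)
  if (k_min > k_max || k_min < 1)
    stop("need 1 <= k_min <= k_max", call. = FALSE)
  if (!is.null(count_matrix) && !file.exists(count_matrix))
    stop("count matrix file not found: ", count_matrix, call. = FALSE)
  if (!is.null(sam_files)) {
    if (is.null(names(sam_files)))
      stop("`sam_files` must be named by well id", call. = FALSE)
    missing <- sam_files[!file.exists(sam_files)]
    if (length(missing))
      stop("SAM file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (is.null(scaffold_lengths) || !file.exists(scaffold_lengths))
      stop("`scaffold_lengths` file is required with `sam_files`",
           call. = FALSE)
  }
  structure(
    list(simulate = simulate, count_matrix = count_matrix,
         sam_files = sam_files, scaffold_lengths = scaffold_lengths,
         min_mapq = min_mapq, min_scaffold_length = min_scaffold_length,
         insert_min = insert_min, insert_max = insert_max,
         read_length = read_length, k_min = k_min, k_max = k_max,
         restarts = restarts, mode = mode,
         relative_threshold = relative_threshold,
         binarize_method = binarize_method,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds derived from the one global seed
  offsets <- c(simulate = 101L, cluster = 211L)
  (seed * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the scaffold-binning pipeline end to end
#'
#' Executes count acquisition (simulation, count-table input, or SAM
#' tallying), normalization, the K sweep with knee selection, occupancy
#' deduction, and the meta-scaffold report, writing every artifact as plain
#' text under `config$output_dir`. Runs are byte-identical for identical
#' configuration, inputs, and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `normalized`, `curve`, `k`, `fit`, `config_result`, `report`, `truth`
#'   when simulated) and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL

  if (!is.null(config$simulate)) {
    s <- config$simulate
    kar <- generate_karyotype(
      n_chromosomes = s$n_chromosomes %||% 13,
      mean_chromosome_length = s$mean_chromosome_length %||% 16e6,
      scaffolds_per_chromosome = s$scaffolds_per_chromosome %||% 115,
      min_scaffold_length = config$min_scaffold_length,
      seed = stage_seed(config$seed, "simulate")
    )
    plan <- generate_pool_plan(
      kar,
      n_wells = s$n_wells %||% 21,
      per_well_min = s$per_well_min %||% 1,
      per_well_max = s$per_well_max %||% 4,
      n_empty_wells = s$n_empty_wells %||% 0,
      require_distinct = isTRUE(s$require_distinct),
      seed = stage_seed(config$seed, "simulate") + 1L
    )
    sim <- simulate_count_matrix(
      kar, plan,
      depth = s$depth %||% 0.01,
      background_rate = s$background_rate %||% 5e-4,
      read_length = config$read_length,
      noise = s$noise %||% "poisson",
      seed = stage_seed(config$seed, "simulate") + 2L
    )
    counts <- sim$counts
    truth <- sim$truth
  } else if (!is.null(config$count_matrix)) {
    counts <- read_count_matrix(config$count_matrix)
  } else {
    lengths <- read_scaffold_lengths(config$scaffold_lengths)
    records <- purrr::imap_dfr(config$sam_files, function(p, well) {
      parse_alignments(p, well_id = well, permissive = TRUE)
    })
    records <- filter_alignments(records, min_mapq = config$min_mapq,
                                 insert_min = config$insert_min,
                                 insert_max = config$insert_max)
    counts <- tally_counts(records, lengths,
                           min_scaffold_length = config$min_scaffold_length,
                           read_length = config$read_length)
  }

  nm <- normalize_counts(counts)
  profiles <- switch(config$mode,
    standardized = standardize_profiles(nm),
    correlation = pearson_matrix(nm)
  )
  k_max <- min(config$k_max, nrow(profiles))
  curve <- k_sweep(profiles, k_min = config$k_min, k_max = k_max,
                   restarts = config$restarts,
                   seed = stage_seed(config$seed, "cluster"))
  k <- select_k_knee(curve)
  fit <- attr(curve, "fits")[[as.character(k)]]
  M <- cluster_well_means(nm, fit)
  config_result <- binarize_configuration(
    M, relative_threshold = config$relative_threshold,
    method = config$binarize_method)
  lengths_tbl <- unique(counts[, c("scaffold_id", "scaffold_length")])
  report <- metascaffold_report(fit, lengths_tbl)

  pars <- list(seed = config$seed, mode = config$mode,
               min_mapq = config$min_mapq,
               min_scaffold_length = config$min_scaffold_length,
               k_min = config$k_min, k_max = k_max,
               restarts = config$restarts,
               relative_threshold = config$relative_threshold,
               binarize_method = config$binarize_method)
  paths <- list(
    counts = file.path(config$output_dir, "count_matrix.tsv"),
    normalized = file.path(config$output_dir, "normalized_matrix.tsv"),
    curve = file.path(config$output_dir, "k_sweep.csv"),
    labels = file.path(config$output_dir, "labels.tsv"),
    occupancy = file.path(config$output_dir, "occupancy.json"),
    report = file.path(config$output_dir, "metascaffold_report.tsv")
  )
  write_count_matrix(counts, paths$counts, pars)
  write_normalized_matrix(nm, paths$normalized, pars)
  write_sweep_curve(curve, paths$curve, pars)
  write_labels(fit, paths$labels, pars)
  write_occupancy_json(config_result, paths$occupancy)
  write_tsv_commented(report, paths$report, pars)

  invisible(list(counts = counts, normalized = nm, curve = curve, k = k,
                 fit = fit, config_result = config_result, report = report,
                 truth = truth, paths = paths))
}
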