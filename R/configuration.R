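#' Mean normalized profile of each cluster across wells
#'
#' Averages the normalized read values of all scaffolds in a cluster,
#' per well. A peak in a cluster's per-well means indicates that the
#' chromosome behind the cluster was present in that well.
#'
#' @param nm A `normalized_matrix` from [normalize_counts()].
#' @param labels A `pool_kmeans` fit or a tibble with columns
#'   `scaffold_id`, `cluster`. Scaffolds of the matrix without a label
#'   (e.g. zero-variance profiles excluded from clustering) are ignored.
#' @return Numeric cluster-by-well matrix of mean normalized values.
#' @export
cluster_well_means <- function(nm, labels) {
  stopifnot(inherits(nm, "normalized_matrix"))
  labels <- as_label_table(labels)
  joined <- dplyr::inner_join(nm, labels, by = "scaffold_id")
  if (!nrow(joined))
    stop("labels cover none of the scaffolds in the matrix", call. = FALSE)
  means <- joined |>
    dplyr::group_by(.data$cluster, .data$well_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "well_id", values_from = "value",
                       values_fill = 0)
  m <- as.matrix(means[, -1, drop = FALSE])
  rownames(m) <- as.character(means$cluster)
  num <- suppressWarnings(as.numeric(rownames(m)))
  m[order(if (anyNA(num)) rownames(m) else num), , drop = FALSE]
}

as_label_table <- function(labels) {
  if (inherits(labels, "pool_kmeans")) return(labels$labels)
  if (is.data.frame(labels) &&
      all(c("scaffold_id", "cluster") %in% names(labels)))
    return(tibble::as_tibble(labels)[, c("scaffold_id", "cluster")])
  stop("`labels` must be a pool_kmeans fit or a (scaffold_id, cluster) table",
       call. = FALSE)
}

#' Deduce the binary chromosome-by-well occupancy configuration
#'
#' Calls a chromosome (cluster) present in a well when the cluster's mean
#' normalized value in that well peaks above background — the computational
#' analogue of reading presence off the per-well peak plots. Two peak
#' rules are available. `"relative"` calls a well occupied when its mean
#' reaches `relative_threshold` times the row maximum. `"split"` (the
#' pipeline default) performs a two-level 1-D split of the row (2-means)
#' and calls the upper level occupied; this is robust to well crowding:
#' because normalization divides by the well total, a chromosome sharing a
#' well with three others shows roughly a quarter of the signal it shows in
#' a singleton well, which a fixed fraction of the row maximum can miss.
#' Rows with all-zero means cannot be called and are flagged.
#'
#' @param M Cluster-by-well matrix of mean normalized values, from
#'   [cluster_well_means()].
#' @param relative_threshold Fraction of the row maximum above which a well
#'   is called occupied (default 0.5; `"relative"` method only).
#' @param method Peak rule, `"relative"` or `"split"` (see above).
#' @return A `well_configuration` object: a tidy tibble with columns
#'   `cluster`, `well_id`, `mean_value`, `present` (0/1), plus attributes
#'   `occupancy` (binary matrix), `threshold`, `method`, and `flagged`
#'   (all-zero clusters).
#' @export
binarize_configuration <- function(M, relative_threshold = 0.5,
                                   method = c("relative", "split")) {
  stopifnot(is.matrix(M))
  method <- match.arg(method)
  if (any(M < 0)) stop("cluster means must be nonnegative", call. = FALSE)
  if (relative_threshold <= 0 || relative_threshold > 1)
    stop("`relative_threshold` must be in (0, 1]", call. = FALSE)
  row_max <- apply(M, 1, max)
  flagged <- rownames(M)[row_max == 0]
  if (method == "relative") {
    B <- (M >= relative_threshold * row_max) * 1L
  } else {
    B <- t(apply(M, 1, split_row_two_levels))
    dimnames(B) <- dimnames(M)
  }
  B[row_max == 0, ] <- 0L
  out <- tibble::as_tibble(as.data.frame.table(M, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- c("cluster", "well_id", "mean_value")
  out$present <- as.integer(B[cbind(out$cluster, out$well_id)])
  out <- out[order(out$cluster, out$well_id), ]
  structure(
    out,
    occupancy = B,
    threshold = relative_threshold,
    method = method,
    flagged = flagged,
    class = c("well_configuration", class(tibble::tibble()))
  )
}

# deterministic two-level 1-D split on the log scale (Lloyd iterations from
# the extremes); signal scales multiplicatively with well crowding, so peaks
# and background separate on log values. Returns 1 for the upper level.
split_row_two_levels <- function(v) {
  if (max(v) == min(v)) return(as.integer(v > 0))
  x <- log10(v + max(v) * 1e-6)
  lo <- min(x); hi <- max(x)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    upper <- x > mid
    lo_new <- mean(x[!upper]); hi_new <- mean(x[upper])
    if (isTRUE(all.equal(c(lo_new, hi_new), c(lo, hi)))) break
    lo <- lo_new; hi <- hi_new
  }
  as.integer(x > (lo + hi) / 2)
}

#' Occupancy matrix of a deduced configuration
#'
#' @param config A `well_configuration`.
#' @return Binary cluster-by-well matrix.
#' @export
configuration_occupancy <- function(config) {
  stopifnot(inherits(config, "well_configuration"))
  attr(config, "occupancy")
}

#' Wells carrying chromosome information
#'
#' A well is informative when at least one chromosome cluster was called
#' present in it; wells containing only background reads contribute nothing
#' to separating the clusters.
#'
#' @param config A `well_configuration`.
#' @return Character vector of informative well ids.
#' @export
informative_wells <- function(config) {
  B <- configuration_occupancy(config)
  colnames(B)[colSums(B) > 0]
}

#' Number of chromosomes deduced per well
#'
#' @param config A `well_configuration`.
#' @return Tibble with `well_id` and `n_chromosomes` (column sums of the
#'   occupancy matrix).
#' @export
chromosomes_per_well <- function(config) {
  B <- configuration_occupancy(config)
  tibble::tibble(well_id = colnames(B), n_chromosomes = unname(colSums(B)))
}

#' Per-cluster meta-scaffold summary
#'
#' Summarizes each chromosome cluster as a meta-scaffold: number of
#' scaffolds, total length, and N50 of its scaffold lengths. Grand means
#' across clusters are attached as the `grand_means` attribute and shown by
#' [glance.pool_kmeans()].
#'
#' @param labels A `pool_kmeans` fit or a (`scaffold_id`, `cluster`) table.
#' @param scaffold_lengths Data frame (`scaffold_id`, `scaffold_length`) or
#'   named vector of lengths in bp.
#' @return Tibble with columns `cluster`, `n_scaffolds`, `total_bp`, `n50`,
#'   sorted by cluster; attribute `grand_means` holds the means of
#'   `total_bp` and `n50` across clusters.
#' @export
metascaffold_report <- function(labels, scaffold_lengths) {
  labels <- as_label_table(labels)
  len <- as_length_table(scaffold_lengths)
  missing_len <- setdiff(labels$scaffold_id, names(len))
  if (length(missing_len))
    stop("no length known for scaffold(s): ",
         paste(utils::head(missing_len, 5), collapse = ", "), call. = FALSE)
  rep_tbl <- labels |>
    dplyr::mutate(scaffold_length = len[.data$scaffold_id]) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_scaffolds = dplyr::n(),
      total_bp = sum(.data$scaffold_length),
      n50 = n50(.data$scaffold_length),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
  attr(rep_tbl, "grand_means") <- tibble::tibble(
    mean_total_bp = mean(rep_tbl$total_bp),
    mean_n50 = mean(rep_tbl$n50)
  )
  rep_tbl
}

#' Compare inferred labels and configuration against simulation truth
#'
#' Scores a clustering of simulated data with permutation-invariant
#' metrics: the adjusted Rand index between inferred cluster labels and the
#' true scaffold-to-chromosome assignment, and the fraction of clusters
#' whose deduced well-occupancy vector exactly equals the configuration of
#' the chromosome contributing most of the cluster's scaffolds.
#'
#' @param labels A `pool_kmeans` fit or label table for simulated scaffolds.
#' @param config Optional `well_configuration` deduced from the same
#'   clustering; when `NULL` only the ARI is computed.
#' @param truth A `sim_truth` from [simulate_count_matrix()].
#' @return One-row tibble with `ari`, `config_match_fraction` (`NA` when no
#'   configuration is supplied), `n_scaffolds`, `n_clusters`.
#' @export
evaluate_against_truth <- function(labels, config = NULL, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- as_label_table(labels)
  joined <- dplyr::inner_join(labels, truth$scaffold_to_chromosome,
                              by = "scaffold_id")
  ari <- mclust::adjustedRandIndex(joined$cluster, joined$chromosome_id)

  match_frac <- NA_real_
  if (!is.null(config)) {
    B <- configuration_occupancy(config)
    occ <- truth$chromosome_to_wells
    shared <- intersect(colnames(B), colnames(occ))
    per_cluster <- joined |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        chromosome_id = names(which.max(table(.data$chromosome_id))),
        .groups = "drop"
      )
    hits <- vapply(seq_len(nrow(per_cluster)), function(i) {
      cl <- as.character(per_cluster$cluster[i])
      ch <- per_cluster$chromosome_id[i]
      cl %in% rownames(B) &&
        identical(unname(B[cl, shared]), unname(occ[ch, shared]))
    }, logical(1))
    match_frac <- mean(hits)
  }
  tibble::tibble(
    ari = ari,
    config_match_fraction = match_frac,
    n_scaffolds = nrow(joined),
    n_clusters = dplyr::n_distinct(labels$cluster)
  )
}
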