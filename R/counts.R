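#' Construct a count matrix
#'
#' A `count_matrix` is a tidy (long) tibble with one row per scaffold-well
#' cell: columns `scaffold_id`, `scaffold_length`, `well_id`, `count`
#' (retained reads) and `covered_bases` (bases of the scaffold covered by at
#' least one retained read). Every scaffold appears in every well.
#'
#' @param x A data frame with the five columns above.
#' @return The validated tibble with class `count_matrix`.
#' @export
new_count_matrix <- function(x) {
  need <- c("scaffold_id", "scaffold_length", "well_id", "count",
            "covered_bases")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("count matrix is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- tibble::as_tibble(x)[need]
  if (any(x$count < 0) || any(x$count != round(x$count)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(x$covered_bases < 0) || any(x$covered_bases > x$scaffold_length))
    stop("covered bases must lie in [0, scaffold_length]", call. = FALSE)
  if (anyDuplicated(x[, c("scaffold_id", "well_id")]))
    stop("duplicated (scaffold_id, well_id) cell", call. = FALSE)
  len <- unique(x[, c("scaffold_id", "scaffold_length")])
  if (anyDuplicated(len$scaffold_id))
    stop("inconsistent lengths for a scaffold across wells", call. = FALSE)
  class(x) <- c("count_matrix", class(tibble::tibble()))
  x
}

#' Per-well read totals
#'
#' @param counts A [count_matrix].
#' @return Tibble with `well_id` and `total` (sum of counts over scaffolds).
#' @export
well_totals <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  counts |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

# scaffold x well numeric matrix from a long column
cm_wide <- function(x, value_col) {
  wide <- tidyr::pivot_wider(
    x[, c("scaffold_id", "well_id", value_col)],
    names_from = "well_id", values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$scaffold_id
  m
}

#' Depth- and coverage-normalize a count matrix
#'
#' Implements the two-step normalization applied to pooled chromosome
#' preparations: each count is divided by the total number of reads in its
#' well (preparation), then scaled by the fractional coverage of the
#' scaffold in that well:
#' \deqn{n_{ij} = \frac{c_{ij}}{T_j} \cdot \frac{v_{ij}}{L_i}}
#' Dividing by the well total makes wells with different sequencing depths
#' comparable; the breadth-of-coverage factor down-weights counts that pile
#' up on a small part of a scaffold (e.g. a repeat) rather than covering it.
#'
#' @param counts A [count_matrix].
#' @param coverage One of `"per_well"` (default): breadth computed per
#'   scaffold and well, or `"pooled"`: a single per-scaffold breadth (the
#'   maximum across wells) applied to all wells of that scaffold.
#' @return A `normalized_matrix` tibble with columns `scaffold_id`,
#'   `well_id`, `value`. Wells whose total is zero are dropped with a
#'   warning.
#' @export
#' @examples
#' cm <- new_count_matrix(tibble::tibble(
#'   scaffold_id = rep(c("s1", "s2"), each = 2),
#'   scaffold_length = rep(c(100, 100), each = 2),
#'   well_id = rep(c("W1", "W2"), 2),
#'   count = c(8, 0, 2, 5),
#'   covered_bases = c(100, 0, 100, 100)
#' ))
#' normalize_counts(cm)
normalize_counts <- function(counts, coverage = c("per_well", "pooled")) {
  stopifnot(inherits(counts, "count_matrix"))
  coverage <- match.arg(coverage)
  tot <- well_totals(counts)
  empty <- tot$well_id[tot$total == 0]
  if (length(empty) == nrow(tot))
    stop("all wells have zero total reads; nothing to normalize",
         call. = FALSE)
  if (length(empty)) {
    warning("dropping ", length(empty), " well(s) with zero total reads: ",
            paste(empty, collapse = ", "), call. = FALSE)
    counts <- counts[!counts$well_id %in% empty, ]
    tot <- tot[!tot$well_id %in% empty, ]
  }
  nm <- counts |>
    dplyr::left_join(tot, by = "well_id") |>
    dplyr::mutate(
      breadth = .data$covered_bases / .data$scaffold_length,
      value = (.data$count / .data$total) * .data$breadth
    )
  if (coverage == "pooled") {
    nm <- nm |>
      dplyr::group_by(.data$scaffold_id) |>
      dplyr::mutate(value = (.data$count / .data$total) *
                      max(.data$breadth)) |>
      dplyr::ungroup()
  }
  out <- nm[, c("scaffold_id", "well_id", "value")]
  class(out) <- c("normalized_matrix", class(tibble::tibble()))
  attr(out, "coverage") <- coverage
  out
}

#' Scaffold-by-well matrix view of a normalized matrix
#'
#' @param nm A `normalized_matrix`.
#' @return Numeric matrix, scaffolds in rows, wells in columns.
#' @export
normalized_wide <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  cm_wide(nm, "value")
}
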