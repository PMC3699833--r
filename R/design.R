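#' Probability that a well captures two copies of a repeat family
#'
#' Models the key design quantity of dilution-pool (long-fragment)
#' sequencing: limiting the number of amplifiable molecules per barcoded
#' well keeps repeats present as single copies, so per-well subassembly can
#' resolve them. With `m` fragments of length `fragment_length` placed
#' independently and uniformly on a genome of size `genome_size`, a given
#' copy of a repeat of unit length `repeat_unit_length` is overlapped by at
#' least one fragment with probability
#' `q = 1 - (1 - (fragment_length + repeat_unit_length - 1)/genome_size)^m`.
#' Treating the `repeat_copies` copies as independent (valid while
#' `repeat_copies * (fragment_length + repeat_unit_length) << genome_size`),
#' the probability that two or more distinct copies are captured in the
#' same well is
#' `1 - (1-q)^n - n q (1-q)^(n-1)`.
#'
#' @param molecules_per_well Number of amplifiable fragments per well (m).
#' @param genome_size Genome size in bp (G).
#' @param fragment_length Fragment length in bp.
#' @param repeat_copies Number of copies of the repeat family in the genome
#'   (n).
#' @param repeat_unit_length Length of one repeat copy in bp.
#' @return Probability in [0, 1]; 0 when `repeat_copies < 2` or
#'   `molecules_per_well == 0`.
#' @export
#' @examples
#' repeat_collision_probability(500, 6e8, 7000, 100, 1000)
repeat_collision_probability <- function(molecules_per_well,
                                         genome_size,
                                         fragment_length,
                                         repeat_copies,
                                         repeat_unit_length) {
  m <- molecules_per_well
  if (m < 0 || repeat_copies < 0 || fragment_length <= 0 ||
      repeat_unit_length <= 0 || genome_size <= 0)
    stop("design parameters must be nonnegative (lengths positive)",
         call. = FALSE)
  if (fragment_length + repeat_unit_length > genome_size)
    stop("fragment and repeat unit exceed the genome size: degenerate ",
         "placement geometry", call. = FALSE)
  if (repeat_copies < 2 || m == 0) return(0)
  p_one <- (fragment_length + repeat_unit_length - 1) / genome_size
  q <- 1 - (1 - p_one)^m
  n <- repeat_copies
  1 - (1 - q)^n - n * q * (1 - q)^(n - 1)
}

#' Consensus error rate under majority vote
#'
#' Over-sequencing every well lets the per-well consensus correct the
#' sequencer's intrinsic error rate: with `coverage` independent reads each
#' wrong with probability `error_rate`, the majority-vote consensus is wrong
#' when more than half the reads err. Exact ties at even coverage are
#' counted as errors (conservative).
#'
#' @param error_rate Per-read error probability in [0, 1].
#' @param coverage Number of independent reads covering the position
#'   (integer >= 1). Vectorized over both arguments.
#' @return Probability the consensus base is wrong.
#' @export
#' @examples
#' consensus_error_rate(0.01, 5)  # ~1e-5: reduced by the coverage
consensus_error_rate <- function(error_rate, coverage) {
  if (any(error_rate < 0) || any(error_rate > 1))
    stop("`error_rate` must be in [0, 1]", call. = FALSE)
  if (any(coverage < 1) || any(coverage != round(coverage)))
    stop("`coverage` must be a positive integer", call. = FALSE)
  # errors win at k > c/2; an exact tie (even c, k = c/2) counts as error
  k_err <- ifelse(coverage %% 2 == 0, coverage / 2, (coverage + 1) / 2)
  stats::pbinom(k_err - 1, size = coverage, prob = error_rate,
                lower.tail = FALSE)
}

#' N50 of a set of contig or scaffold lengths
#'
#' The length of the element at which the cumulative sum of the
#' descending-sorted lengths first reaches half of the total.
#'
#' @param lengths Numeric vector of positive lengths in bp.
#' @return The N50 in bp.
#' @export
#' @examples
#' n50(c(2, 3, 4, 5, 7))  # 5
n50 <- function(lengths) {
  if (!length(lengths)) stop("`lengths` must be nonempty", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Fold coverage of a genome
#'
#' @param total_bases Total sequenced bases.
#' @param genome_size Genome size in bp (> 0).
#' @return `total_bases / genome_size`, unrounded.
#' @export
#' @examples
#' coverage_fold(6683e6, 600e6)  # ~11.1-fold
coverage_fold <- function(total_bases, genome_size) {
  if (any(genome_size <= 0))
    stop("`genome_size` must be positive", call. = FALSE)
  if (any(total_bases < 0))
    stop("`total_bases` must be nonnegative", call. = FALSE)
  total_bases / genome_size
}

#' Collision-probability table over a molecules-per-well grid
#'
#' Convenience table for choosing the dilution level: for each candidate
#' number of molecules per well and each repeat family, the probability that
#' a well captures two or more distinct copies of the family.
#'
#' @param molecules_grid Vector of candidate molecules-per-well values.
#' @param genome_size,fragment_length As in
#'   [repeat_collision_probability()].
#' @param families Data frame with columns `repeat_copies` and
#'   `repeat_unit_length`, one row per repeat family (an optional `family`
#'   column names them).
#' @return Tibble with one row per (molecules per well, family) pair and a
#'   `collision_probability` column.
#' @export
design_grid <- function(molecules_grid, genome_size, fragment_length,
                        families) {
  stopifnot(is.data.frame(families),
            all(c("repeat_copies", "repeat_unit_length") %in%
                  names(families)))
  fam <- tibble::as_tibble(families)
  if (!"family" %in% names(fam))
    fam$family <- sprintf("family_%d", seq_len(nrow(fam)))
  tidyr::expand_grid(molecules_per_well = molecules_grid, fam) |>
    dplyr::mutate(
      collision_probability = purrr::pmap_dbl(
        list(.data$molecules_per_well, .data$repeat_copies,
             .data$repeat_unit_length),
        function(m, n, r) repeat_collision_probability(
          m, genome_size, fragment_length, n, r)
      )
    )
}
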