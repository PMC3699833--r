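#' Generate a synthetic karyotype
#'
#' Builds a karyotype for simulated chromosome-pool experiments: a set of
#' chromosomes and a set of assembly scaffolds, each scaffold assigned to
#' exactly one chromosome. Scaffold lengths are drawn from a log-normal
#' distribution truncated below at `min_scaffold_length`, so that every
#' simulated scaffold survives the downstream contig-size filter by
#' construction.
#'
#' @param n_chromosomes Number of chromosomes (haploid count), >= 1.
#' @param mean_chromosome_length Target chromosome length in bp.
#' @param scaffolds_per_chromosome Number of scaffolds drawn per chromosome.
#' @param scaffold_length_sdlog Log-scale standard deviation of scaffold
#'   lengths; larger values give a heavier-tailed size distribution.
#' @param min_scaffold_length Lower truncation bound for scaffold lengths in
#'   bp. The default mirrors the 7 kb contig-size filter applied when
#'   tabulating real alignments.
#' @param assembly_fraction Fraction of each chromosome expected to be
#'   covered by scaffolds; scales the scaffold length distribution.
#' @param seed Integer seed; the same seed always reproduces the same
#'   karyotype.
#'
#' @return A `karyotype` object: a list with tibbles `chromosomes`
#'   (`chromosome_id`, `chromosome_length`) and `scaffolds` (`scaffold_id`,
#'   `scaffold_length`, `chromosome_id`).
#' @export
#' @examples
#' kar <- generate_karyotype(3, 2e6, scaffolds_per_chromosome = 10, seed = 1)
#' kar$scaffolds
generate_karyotype <- function(n_chromosomes,
                               mean_chromosome_length = 16e6,
                               scaffolds_per_chromosome = 150,
                               scaffold_length_sdlog = 0.7,
                               min_scaffold_length = 7000,
                               assembly_fraction = 0.9,
                               seed = 1L) {
  stopifnot(is.numeric(n_chromosomes), length(n_chromosomes) == 1)
  if (n_chromosomes < 1 || scaffolds_per_chromosome < 1)
    stop("`n_chromosomes` and `scaffolds_per_chromosome` must be >= 1",
         call. = FALSE)
  if (mean_chromosome_length <= 0 || min_scaffold_length <= 0)
    stop("lengths must be positive", call. = FALSE)
  if (assembly_fraction <= 0 || assembly_fraction > 1)
    stop("`assembly_fraction` must be in (0, 1]", call. = FALSE)

  target_mean <- assembly_fraction * mean_chromosome_length /
    scaffolds_per_chromosome
  if (target_mean < min_scaffold_length)
    stop("chromosome length too short for the requested number of ",
         "scaffolds at `min_scaffold_length`", call. = FALSE)
  meanlog <- log(target_mean) - scaffold_length_sdlog^2 / 2

  withr::with_seed(seed, {
    chrom_ids <- sprintf("chr%02d", seq_len(n_chromosomes))
    n_scaff <- n_chromosomes * scaffolds_per_chromosome
    # inverse-CDF draw from the left-truncated log-normal
    p_lo <- stats::plnorm(min_scaffold_length, meanlog, scaffold_length_sdlog)
    u <- stats::runif(n_scaff, min = p_lo, max = 1)
    scaff_len <- round(stats::qlnorm(u, meanlog, scaffold_length_sdlog))
    scaff_chr <- rep(chrom_ids, each = scaffolds_per_chromosome)

    scaffolds <- tibble::tibble(
      scaffold_id = sprintf("scaffold_%04d", seq_len(n_scaff)),
      scaffold_length = as.numeric(scaff_len),
      chromosome_id = scaff_chr
    )
    per_chr_sum <- scaffolds |>
      dplyr::group_by(.data$chromosome_id) |>
      dplyr::summarise(total = sum(.data$scaffold_length), .groups = "drop")
    # nominal length with mild biological variation; never shorter than the
    # scaffolds it must contain
    nominal <- round(mean_chromosome_length *
                       exp(stats::rnorm(n_chromosomes, 0, 0.1)))
    chromosomes <- tibble::tibble(
      chromosome_id = chrom_ids,
      chromosome_length = pmax(as.numeric(nominal), per_chr_sum$total)
    )
    structure(
      list(chromosomes = chromosomes, scaffolds = scaffolds),
      seed = seed,
      class = "karyotype"
    )
  })
}

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$scaffolds), " scaffolds, ",
      format(sum(x$scaffolds$scaffold_length), big.mark = ","),
      " bp in scaffolds\n", sep = "")
  invisible(x)
}

#' Generate a dilution-pool plan
#'
#' Assigns a random subset of chromosomes to each well, emulating the
#' limiting-dilution loading of metaphase chromosomes into microfluidic
#' wells. Subset sizes are drawn uniformly between `per_well_min` and
#' `per_well_max`, and chromosomes within a well are sampled without
#' replacement.
#'
#' @param karyotype A `karyotype` from [generate_karyotype()].
#' @param n_wells Number of loaded wells (default 21).
#' @param per_well_min,per_well_max Bounds on the number of chromosomes per
#'   loaded well (defaults 1 and 4).
#' @param n_empty_wells Number of additional wells that received no
#'   chromosome and will carry only background reads; useful for emulating
#'   experiments where only part of the wells are informative.
#' @param require_distinct If `TRUE`, redraw the plan until every chromosome
#'   occupies at least one well and no two chromosomes share the same
#'   well-occupancy configuration vector, so all chromosomes are
#'   identifiable in principle.
#' @param max_tries Maximum redraws attempted when `require_distinct = TRUE`.
#' @param seed Integer seed.
#'
#' @return A `pool_plan`: a tibble with one row per (well, chromosome)
#'   loading, plus attributes recording all well ids (including empty
#'   wells), the bounds, and the seed.
#' @export
generate_pool_plan <- function(karyotype,
                               n_wells = 21,
                               per_well_min = 1,
                               per_well_max = 4,
                               n_empty_wells = 0,
                               require_distinct = FALSE,
                               max_tries = 1000,
                               seed = 1L) {
  stopifnot(inherits(karyotype, "karyotype"))
  chrom_ids <- karyotype$chromosomes$chromosome_id
  n_chrom <- length(chrom_ids)
  if (per_well_min < 1 || per_well_min > per_well_max ||
      per_well_max > n_chrom)
    stop("need 1 <= per_well_min <= per_well_max <= number of chromosomes",
         call. = FALSE)
  if (n_wells < 1 || n_empty_wells < 0)
    stop("`n_wells` must be >= 1 and `n_empty_wells` >= 0", call. = FALSE)

  well_ids <- sprintf("W%02d", seq_len(n_wells + n_empty_wells))
  loaded <- well_ids[seq_len(n_wells)]

  draw_plan <- function() {
    sizes <- if (per_well_min == per_well_max) {
      rep(per_well_min, n_wells)
    } else {
      sample(seq(per_well_min, per_well_max), n_wells, replace = TRUE)
    }
    purrr::map2_dfr(loaded, sizes, function(w, s) {
      tibble::tibble(well_id = w, chromosome_id = sample(chrom_ids, s))
    })
  }

  withr::with_seed(seed, {
    plan_tbl <- draw_plan()
    if (require_distinct) {
      ok <- function(tbl) {
        occ <- occupancy_from_plan(tbl, chrom_ids, well_ids)
        all(rowSums(occ) >= 1) && nrow(unique(occ)) == n_chrom
      }
      tries <- 1
      while (!ok(plan_tbl)) {
        if (tries >= max_tries)
          stop("could not draw a plan with pairwise-distinct configurations ",
               "in ", max_tries, " tries", call. = FALSE)
        plan_tbl <- draw_plan()
        tries <- tries + 1
      }
    }
    structure(
      plan_tbl,
      well_ids = well_ids,
      chromosome_ids = chrom_ids,
      per_well_min = per_well_min,
      per_well_max = per_well_max,
      seed = seed,
      class = c("pool_plan", class(plan_tbl))
    )
  })
}

# binary chromosome x well matrix from the long plan table
occupancy_from_plan <- function(plan_tbl, chrom_ids, well_ids) {
  occ <- matrix(0L, nrow = length(chrom_ids), ncol = length(well_ids),
                dimnames = list(chrom_ids, well_ids))
  occ[cbind(match(plan_tbl$chromosome_id, chrom_ids),
            match(plan_tbl$well_id, well_ids))] <- 1L
  occ
}

#' True chromosome-by-well occupancy matrix of a plan
#'
#' @param plan A `pool_plan`.
#' @return Binary integer matrix, chromosomes in rows, wells in columns.
#' @export
plan_occupancy <- function(plan) {
  stopifnot(inherits(plan, "pool_plan"))
  occupancy_from_plan(plan, attr(plan, "chromosome_ids"),
                      attr(plan, "well_ids"))
}

#' Number of distinct well-occupancy configurations in a plan
#'
#' Chromosomes that occupy exactly the same set of wells have identical
#' configuration vectors and cannot be separated by pool clustering; the
#' number of distinct configurations is therefore the number of chromosome
#' clusters the experiment can resolve at best.
#'
#' @param plan A `pool_plan`.
#' @return Integer count of distinct configuration vectors, at most the
#'   number of chromosomes.
#' @export
distinct_configurations <- function(plan) {
  occ <- plan_occupancy(plan)
  nrow(unique(occ))
}

#' Simulate a per-well read-count matrix with known truth
#'
#' Draws a scaffold-by-well table of read counts. The expected count for
#' scaffold i in well j is `L_i * depth` when i's chromosome is present in j
#' plus `L_i * background_rate` in every well; counts are Poisson around that
#' mean (or the rounded mean itself with `noise = "none"`). Covered bases are
#' derived from the count through the Lander-Waterman expectation
#' `L * (1 - exp(-count * read_length / L))`.
#'
#' @param karyotype A `karyotype`.
#' @param plan A `pool_plan` over the same chromosomes.
#' @param depth Sequencing depth of a present chromosome, in reads per bp.
#'   Either a single value or a vector named by chromosome id.
#' @param background_rate Background (contamination) rate in reads per bp
#'   applied to every scaffold in every well.
#' @param read_length Read length in bp used for the covered-base model.
#' @param noise `"poisson"` (default) or `"none"` for deterministic expected
#'   counts.
#' @param seed Integer seed.
#'
#' @return A list with `counts` (a [count_matrix] tibble) and `truth` (a
#'   `sim_truth` holding the scaffold-to-chromosome map, the occupancy
#'   matrix, and the rates).
#' @export
simulate_count_matrix <- function(karyotype, plan,
                                  depth = 0.01,
                                  background_rate = 5e-4,
                                  read_length = 100,
                                  noise = c("poisson", "none"),
                                  seed = 1L) {
  stopifnot(inherits(karyotype, "karyotype"), inherits(plan, "pool_plan"))
  noise <- match.arg(noise)
  if (any(depth < 0) || background_rate < 0)
    stop("rates must be nonnegative", call. = FALSE)

  chrom_ids <- karyotype$chromosomes$chromosome_id
  if (length(depth) == 1) {
    depth <- stats::setNames(rep(depth, length(chrom_ids)), chrom_ids)
  } else if (!all(chrom_ids %in% names(depth))) {
    stop("`depth` must be scalar or named by chromosome id", call. = FALSE)
  }
  occ <- plan_occupancy(plan)
  well_ids <- colnames(occ)
  scaff <- karyotype$scaffolds

  # expected counts: scaffolds x wells
  depth_mat <- occ[scaff$chromosome_id, , drop = FALSE] *
    depth[scaff$chromosome_id]
  mu <- scaff$scaffold_length * (depth_mat + background_rate)

  counts <- withr::with_seed(seed, {
    if (noise == "poisson") {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      round(mu)
    }
  })
  dimnames(counts) <- list(scaff$scaffold_id, well_ids)

  L <- scaff$scaffold_length
  covered <- round(L * (1 - exp(-(counts * read_length) / L)))
  covered <- pmin(covered, L)

  long <- tibble::tibble(
    scaffold_id = rep(scaff$scaffold_id, times = length(well_ids)),
    scaffold_length = rep(L, times = length(well_ids)),
    well_id = rep(well_ids, each = nrow(scaff)),
    count = as.numeric(counts),
    covered_bases = as.numeric(covered)
  )
  cm <- new_count_matrix(long)

  truth <- structure(
    list(
      scaffold_to_chromosome = scaff[, c("scaffold_id", "chromosome_id")],
      chromosome_to_wells = occ,
      depth_per_chromosome = depth,
      background_rate = background_rate,
      read_length = read_length,
      seed = seed
    ),
    class = "sim_truth"
  )
  list(counts = cm, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$scaffold_to_chromosome), " scaffolds on ",
      nrow(x$chromosome_to_wells), " chromosomes across ",
      ncol(x$chromosome_to_wells), " wells; background ",
      x$background_rate, " reads/bp\n", sep = "")
  invisible(x)
}
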