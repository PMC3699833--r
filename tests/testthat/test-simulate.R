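test_that("generate_karyotype covers minimal and full-size cases", {
  one <- generate_karyotype(1, 1e6, scaffolds_per_chromosome = 1, seed = 7)
  expect_equal(nrow(one$scaffolds), 1)
  expect_equal(one$scaffolds$chromosome_id, one$chromosomes$chromosome_id)

  kar <- generate_karyotype(13, 16e6, scaffolds_per_chromosome = 150,
                            seed = 1)
  expect_equal(nrow(kar$scaffolds), 13 * 150)
  expect_true(all(kar$scaffolds$scaffold_length > 0))
  expect_true(all(kar$scaffolds$chromosome_id %in%
                    kar$chromosomes$chromosome_id))
  expect_true(all(table(kar$scaffolds$chromosome_id) >= 1))
  per_chr <- tapply(kar$scaffolds$scaffold_length,
                    kar$scaffolds$chromosome_id, sum)
  expect_true(all(per_chr <= kar$chromosomes$chromosome_length[
    match(names(per_chr), kar$chromosomes$chromosome_id)]))
  # truncation at the contig-size filter
  expect_true(all(kar$scaffolds$scaffold_length >= 7000))
})

test_that("karyotype generation is deterministic under a fixed seed", {
  a <- generate_karyotype(4, 8e6, scaffolds_per_chromosome = 30, seed = 5)
  b <- generate_karyotype(4, 8e6, scaffolds_per_chromosome = 30, seed = 5)
  expect_identical(a, b)
  expect_error(generate_karyotype(0, 1e6), "must be >= 1")
  expect_error(generate_karyotype(2, -1), "positive")
})

test_that("pool plans respect composition bounds and seeding", {
  kar1 <- generate_karyotype(1, 1e6, scaffolds_per_chromosome = 2, seed = 1)
  forced <- generate_pool_plan(kar1, n_wells = 1, per_well_min = 1,
                               per_well_max = 1, seed = 1)
  expect_equal(forced$chromosome_id, kar1$chromosomes$chromosome_id)

  kar <- generate_karyotype(16, 8e6, scaffolds_per_chromosome = 5, seed = 2)
  plan <- generate_pool_plan(kar, n_wells = 21, per_well_min = 1,
                             per_well_max = 4, seed = 3)
  sizes <- table(plan$well_id)
  expect_length(sizes, 21)
  expect_true(all(sizes >= 1 & sizes <= 4))
  expect_error(generate_pool_plan(kar, per_well_min = 5, per_well_max = 2),
               "per_well_min")

  same <- generate_pool_plan(kar, n_wells = 21, seed = 3)
  expect_identical(tibble::as_tibble(plan), tibble::as_tibble(same))
  n_diff <- sum(vapply(1:100, function(s) {
    other <- generate_pool_plan(kar, n_wells = 21, seed = 1000 + s)
    !identical(tibble::as_tibble(other), tibble::as_tibble(plan))
  }, logical(1)))
  expect_gt(n_diff, 0)
})

test_that("distinct_configurations equals the unique-row count of the truth", {
  kar <- generate_karyotype(3, 2e6, scaffolds_per_chromosome = 2, seed = 1)
  # A and B share both wells; C sits alone in a third
  dup <- structure(
    tibble::tibble(
      well_id = c("W01", "W01", "W02", "W02", "W03"),
      chromosome_id = c("chr01", "chr02", "chr01", "chr02", "chr03")
    ),
    well_ids = c("W01", "W02", "W03"),
    chromosome_ids = kar$chromosomes$chromosome_id,
    per_well_min = 1, per_well_max = 2, seed = 0,
    class = c("pool_plan", class(tibble::tibble()))
  )
  expect_equal(distinct_configurations(dup), 2)

  disjoint <- structure(
    tibble::tibble(well_id = c("W01", "W02", "W03"),
                   chromosome_id = c("chr01", "chr02", "chr03")),
    well_ids = c("W01", "W02", "W03"),
    chromosome_ids = kar$chromosomes$chromosome_id,
    per_well_min = 1, per_well_max = 1, seed = 0,
    class = c("pool_plan", class(tibble::tibble()))
  )
  expect_equal(distinct_configurations(disjoint), 3)

  kar10 <- generate_karyotype(10, 4e6, scaffolds_per_chromosome = 2,
                              seed = 4)
  for (s in 1:20) {
    plan <- generate_pool_plan(kar10, n_wells = 12, seed = s)
    occ <- plan_occupancy(plan)
    expect_equal(distinct_configurations(plan),
                 nrow(unique(occ)))
  }
})

test_that("simulated counts follow the stated Poisson means", {
  kar <- generate_karyotype(2, 1e6, scaffolds_per_chromosome = 1, seed = 1)
  plan <- generate_pool_plan(kar, n_wells = 2, per_well_min = 1,
                             per_well_max = 1, require_distinct = TRUE,
                             seed = 2)
  occ <- plan_occupancy(plan)

  # zero background: cells of absent chromosomes are exactly zero
  sim0 <- simulate_count_matrix(kar, plan, depth = 0.001,
                                background_rate = 0, seed = 3)
  # join counts through the scaffold->chromosome map
  cm <- dplyr::inner_join(sim0$counts, kar$scaffolds,
                          by = c("scaffold_id", "scaffold_length"))
  present <- occ[cbind(cm$chromosome_id, cm$well_id)] == 1
  expect_true(all(cm$count[!present] == 0))

  # empirical mean of many seeded draws within 3 SE of depth * length
  L <- kar$scaffolds$scaffold_length[1]
  d <- 0.002
  draws <- vapply(1:2000, function(s) {
    x <- simulate_count_matrix(kar, plan, depth = d, background_rate = 0,
                               seed = s)$counts
    ch <- kar$scaffolds$chromosome_id[1]
    w <- colnames(occ)[occ[ch, ] == 1]
    x$count[x$scaffold_id == kar$scaffolds$scaffold_id[1] &
              x$well_id == w]
  }, numeric(1))
  se <- sqrt(d * L / length(draws))   # Poisson variance = mean
  expect_lt(abs(mean(draws) - d * L), 3 * se)

  # background-only cells have mean L_i * background within 3 SE (pooled
  # over every absent cell of every draw)
  bg <- 5e-4
  chrom_of <- stats::setNames(kar$scaffolds$chromosome_id,
                              kar$scaffolds$scaffold_id)
  resid <- unlist(lapply(1:2000, function(s) {
    x <- simulate_count_matrix(kar, plan, depth = d, background_rate = bg,
                               seed = s)$counts
    absent <- occ[cbind(chrom_of[x$scaffold_id], x$well_id)] == 0
    x$count[absent] - bg * x$scaffold_length[absent]
  }))
  var_cell <- bg * mean(kar$scaffolds$scaffold_length)  # Poisson variance
  se_bg <- sqrt(var_cell / length(resid))
  expect_lt(abs(mean(resid)), 3 * se_bg)

  # bit-reproducibility and integer nonnegativity
  a <- simulate_count_matrix(kar, plan, seed = 9)
  b <- simulate_count_matrix(kar, plan, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts$count >= 0))
  expect_true(all(a$counts$count == round(a$counts$count)))
  expect_error(simulate_count_matrix(kar, plan, depth = -1),
               "nonnegative")
})
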