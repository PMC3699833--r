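make_nm <- function(mat) {
  long <- tibble::as_tibble(as.data.frame.table(mat,
                                                stringsAsFactors = FALSE))
  names(long) <- c("scaffold_id", "well_id", "value")
  class(long) <- c("normalized_matrix", class(tibble::tibble()))
  long
}

test_that("cluster_well_means equals the group-mean oracle", {
  m <- rbind(s1 = c(0, 2), s2 = c(0, 4), s3 = c(5, 1))
  colnames(m) <- c("W01", "W02")
  nm <- make_nm(m)
  lab <- tibble::tibble(scaffold_id = c("s1", "s2", "s3"),
                        cluster = c(1, 1, 2))
  M <- cluster_well_means(nm, lab)
  expect_equal(M["1", ], c(W01 = 0, W02 = 3))
  expect_equal(M["2", ], c(W01 = 5, W02 = 1))   # mean of one = the profile

  set.seed(11)
  big <- matrix(runif(60), 10,
                dimnames = list(sprintf("s%d", 1:10), sprintf("W%d", 1:6)))
  labs <- tibble::tibble(scaffold_id = rownames(big),
                         cluster = sample(1:3, 10, replace = TRUE))
  got <- cluster_well_means(make_nm(big), labs)
  for (k in unique(labs$cluster)) {
    ref <- colMeans(big[labs$scaffold_id[labs$cluster == k], , drop = FALSE])
    expect_equal(got[as.character(k), ], ref)
  }
})

test_that("binarize_configuration thresholds peaks and flags dead rows", {
  M <- rbind(`1` = c(10, 0.1, 9.8, 0.2), `2` = c(0, 0, 0, 0))
  colnames(M) <- sprintf("W%02d", 1:4)
  cfg <- binarize_configuration(M, relative_threshold = 0.5,
                                method = "relative")
  B <- configuration_occupancy(cfg)
  expect_equal(unname(B["1", ]), c(1, 0, 1, 0))
  expect_equal(unname(B["2", ]), c(0, 0, 0, 0))
  expect_equal(attr(cfg, "flagged"), "2")

  # invariant to global rescaling
  cfg2 <- binarize_configuration(M * 1000, relative_threshold = 0.5,
                                 method = "relative")
  expect_equal(configuration_occupancy(cfg2), B)
  cfg3 <- binarize_configuration(M * 1000, method = "split")
  expect_equal(configuration_occupancy(cfg3),
               configuration_occupancy(binarize_configuration(
                 M, method = "split")))

  # the split rule tolerates crowding-diluted peaks that 0.5 x max misses
  Mc <- rbind(`1` = c(1, 0.25, 0.002, 0.003))
  colnames(Mc) <- sprintf("W%02d", 1:4)
  split_cfg <- binarize_configuration(Mc, method = "split")
  expect_equal(unname(configuration_occupancy(split_cfg)["1", ]),
               c(1, 1, 0, 0))
})

test_that("deduced occupancy matches simulated truth on clean data", {
  toy <- toy_sim(n_chrom = 6, n_wells = 10, seed = 31)
  nm <- normalize_counts(toy$counts)
  fit <- kmeans_fit(standardize_profiles(nm),
                    distinct_configurations(toy$plan),
                    restarts = 10, seed = 5)
  cfg <- binarize_configuration(cluster_well_means(nm, fit),
                                method = "split")
  ev <- evaluate_against_truth(fit, cfg, toy$truth)
  expect_equal(ev$ari, 1)
  expect_equal(ev$config_match_fraction, 1)

  cpw <- chromosomes_per_well(cfg)
  truth_cpw <- colSums(toy$truth$chromosome_to_wells)
  expect_equal(stats::setNames(cpw$n_chromosomes, cpw$well_id), truth_cpw)
  expect_true(all(cpw$n_chromosomes >= 1 & cpw$n_chromosomes <= 4))
})

test_that("informative wells are the loaded wells", {
  M <- rbind(`1` = c(3, 0, 2), `2` = c(1, 0, 0))
  colnames(M) <- c("W01", "W02", "W03")
  cfg <- binarize_configuration(M, method = "relative",
                                relative_threshold = 0.3)
  expect_false("W02" %in% informative_wells(cfg))

  all_on <- binarize_configuration(
    rbind(`1` = c(2, 2, 2)) |> `colnames<-`(c("W01", "W02", "W03")),
    method = "relative")
  expect_equal(informative_wells(all_on), c("W01", "W02", "W03"))

  # 17 loaded + 4 background-only wells: exactly the 17 come back
  toy <- toy_sim(n_chrom = 8, n_wells = 17, seed = 77, n_empty_wells = 4)
  nm <- normalize_counts(toy$counts)
  fit <- kmeans_fit(standardize_profiles(nm),
                    distinct_configurations(toy$plan),
                    restarts = 10, seed = 6)
  cfg <- binarize_configuration(cluster_well_means(nm, fit),
                                method = "split")
  loaded <- sprintf("W%02d", 1:17)
  expect_setequal(informative_wells(cfg), loaded)
})

test_that("metascaffold_report summarizes clusters and conserves bp", {
  lens <- c(a = 7)
  lab <- tibble::tibble(scaffold_id = "a", cluster = 1)
  rep1 <- metascaffold_report(lab, lens)
  expect_equal(rep1$total_bp, 7)
  expect_equal(rep1$n50, 7)

  lens2 <- c(a = 2, b = 3, c = 4, d = 5, e = 7)
  lab2 <- tibble::tibble(scaffold_id = names(lens2), cluster = 1)
  expect_equal(metascaffold_report(lab2, lens2)$n50, 5)

  # splitting a cluster conserves the summed bp
  lab_split <- tibble::tibble(scaffold_id = names(lens2),
                              cluster = c(1, 1, 2, 2, 2))
  rep_split <- metascaffold_report(lab_split, lens2)
  expect_equal(sum(rep_split$total_bp), sum(lens2))
  gm <- attr(rep_split, "grand_means")
  expect_equal(gm$mean_total_bp, mean(rep_split$total_bp))
})

test_that("evaluation metrics are permutation invariant and match the ARI formula", {
  toy <- toy_sim(n_chrom = 4, n_wells = 8, seed = 41,
                 scaffolds_per_chromosome = 10)
  truth <- toy$truth
  perfect <- truth$scaffold_to_chromosome |>
    dplyr::mutate(cluster = match(.data$chromosome_id,
                                  unique(.data$chromosome_id))) |>
    dplyr::select("scaffold_id", "cluster")
  expect_equal(evaluate_against_truth(perfect, truth = truth)$ari, 1)

  lumped <- dplyr::mutate(perfect, cluster = 1)
  expect_equal(evaluate_against_truth(lumped, truth = truth)$ari, 0)

  set.seed(2)
  noisy <- dplyr::mutate(perfect,
                         cluster = ifelse(stats::runif(dplyr::n()) < 0.3,
                                          sample(4, dplyr::n(), TRUE),
                                          .data$cluster))
  ari_pkg <- evaluate_against_truth(noisy, truth = truth)$ari
  joined <- dplyr::inner_join(noisy, truth$scaffold_to_chromosome,
                              by = "scaffold_id")
  expect_equal(ari_pkg, ari_oracle(joined$cluster, joined$chromosome_id))

  relabel <- dplyr::mutate(noisy, cluster = c(4, 3, 2, 1)[.data$cluster])
  expect_equal(evaluate_against_truth(relabel, truth = truth)$ari, ari_pkg)
})
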