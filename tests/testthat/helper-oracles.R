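# Independent oracles used across the suite. These are deliberately naive
# (per-base tallies, exhaustive enumeration) and must stay independent of
# the package implementation paths they check.

# covered bases of the union of [pos, pos + rl - 1] clipped to [1, L],
# counted base by base
brute_covered <- function(positions, read_length, scaffold_length) {
  hit <- logical(scaffold_length)
  for (p in positions) {
    lo <- max(1, p)
    hi <- min(scaffold_length, p + read_length - 1)
    if (lo <= hi) hit[lo:hi] <- TRUE
  }
  sum(hit)
}

# minimum within-cluster sum of squares over all assignments of n points
# into k nonempty groups (n small)
brute_min_wss <- function(x, k) {
  n <- nrow(x)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (length(unique(a)) < k) next
    wss <- 0
    for (g in unique(a)) {
      xg <- x[a == g, , drop = FALSE]
      ctr <- colMeans(xg)
      wss <- wss + sum(sweep(xg, 2, ctr)^2)
    }
    best <- min(best, wss)
  }
  best
}

# adjusted Rand index from the contingency-table formula
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(sum(tab))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# N50 straight from the definition, scanning the descending-sorted lengths
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  run <- 0
  for (v in s) {
    run <- run + v
    if (run >= half) return(v)
  }
}

# Monte-Carlo placement oracle for the repeat collision probability.
# Repeat copies sit in disjoint evenly spaced windows; each of the m
# fragments lands uniformly and hits the window of at most one copy.
# Fragments are allocated to copies multinomially with the exact per-copy
# hit probability, preserving the dependence between copies that the
# analytic formula approximates away.
mc_collision <- function(m, genome_size, fragment_length, repeat_copies,
                         repeat_unit_length, trials = 1e5) {
  p_one <- (fragment_length + repeat_unit_length - 1) / genome_size
  hits <- stats::rbinom(trials, m, repeat_copies * p_one)
  collided <- vapply(hits, function(k) {
    if (k < 2) return(FALSE)
    length(unique(sample.int(repeat_copies, k, replace = TRUE))) >= 2
  }, logical(1))
  mean(collided)
}

# direct placement version (slow; used at a single grid point): uniform
# fragment starts, explicit overlap test against evenly spaced copies
mc_collision_direct <- function(m, genome_size, fragment_length,
                                repeat_copies, repeat_unit_length,
                                trials = 2e4) {
  spacing <- floor(genome_size / repeat_copies)
  starts <- (seq_len(repeat_copies) - 1) * spacing + 1
  collided <- logical(trials)
  for (t in seq_len(trials)) {
    x <- sample.int(genome_size - fragment_length + 1, m, replace = TRUE)
    n_hit <- 0
    for (s in starts) {
      if (any(x >= s - fragment_length + 1 & x <= s + repeat_unit_length - 1)) {
        n_hit <- n_hit + 1
        if (n_hit >= 2) break
      }
    }
    collided[t] <- n_hit >= 2
  }
  mean(collided)
}

# majority-vote consensus error by direct term-by-term enumeration
consensus_oracle <- function(e, c) {
  ks <- 0:c
  err <- ks > c / 2 | (c %% 2 == 0 & ks == c / 2)
  sum(choose(c, ks[err]) * e^ks[err] * (1 - e)^(c - ks[err]))
}

# a small simulated experiment shared by several tests
toy_sim <- function(n_chrom = 5, n_wells = 8, seed = 42, noise = "poisson",
                    scaffolds_per_chromosome = 20, depth = 0.01,
                    background_rate = 5e-4, ...) {
  kar <- generate_karyotype(n_chrom, 4e6,
                            scaffolds_per_chromosome = scaffolds_per_chromosome,
                            seed = seed)
  plan <- generate_pool_plan(kar, n_wells = n_wells,
                             per_well_min = 1, per_well_max = min(3, n_chrom),
                             require_distinct = TRUE, seed = seed + 1, ...)
  sim <- simulate_count_matrix(kar, plan, depth = depth,
                               background_rate = background_rate,
                               noise = noise, seed = seed + 2)
  list(karyotype = kar, plan = plan, counts = sim$counts, truth = sim$truth)
}

# unique-occupancy-row count straight from a sim_truth object
distinct_configurations_from_truth <- function(truth) {
  nrow(unique(truth$chromosome_to_wells))
}

# minimal SAM text builder
sam_lines <- function(df, header = "@HD\tVN:1.6") {
  body <- apply(df, 1, function(r) {
    paste(r[["qname"]], r[["flag"]], r[["rname"]], r[["pos"]], r[["mapq"]],
          "100M", "*", "0", r[["tlen"]], "*", "*", sep = "\t")
  })
  c(header, body)
}

sam_record <- function(qname = "r1", flag = 0, rname = "s1", pos = 1,
                       mapq = 60, tlen = 300) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, tlen = tlen, stringsAsFactors = FALSE)
}
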