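---
title: "Binning assembly scaffolds by metaphase chromosome pools: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning assembly scaffolds by metaphase chromosome pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrompool)
```

## The measurement model

A dilute suspension of metaphase chromosomes is partitioned into barcoded
wells so that each well receives a small random pool of chromosomes
(typically 1–4 of the 21 wells used here). After per-well amplification and
sequencing, reads from well $j$ are aligned to the draft assembly. If
chromosome $g$ is present in well $j$, every scaffold on $g$ receives reads
in $j$; otherwise it sees only background (contaminating DNA, index
hopping, mapping noise). Chromosome $g$ is therefore summarized by a binary
*configuration vector* over wells, and two scaffolds share a chromosome
exactly when they share a configuration.

`chrompool` models the observed count of scaffold $i$ (length $L_i$) in
well $j$ as

$$ c_{ij} \sim \mathrm{Poisson}\!\left( L_i\,(d_g\,B_{gj} + b) \right), $$

where $d_g$ is the sequencing depth of a present chromosome (reads/bp),
$B_{gj} \in \{0,1\}$ the true occupancy, and $b$ a uniform background rate.
The Poisson form is the minimal counting model: nothing in the deduction
depends on it, but it makes the simulator's expectations analytic and the
tests sharp.

## Normalization

Counts are made comparable across wells and scaffolds in two steps:

$$ n_{ij} = \frac{c_{ij}}{T_j} \cdot \frac{v_{ij}}{L_i}, $$

with $T_j = \sum_i c_{ij}$ the well total (computed after all filters) and
$v_{ij}$ the number of scaffold bases covered by at least one retained
read. Division by $T_j$ removes per-well depth — the pipeline is exactly
invariant to rescaling all counts of a well, which the test suite asserts.
The breadth factor $v_{ij}/L_i$ penalizes reads that pile up on a fragment
of the scaffold, as a repeat-driven cross-mapping signal does, relative to
reads spread along its length. Breadth is computed per (scaffold, well);
a pooled variant (one breadth per scaffold across wells) is available via
`normalize_counts(coverage = "pooled")`. Wells with $T_j = 0$ carry no
information and are dropped with a warning rather than imputed.

Alignment filters follow the fields of a minimal SAM record: mapped flag
set, MAPQ **strictly greater than 30** by default, optional bounds on the
absolute template length, and a contig-size filter keeping only scaffolds
longer than 7 kb (short contigs carry too few reads for a stable profile).
The source protocol for this experiment stated two different MAPQ cutoffs
(">30" and ">25") in adjacent steps; we default to the stricter one and
expose it as `min_mapq`. Whether the well total should include reads on
sub-7 kb scaffolds is equally unstated; we total after all filters, so the
matrix is self-consistent.

The simulator derives covered bases from the count through the
Lander–Waterman expectation $v = L\,(1 - e^{-c\,\ell/L})$ with read length
$\ell$ (default 100 bp), so breadth saturates realistically as coverage
grows.

## Clustering in correlation space

"K-means with Pearson correlation as the distance" is not directly
well-posed, because the centroid update of K-means is tied to squared
Euclidean distance. We use the standard equivalence instead: if each
scaffold's profile is standardized to zero mean and unit *population*
variance across the $W$ wells, then

$$ \lVert z_i - z_{i'} \rVert^2 = 2\,W\,(1 - r_{ii'}), $$

so Euclidean K-means on standardized profiles *is* K-means under
correlation distance. (The identity is checked numerically in the test
suite.) An alternative mode clusters rows of the correlation matrix itself
(`mode = "correlation"` in `pipeline_config()`); both readings of the
original procedure are implemented, with the standardized mode as default
because it has the exact distance interpretation. Scaffolds with
zero-variance profiles (no reads anywhere, or a constant profile) carry no
correlation signal; they are excluded before clustering and reported as
unassigned rather than forced into a cluster.

K-means itself is `stats::kmeans` wrapped in a seeded restart loop with
distance-weighted (K-means++-style) initial centers, keeping the best of
`restarts` runs by WSS. When K exceeds the number of *distinct* profiles
(which happens on noise-free simulations, where all scaffolds of a
chromosome have identical standardized profiles), K-means is bypassed:
distinct profiles become singleton clusters and duplicate groups are split
arbitrarily, which attains the exact optimum (WSS 0) where the generic
algorithm would fail.

## Choosing the number of chromosomes

The sweep `k_sweep()` records the best WSS for each candidate K, warm
starting each K from the previous best centers plus the worst-fit point —
this guarantees a monotone nonincreasing curve, so the knee is always
well defined. The knee rule in `select_k_knee()` maximizes the discrete
second difference **of the log curve**,
$\log W_{K-1} - 2\log W_K + \log W_{K+1}$.

Curvature on the raw scale was considered and rejected: with many
well-separated clusters the absolute WSS drops at small K are orders of
magnitude larger than at the true K, and raw second differences select
K = 3–6 on data whose true structure is unambiguous (the 12→13 drop in a
typical simulated sweep is ~17-fold, yet numerically smaller than the
2→3 drop). The log-scale rule is scale invariant — it asks where the
*relative* improvement collapses, which is what "only marginal improvement
in the error" means — and it still reproduces the hand-checkable example
`WSS = (100, 10, 9, 8.5) → K* = 2`. Ties break toward smaller K
(parsimony); flat or linear curves have no positive log-curvature and
return `k_min` with a warning; exact zeros (noise-free saturation) are
floored at $10^{-10}\,\max W$ before taking logs.

Chromosomes that happen to share the same well set are fundamentally
unresolvable: their scaffolds have identical configurations. The pipeline
then recovers `distinct_configurations(plan)` clusters, and the merged
cluster carries the shared configuration — the identifiability limit, not
an algorithmic failure. With 21 wells and 1–4 chromosomes per well the
chance of a collision among 13 chromosomes is small but real; the
simulator's `require_distinct = TRUE` redraws plans until configurations
are pairwise distinct when an identifiable truth is wanted.

## Deduce the well configuration

`cluster_well_means()` averages normalized values over each cluster's
scaffolds, per well; presence appears as a per-well peak.
`binarize_configuration()` offers two peak rules:

* `"relative"` — occupied iff the well mean reaches
  `relative_threshold` (default 0.5) of the row maximum. Simple, but
  because normalization divides by the well total, a chromosome sharing a
  well with three others shows roughly a quarter of the signal it shows
  alone, which a fixed 0.5 fraction can miss.
* `"split"` (pipeline default) — a deterministic two-level 1-D split of
  the row *on the log scale*. Signal scales multiplicatively with well
  crowding while background sits orders of magnitude lower, so the two
  levels separate cleanly in log space; a linear-scale split can instead
  isolate only the single tallest peak.

Both rules are invariant to global rescaling of the mean matrix. Rows with
all-zero means are flagged and called absent everywhere. An *informative
well* is one with at least one chromosome called present — wells that
received no chromosome show only background and drop out; the original
experiment reported 17 of its 21 wells as informative, a scenario the
simulator reproduces with `n_empty_wells = 4`. The criterion behind that
published 17/21 was never stated, so our definition is one plausible
reading, exposed as its own function rather than hidden in the pipeline.

Per-cluster meta-scaffold summaries use the standard N50 convention: the
length at which the descending-sorted cumulative length first reaches half
the total.

## The simulator as a test bed

Defaults mirror the experiment the package is built around: 21 wells of
1–4 chromosomes, 13–16 chromosomes of ~16 Mb, scaffolds log-normal with a
7 kb lower truncation (so every simulated scaffold survives the contig
filter), ~115 scaffolds per chromosome (~1500 total), depth 0.01 reads/bp
against background 5 × 10⁻⁴ (signal-to-background 20, a conservative
stand-in for the very clean per-well libraries of a microfluidic device).
Well composition is sampled uniformly within the size bounds, as the
physical loading distribution over {1,2,3,4} was never published.

The simulator emulates *count-level* data only. It does not model read
sequences, base errors, alignment ambiguity, amplification bias, GC
effects, or repeat-driven cross-mapping between chromosomes — the
phenomena that make real normalized profiles noisier than Poisson. Passing
tests therefore demonstrate that the deduction machinery is correct and
identifiable under the stated noise model, not that any particular real
data set will cluster as cleanly.

Every stochastic function takes an integer seed and is bit-reproducible;
the pipeline derives per-stage seeds deterministically from one global
seed, and rerunning any configuration reproduces its output files byte for
byte.

## Dilution-pool design calculus

Two closed-form models quantify why limiting molecules per well works:

* **Repeat collision.** With $m$ fragments of length $\ell_f$ placed
  independently and uniformly on a genome of size $G$, one copy of a
  repeat of unit length $\rho$ is touched with probability
  $q = 1 - (1 - (\ell_f + \rho - 1)/G)^m$; treating the $n$ copies as
  independent, the chance a well captures ≥ 2 distinct copies is
  $1 - (1-q)^n - n\,q\,(1-q)^{n-1}$. The independence approximation is
  valid while $n(\ell_f + \rho) \ll G$ and is validated against a
  Monte-Carlo placement oracle (3 SE at every tested grid point); the
  probability is monotone in each parameter in the expected direction.
* **Consensus error.** Over-sequencing a well lets majority vote correct
  the intrinsic per-read error $e$: the consensus at coverage $c$ errs
  with probability $\sum_{k > c/2} \binom{c}{k} e^k (1-e)^{c-k}$, ties at
  even $c$ counted as errors (conservative). For odd panels this is
  nonincreasing in $c$ and ≤ $e$ — "the error rate is reduced by the
  coverage". The conservative tie rule makes even panels slightly *worse*
  than the next odd panel down (at $c = 2$ the rate is $2e - e^2 > e$), so
  monotonicity claims are stated over odd coverages, where majority vote
  is well defined.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run everything at the scale of
the study design itself: 20 seeded replicates of a 13-chromosome, 21-well,
~1500-scaffold experiment (a sweep over K = 2…20 with 5 restarts plus a
warm start per K completes in about a second per replicate), exhaustive
K-means oracles at ≤ 8 points, 10⁵-trial Monte-Carlo checks of the
collision model, and brute-force per-base coverage oracles at a few
hundred reads. These sizes were chosen as the smallest at which every
claim is exercised at full experimental dimensions.

## Known limitations

* Scaffolds are binned, not ordered: no intra-chromosomal scaffolding is
  attempted, and clusters are arbitrary labels, not cytogenetically named
  chromosomes.
* Chromosomes sharing a configuration merge irrecoverably; more wells (or
  a designed loading) is the only fix.
* The configuration-matching score maps each cluster to its majority
  chromosome; with gross misclustering that mapping itself degrades, so
  `config_match_fraction` is only meaningful alongside a high adjusted
  Rand index.
* The background model is uniform per bp; structured contamination (e.g. a
  well contaminated by one specific chromosome arm) would look like signal
  to any method based on this design.
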