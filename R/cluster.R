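#' Pearson correlation matrix between scaffold well profiles
#'
#' Correlates every pair of scaffolds over their per-well normalized read
#' profiles. Scaffolds whose profile has zero variance across wells carry no
#' configuration signal and are excluded with a message.
#'
#' @param nm A `normalized_matrix` from [normalize_counts()], or a numeric
#'   scaffold-by-well matrix.
#' @return Symmetric correlation matrix over the retained scaffolds, with an
#'   attribute `excluded` listing zero-variance scaffold ids.
#' @export
pearson_matrix <- function(nm) {
  x <- profile_matrix(nm)
  if (ncol(x) < 2)
    stop("need at least 2 wells to correlate profiles", call. = FALSE)
  v <- apply(x, 1, stats::var)
  excluded <- rownames(x)[v == 0]
  if (length(excluded))
    message(length(excluded), " zero-variance scaffold profile(s) excluded")
  x <- x[v > 0, , drop = FALSE]
  r <- stats::cor(t(x))
  attr(r, "excluded") <- excluded
  r
}

profile_matrix <- function(nm) {
  if (inherits(nm, "normalized_matrix")) normalized_wide(nm)
  else if (is.matrix(nm)) nm
  else stop("expected a normalized_matrix or a numeric matrix",
            call. = FALSE)
}

#' Standardize scaffold profiles for correlation-distance K-means
#'
#' Centers and scales each scaffold's well profile to mean 0 and unit
#' (population) variance. On such vectors the squared Euclidean distance
#' between two scaffolds is `2 * W * (1 - r)` where `W` is the number of
#' wells and `r` their Pearson correlation, so ordinary Euclidean K-means on
#' the standardized profiles is K-means under correlation distance.
#'
#' @param nm A `normalized_matrix` or a scaffold-by-well matrix.
#' @return Standardized scaffold-by-well matrix; zero-variance scaffolds are
#'   dropped and listed in the `excluded` attribute.
#' @export
standardize_profiles <- function(nm) {
  x <- profile_matrix(nm)
  if (ncol(x) < 2)
    stop("need at least 2 wells to standardize profiles", call. = FALSE)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  excluded <- rownames(x)[sd_pop == 0]
  if (length(excluded))
    message(length(excluded), " zero-variance scaffold profile(s) excluded")
  keep <- sd_pop > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  attr(z, "excluded") <- excluded
  z
}

# kmeans++-style init: distance-weighted sampling of k distinct rows
init_centers_pp <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(x) - x[idx[1], ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

kmeans_once <- function(x, centers, iter_max) {
  # Hartigan-Wong can abort on unlucky starts ("empty cluster"); retry with
  # fresh distance-weighted centers, then fall back to MacQueen
  for (attempt in 1:5) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Hartigan-Wong")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
    centers <- init_centers_pp(unique(x), nrow(centers))
  }
  suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max,
                                 algorithm = "MacQueen"))
}

#' Seeded best-of-restarts K-means on scaffold profiles
#'
#' Runs Euclidean K-means with distance-weighted (K-means++-style) seeded
#' starting centers, keeping the restart with the lowest within-cluster sum
#' of squares. When the data contain fewer distinct profiles than `k`
#' (exact duplicates, as in noise-free simulations), duplicate groups are
#' split arbitrarily to reach `k` nonempty clusters at unchanged (zero
#' added) cost.
#'
#' @param profiles Standardized profile matrix from
#'   [standardize_profiles()], a `normalized_matrix` (standardized
#'   internally), or any numeric matrix with observations in rows.
#' @param k Number of clusters, `1 <= k <= nrow(profiles)`.
#' @param restarts Number of random restarts (default 50).
#' @param seed Integer seed making the restart sequence reproducible.
#' @param iter_max Maximum Lloyd/Hartigan-Wong iterations per restart.
#' @param init Optional matrix of starting centers tried in addition to the
#'   random restarts (used for warm starts in [k_sweep()]).
#'
#' @return A `pool_kmeans` object with fields `k`, `labels` (tibble
#'   `scaffold_id`, `cluster`), `wss`, `centers`, `sizes`, `restarts`,
#'   `seed`, and `unassigned` (zero-variance scaffolds, when standardization
#'   happened here).
#' @export
kmeans_fit <- function(profiles, k, restarts = 50, seed = 1L,
                       iter_max = 100, init = NULL) {
  if (inherits(profiles, "normalized_matrix"))
    profiles <- standardize_profiles(profiles)
  x <- as.matrix(profiles)
  n <- nrow(x)
  if (k < 1 || k > n)
    stop("`k` must lie in [1, number of profiles]", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))

  ux <- unique(x)
  n_unique <- nrow(ux)

  if (k >= n_unique) {
    fit <- duplicate_split_fit(x, ux, k)
  } else {
    fit <- withr::with_seed(seed, {
      best <- NULL
      for (r in seq_len(restarts)) {
        cand <- kmeans_once(x, init_centers_pp(ux, k), iter_max)
        if (is.null(best) || cand$tot.withinss < best$tot.withinss)
          best <- cand
      }
      if (!is.null(init)) {
        cand <- kmeans_once(x, init, iter_max)
        if (cand$tot.withinss < best$tot.withinss) best <- cand
      }
      best
    })
  }

  structure(
    list(
      k = k,
      labels = tibble::tibble(scaffold_id = rownames(x),
                              cluster = unname(fit$cluster)),
      wss = unname(fit$tot.withinss),
      centers = fit$centers,
      sizes = unname(fit$size),
      restarts = restarts,
      seed = seed,
      unassigned = attr(profiles, "excluded") %||% character()
    ),
    class = "pool_kmeans"
  )
}

# k exceeds the number of distinct rows: give each distinct row its own
# cluster (WSS 0) and split the largest duplicate groups to reach k
duplicate_split_fit <- function(x, ux, k) {
  grp <- match(
    apply(x, 1, paste, collapse = "\r"),
    apply(ux, 1, paste, collapse = "\r")
  )
  cluster <- grp
  next_id <- nrow(ux) + 1L
  while (next_id <= k) {
    sizes <- table(cluster)
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(cluster == big)
    cluster[members[seq_len(floor(length(members) / 2))]] <- next_id
    next_id <- next_id + 1L
  }
  list(cluster = stats::setNames(cluster, rownames(x)),
       tot.withinss = 0,
       centers = rowsum(x, cluster) / as.vector(table(cluster)),
       size = as.vector(table(cluster)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pool_kmeans <- function(x, ...) {
  cat("<pool_kmeans> k = ", x$k, ", ", nrow(x$labels),
      " scaffolds, WSS = ", signif(x$wss, 5),
      " (", x$restarts, " restarts, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Sweep K and record the within-cluster sum of squares
#'
#' Fits K-means for every candidate K and records the best within-cluster
#' sum of squares, producing the elbow curve used to select the chromosome
#' number. Each K is additionally warm-started from the previous K's best
#' centers plus the point farthest from its assigned center, which
#' guarantees the curve is monotone nonincreasing.
#'
#' @inheritParams kmeans_fit
#' @param k_min,k_max Candidate K range (inclusive).
#' @param keep_fits Keep the fitted `pool_kmeans` objects in the `fits`
#'   attribute (default `TRUE`) so the selected K needs no refit.
#' @return A `k_sweep_curve`: tibble with columns `k` and `wss`; attributes
#'   `fits` (when kept), `restarts`, `seed`.
#' @export
k_sweep <- function(profiles, k_min = 2, k_max = 20, restarts = 50,
                    seed = 1L, iter_max = 100, keep_fits = TRUE) {
  if (inherits(profiles, "normalized_matrix"))
    profiles <- standardize_profiles(profiles)
  x <- as.matrix(profiles)
  if (k_min > k_max || k_max > nrow(x) || k_min < 1)
    stop("need 1 <= k_min <= k_max <= number of profiles", call. = FALSE)

  ks <- seq(k_min, k_max)
  fits <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    init <- if (!is.null(prev) && nrow(prev$centers) == k - 1)
      warm_centers(x, prev) else NULL
    fit <- kmeans_fit(x, k, restarts = restarts, seed = seed + i - 1L,
                      iter_max = iter_max, init = init)
    fit$unassigned <- attr(profiles, "excluded") %||% character()
    fits[[i]] <- fit
    prev <- fit
  }
  curve <- tibble::tibble(k = ks, wss = vapply(fits, `[[`, numeric(1), "wss"))
  structure(
    curve,
    fits = if (keep_fits) stats::setNames(fits, ks) else NULL,
    restarts = restarts,
    seed = seed,
    class = c("k_sweep_curve", class(tibble::tibble()))
  )
}

# previous centers plus the point farthest from its assigned center
warm_centers <- function(x, prev) {
  d2 <- rowSums((x - prev$centers[prev$labels$cluster, , drop = FALSE])^2)
  cand <- x[which.max(d2), , drop = FALSE]
  centers <- rbind(prev$centers, cand)
  # collapse exact duplicates (possible on degenerate data) by jittering is
  # unnecessary: kmeans tolerates duplicate centers only if distinct, so
  # fall back to NULL when the new center duplicates an old one
  if (anyDuplicated(centers)) NULL else unname(centers)
}

#' Select K at the knee of the WSS curve
#'
#' Picks the K with the largest discrete second difference of the
#' log-transformed curve, `log WSS(K-1) - 2 log WSS(K) + log WSS(K+1)`:
#' the sharpest bend after which adding clusters yields only marginal
#' improvement relative to the error remaining. Working on the log scale
#' makes the rule invariant to the overall scale of the curve, so the
#' large absolute drops at small K (where the error is still huge) cannot
#' out-curve the knee. Ties break toward the smaller K (parsimony). Curves
#' with no positive curvature (flat, or straight lines, whose logarithm is
#' concave) return `k_min` with a warning.
#'
#' @param curve A `k_sweep_curve` (or any data frame with columns `k`,
#'   `wss`, at least 3 rows).
#' @return The selected K (integer).
#' @export
#' @examples
#' select_k_knee(tibble::tibble(k = 1:4, wss = c(100, 10, 9, 8.5)))
select_k_knee <- function(curve) {
  if (nrow(curve) < 3)
    stop("need at least 3 points on the WSS curve to locate a knee",
         call. = FALSE)
  curve <- curve[order(curve$k), ]
  w <- curve$wss
  if (max(w) == 0) {
    warning("WSS curve is identically zero; returning k_min", call. = FALSE)
    return(curve$k[1])
  }
  # floor at a tiny fraction of the curve scale so exact zeros (noise-free
  # saturation) stay finite on the log scale
  lw <- log(pmax(w, 1e-10 * max(w)))
  n <- length(lw)
  d2 <- lw[seq_len(n - 2)] - 2 * lw[seq(2, n - 1)] + lw[seq(3, n)]
  tol <- 1e-10
  if (all(d2 <= tol)) {
    warning("WSS curve has no knee (flat or linear); returning k_min",
            call. = FALSE)
    return(curve$k[1])
  }
  curve$k[which.max(d2) + 1L]
}
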