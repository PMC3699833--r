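#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a K-means scaffold clustering
#'
#' @param x A `pool_kmeans` fit.
#' @param ... Ignored.
#' @return Tibble with one row per scaffold: `scaffold_id`, `cluster`.
#' @method tidy pool_kmeans
#' @export
tidy.pool_kmeans <- function(x, ...) x$labels

#' One-row summary of a K-means scaffold clustering
#'
#' @param x A `pool_kmeans` fit.
#' @param ... Ignored.
#' @return Tibble with `k`, `wss`, `n_scaffolds`, `n_unassigned`,
#'   `restarts`, `seed`.
#' @method glance pool_kmeans
#' @export
glance.pool_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, wss = x$wss, n_scaffolds = nrow(x$labels),
    n_unassigned = length(x$unassigned),
    restarts = x$restarts, seed = x$seed
  )
}

#' Tidy a deduced well configuration
#'
#' @param x A `well_configuration`.
#' @param ... Ignored.
#' @return Tibble with `cluster`, `well_id`, `mean_value`, `present`.
#' @method tidy well_configuration
#' @export
tidy.well_configuration <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a deduced well configuration
#'
#' @param x A `well_configuration`.
#' @param ... Ignored.
#' @return Tibble with `n_clusters`, `n_wells`, `n_informative_wells`,
#'   `relative_threshold`, `n_flagged`.
#' @method glance well_configuration
#' @export
glance.well_configuration <- function(x, ...) {
  B <- configuration_occupancy(x)
  tibble::tibble(
    n_clusters = nrow(B),
    n_wells = ncol(B),
    n_informative_wells = length(informative_wells(x)),
    relative_threshold = attr(x, "threshold"),
    n_flagged = length(attr(x, "flagged"))
  )
}
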