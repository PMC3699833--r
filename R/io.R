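comment_header <- function(params) {
  c(sprintf("# chrompool %s",
            as.character(utils::packageVersion("chrompool"))),
    sprintf("# %s=%s", names(params),
            vapply(params, function(p) paste(format(p), collapse = ","),
                   character(1))))
}

write_tsv_commented <- function(x, path, params = list()) {
  writeLines(comment_header(params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, ...)
}

#' Write and read a count matrix as TSV
#'
#' The on-disk layout is wide, one row per scaffold: `scaffold_id`,
#' `scaffold_length`, one `count:<well>` and one `covered:<well>` column per
#' well, preceded by `#` comment lines recording the package version and
#' any parameters supplied. The round trip is lossless.
#'
#' @param counts A [count_matrix].
#' @param path Output file.
#' @param params Named list recorded in the comment header.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(counts, path, params = list()) {
  stopifnot(inherits(counts, "count_matrix"))
  wide <- counts |>
    tidyr::pivot_wider(
      names_from = "well_id",
      values_from = c("count", "covered_bases"),
      names_glue = "{.value}:{well_id}"
    )
  names(wide) <- sub("^covered_bases:", "covered:", names(wide))
  write_tsv_commented(wide, path, params)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  wide <- read_tsv_commented(path)
  if (anyDuplicated(wide$scaffold_id))
    stop("duplicated scaffold row in ", path, call. = FALSE)
  count_cols <- grep("^count:", names(wide), value = TRUE)
  cov_cols <- grep("^covered:", names(wide), value = TRUE)
  if (!length(count_cols) || length(count_cols) != length(cov_cols))
    stop("malformed count matrix file: expected paired count:<well> and ",
         "covered:<well> columns, got ",
         paste(setdiff(names(wide), c("scaffold_id", "scaffold_length")),
               collapse = ", "), call. = FALSE)
  long <- wide |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c(count_cols, cov_cols)),
      names_to = c(".value", "well_id"), names_sep = ":"
    ) |>
    dplyr::rename(covered_bases = "covered")
  new_count_matrix(long)
}

#' Read coverageBED-style per-well tables into a count matrix
#'
#' Each input file describes one well with one row per scaffold and columns
#' `scaffold_id`, `count`, `covered_bases`, `length` (header optional,
#' tab-separated). Scaffolds not longer than `min_scaffold_length` are
#' dropped.
#'
#' @param paths Named character vector: names are well ids, values paths.
#' @param min_scaffold_length Contig-size filter in bp (default 7000).
#' @return A [count_matrix].
#' @export
read_coveragebed <- function(paths, min_scaffold_length = 7000) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by well id", call. = FALSE)
  long <- purrr::imap_dfr(paths, function(p, well) {
    tbl <- readr::read_tsv(
      p, comment = "#", show_col_types = FALSE,
      col_names = c("scaffold_id", "count", "covered_bases", "length"),
      col_types = "ciid", skip = has_header_row(p)
    )
    if (anyDuplicated(tbl$scaffold_id))
      stop("duplicated scaffold row in ", p, call. = FALSE)
    tbl$well_id <- well
    tbl
  })
  long <- long |>
    dplyr::rename(scaffold_length = "length") |>
    dplyr::filter(.data$scaffold_length > min_scaffold_length) |>
    dplyr::mutate(count = as.numeric(.data$count),
                  covered_bases = as.numeric(.data$covered_bases))
  new_count_matrix(long)
}

# lines to skip before tabular data: leading comments plus a column-name
# header when present
has_header_row <- function(path) {
  lines <- readLines(path, n = 100)
  n_comment <- match(FALSE, startsWith(lines, "#"), nomatch = length(lines) + 1) - 1
  first <- lines[n_comment + 1]
  n_comment + as.integer(!is.na(first) && grepl("^scaffold_id\\b", first))
}

#' Scaffold lengths from a FASTA file or two-column table
#'
#' @param path FASTA file (requires the Biostrings package) or a
#'   tab-separated two-column table `scaffold_id`, `scaffold_length`.
#' @param format `"auto"` (by extension), `"fasta"`, or `"tsv"`.
#' @return Tibble with `scaffold_id` and `scaffold_length`.
#' @export
read_scaffold_lengths <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path)) "fasta" else "tsv"
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA lengths requires the Biostrings package",
           call. = FALSE)
    seqs <- Biostrings::readDNAStringSet(path)
    tibble::tibble(scaffold_id = sub("\\s.*$", "", names(seqs)),
                   scaffold_length = as.numeric(Biostrings::width(seqs)))
  } else {
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_names = c("scaffold_id", "scaffold_length"),
                    col_types = "cd", skip = has_header_row(path))
  }
}

#' Write a normalized matrix, labels, sweep curve, or occupancy
#'
#' Plain-text writers for the pipeline artifacts: normalized matrix (wide
#' TSV), cluster labels (TSV), WSS sweep curve (CSV) and the occupancy
#' configuration (JSON mirroring the binary configuration-vector notation).
#'
#' @param nm,fit,curve,config The object to write.
#' @param path Output file.
#' @param params Named list recorded in the comment header (TSV/CSV only).
#' @return The path, invisibly.
#' @name pipeline-writers
NULL

#' @rdname pipeline-writers
#' @export
write_normalized_matrix <- function(nm, path, params = list()) {
  stopifnot(inherits(nm, "normalized_matrix"))
  wide <- tidyr::pivot_wider(nm, names_from = "well_id",
                             values_from = "value")
  write_tsv_commented(wide, path, params)
}

#' @rdname pipeline-writers
#' @export
write_labels <- function(fit, path, params = list()) {
  params <- c(params, list(k = fit$k, wss = fit$wss, seed = fit$seed,
                           restarts = fit$restarts))
  write_tsv_commented(fit$labels, path, params)
}

#' @rdname pipeline-writers
#' @export
write_sweep_curve <- function(curve, path, params = list()) {
  params <- c(params, list(seed = attr(curve, "seed"),
                           restarts = attr(curve, "restarts")))
  writeLines(sub("\t", ",", comment_header(params)), path)
  readr::write_csv(tibble::as_tibble(curve)[, c("k", "wss")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname pipeline-writers
#' @export
write_occupancy_json <- function(config, path) {
  B <- configuration_occupancy(config)
  payload <- list(
    wells = colnames(B),
    threshold = attr(config, "threshold"),
    informative_wells = informative_wells(config),
    configuration = stats::setNames(
      lapply(rownames(B), function(k) unname(B[k, ])), rownames(B))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
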