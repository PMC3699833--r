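#' Parse minimal SAM alignments for one well
#'
#' Reads the 11 mandatory SAM columns from text and returns one record per
#' alignment line. Header lines (starting with `@`) are skipped. Unmapped
#' records (FLAG bit 0x4) are retained but marked, so that filtering is an
#' explicit, separate step.
#'
#' @param input Path to a SAM file, or a character vector of SAM lines.
#' @param well_id Identifier of the well (chromosome preparation) these
#'   alignments belong to.
#' @param permissive If `TRUE`, lines with fewer than 11 fields or
#'   non-numeric POS/MAPQ/TLEN are skipped with a message instead of
#'   aborting.
#'
#' @return A tibble of alignment records: `well_id`, `read_id`,
#'   `scaffold_id`, `position` (1-based leftmost), `mapq`,
#'   `template_length`, `flag`, `mapped`.
#' @export
parse_alignments <- function(input, well_id, permissive = FALSE) {
  lines <- if (length(input) == 1 && !grepl("\t", input) &&
               file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  if (!length(body_idx)) return(empty_records(well_id))

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- n_fields < 11
  take <- function(k) vapply(fields[!bad], `[[`, character(1), k)
  pos  <- suppressWarnings(as.numeric(take(4)))
  mapq <- suppressWarnings(as.integer(take(5)))
  tlen <- suppressWarnings(as.numeric(take(9)))
  flag <- suppressWarnings(as.integer(take(2)))
  numeric_bad <- is.na(pos) | is.na(mapq) | is.na(tlen) | is.na(flag) |
    pos < 1 | mapq < 0 | mapq > 255

  bad_lines <- c(body_idx[bad], body_idx[!bad][numeric_bad])
  if (length(bad_lines)) {
    if (!permissive)
      stop("malformed SAM record at line ", min(bad_lines),
           " (need 11 tab-separated fields with numeric FLAG/POS/MAPQ/TLEN)",
           call. = FALSE)
    message("skipping ", length(bad_lines), " malformed SAM line(s): ",
            paste(sort(bad_lines), collapse = ", "))
  }
  keep <- !numeric_bad
  tibble::tibble(
    well_id = well_id,
    read_id = take(1)[keep],
    scaffold_id = take(3)[keep],
    position = pos[keep],
    mapq = mapq[keep],
    template_length = tlen[keep],
    flag = flag[keep],
    mapped = bitwAnd(flag[keep], 4L) == 0L
  )
}

empty_records <- function(well_id) {
  tibble::tibble(
    well_id = character(), read_id = character(), scaffold_id = character(),
    position = numeric(), mapq = integer(), template_length = numeric(),
    flag = integer(), mapped = logical()
  )
}

#' Filter alignment records by mapping quality and insert size
#'
#' Keeps mapped records whose MAPQ is strictly greater than `min_mapq`
#' (default 30, the high-quality mapping filter used on pooled chromosome
#' reads) and, when bounds are supplied, whose absolute template length lies
#' within `[insert_min, insert_max]`.
#'
#' @param records Tibble from [parse_alignments()] (rows from several wells
#'   may be bound together).
#' @param min_mapq Records must have MAPQ strictly greater than this.
#' @param insert_min,insert_max Optional inclusive bounds on
#'   `abs(template_length)`; `NULL` disables that bound.
#' @return The retained records.
#' @export
filter_alignments <- function(records, min_mapq = 30,
                              insert_min = NULL, insert_max = NULL) {
  if (!is.null(insert_min) && !is.null(insert_max) &&
      insert_min > insert_max)
    stop("`insert_min` must be <= `insert_max`", call. = FALSE)
  keep <- records$mapped & records$mapq > min_mapq
  if (!is.null(insert_min))
    keep <- keep & abs(records$template_length) >= insert_min
  if (!is.null(insert_max))
    keep <- keep & abs(records$template_length) <= insert_max
  records[keep, , drop = FALSE]
}

# named numeric vector of lengths from a tibble/data.frame or named vector
as_length_table <- function(scaffold_lengths) {
  if (is.data.frame(scaffold_lengths)) {
    nm <- intersect(c("scaffold_id", "scaffold_length", "length"),
                    names(scaffold_lengths))
    if (!"scaffold_id" %in% nm || length(nm) < 2)
      stop("length table needs columns scaffold_id and scaffold_length",
           call. = FALSE)
    len_col <- setdiff(nm, "scaffold_id")[1]
    stats::setNames(as.numeric(scaffold_lengths[[len_col]]),
                    scaffold_lengths$scaffold_id)
  } else if (!is.null(names(scaffold_lengths))) {
    as.numeric(scaffold_lengths) |>
      stats::setNames(names(scaffold_lengths))
  } else {
    stop("`scaffold_lengths` must be a data frame or a named vector",
         call. = FALSE)
  }
}

#' Tabulate filtered alignments into a count matrix
#'
#' Applies the contig-size filter (scaffolds must be strictly longer than
#' `min_scaffold_length`) and tallies, for every retained scaffold and every
#' well present in `records`, the number of reads and the number of scaffold
#' bases covered by at least one read (the union of read intervals, clipped
#' to the scaffold). Scaffolds passing the length filter but receiving no
#' reads appear with zero counts.
#'
#' @param records Filtered alignment records (see [filter_alignments()])
#'   with a `well_id` column.
#' @param scaffold_lengths Data frame (`scaffold_id`, `scaffold_length`) or
#'   named vector of scaffold lengths in bp.
#' @param min_scaffold_length Scaffolds with length <= this are excluded
#'   entirely (default 7000 bp).
#' @param read_length Read length in bp used to turn leftmost positions into
#'   covered intervals.
#' @return A [count_matrix].
#' @export
tally_counts <- function(records, scaffold_lengths,
                         min_scaffold_length = 7000, read_length = 100) {
  len <- as_length_table(scaffold_lengths)
  unknown <- setdiff(unique(records$scaffold_id), names(len))
  if (length(unknown))
    stop("records reference scaffolds absent from the length table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  len <- len[len > min_scaffold_length]
  wells <- sort(unique(records$well_id))
  if (!length(wells)) stop("no records: cannot infer wells", call. = FALSE)
  recs <- records[records$scaffold_id %in% names(len), , drop = FALSE]

  grid <- tidyr::expand_grid(scaffold_id = names(len), well_id = wells)
  tallied <- recs |>
    dplyr::group_by(.data$scaffold_id, .data$well_id) |>
    dplyr::summarise(
      count = dplyr::n(),
      covered_bases = covered_union(.data$position,
                                    read_length,
                                    len[[dplyr::cur_group()$scaffold_id]]),
      .groups = "drop"
    )
  out <- grid |>
    dplyr::left_join(tallied, by = c("scaffold_id", "well_id")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      covered_bases = dplyr::coalesce(.data$covered_bases, 0),
      scaffold_length = len[.data$scaffold_id]
    )
  new_count_matrix(out)
}

# bases covered by the union of [pos, pos + read_length - 1], clipped to
# [1, scaffold_length]
covered_union <- function(positions, read_length, scaffold_length) {
  ir <- IRanges::IRanges(start = positions, width = read_length)
  ir <- IRanges::restrict(ir, start = 1L, end = as.integer(scaffold_length))
  sum(IRanges::width(IRanges::reduce(ir)))
}
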