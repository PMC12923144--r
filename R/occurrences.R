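#' Occurrence tables
#'
#' Occurrence records travel through the pipeline as tibbles with columns
#' `taxon_id`, `lon`, `lat`, `year`, `month`, `basis_of_record`
#' (`observation`, `specimen`, `erm_generated`, `other` or `NA`), `source`
#' (`aquamaps`, `obis`, `gbif`, `synthetic`), `original_flags`
#' (semicolon-joined source flag strings, `""` if none) and `flag`
#' (integer: `1` verified, `0` erroneous, `NA` unflagged).
#'
#' @name occurrence-table
NULL

occ_sources <- c("aquamaps", "obis", "gbif", "synthetic")

as_occurrence_tbl <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("taxon_id", "lon", "lat")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("occurrence table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    year = NA_integer_, month = NA_integer_,
    basis_of_record = NA_character_, source = "synthetic",
    original_flags = "", flag = NA_integer_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(records)) records[[nm]] <- defaults[[nm]]
  }
  records
}

#' Default set of source flags treated as erroneous
#'
#' Flag strings from the multi-flag source vocabulary that mark a record as
#' geographically invalid. Flags outside this set (e.g. depth anomalies) are
#' carried through unflagged.
#'
#' @export
erroneous_flag_set <- function() {
  c("on_land", "no_coords", "zero_coords", "implausible_location")
}

#' Unify source-specific quality flags into the binary scheme
#'
#' Collapses heterogeneous source flag vocabularies into a ternary column:
#' `1` verified, `0` erroneous, `NA` unflagged. Records from the binary-flag
#' source (`aquamaps`) keep their flag; multi-flag (`obis`) records are set to
#' `0` only when a flag names a geographic impossibility (land placement,
#' missing/zero coordinates, implausible location), other flags being retained
#' in `original_flags` with the binary flag left blank; `gbif` records are
#' always left blank; `synthetic` records keep whatever flag they carry.
#'
#' @param records Occurrence tibble (see [occurrence-table]).
#' @param erroneous_flags Character set of flag strings that imply an
#'   erroneous record; default [erroneous_flag_set()].
#' @return The tibble with `flag` standardised; coordinates and dates are
#'   never touched.
#' @export
standardize_flags <- function(records, erroneous_flags = erroneous_flag_set()) {
  records <- as_occurrence_tbl(records)
  bad_src <- setdiff(unique(records$source), occ_sources)
  if (length(bad_src)) {
    stop("unknown occurrence source(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  flags_of <- function(s) {
    if (is.na(s) || s == "") character(0) else trimws(strsplit(s, ";")[[1]])
  }
  has_bad <- vapply(
    records$original_flags,
    function(s) any(flags_of(s) %in% erroneous_flags),
    logical(1), USE.NAMES = FALSE
  )
  records |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$source == "aquamaps" ~ .data$flag,
        .data$source == "synthetic" ~ .data$flag,
        .data$source == "obis" & has_bad ~ 0L,
        .data$source == "obis" ~ NA_integer_,
        .data$source == "gbif" ~ NA_integer_
      )
    )
}

#' Clean occurrence coordinates
#'
#' Rounds coordinates to 4 decimal places (round-half-even), removes records
#' at exactly (0, 0), and removes records with out-of-bounds coordinates.
#' Removals are reported as an attribute, never as an error.
#'
#' @param records Occurrence tibble.
#' @return Cleaned tibble; attribute `removed` holds a named count vector
#'   (`zero_zero`, `out_of_bounds`). Flags are never touched.
#' @export
clean_coordinates <- function(records) {
  records <- as_occurrence_tbl(records)
  records$lon <- round_half_even(records$lon, 4)
  records$lat <- round_half_even(records$lat, 4)
  zz <- !is.na(records$lon) & !is.na(records$lat) &
    records$lon == 0 & records$lat == 0
  oob <- is.na(records$lon) | is.na(records$lat) |
    records$lon < -180 | records$lon > 180 |
    records$lat < -90 | records$lat > 90
  oob <- oob & !zz
  out <- records[!zz & !oob, , drop = FALSE]
  attr(out, "removed") <- c(zero_zero = sum(zz), out_of_bounds = sum(oob))
  out
}

#' Deduplicate occurrence records
#'
#' Groups records on (`taxon_id`, `lon`, `lat`, `year`, `month`) — missing
#' year/month acting as a distinct key value — and keeps exactly one record
#' per group: the most complete one, completeness being
#' `has(flag) + has(basis_of_record)`. Ties break by source priority
#' (`aquamaps` > `obis` > `gbif` > `synthetic`), then first-seen order.
#'
#' @param records Occurrence tibble with cleaned coordinates.
#' @return Tibble with one record per duplicate group, in first-seen order.
#' @export
deduplicate <- function(records) {
  records <- as_occurrence_tbl(records)
  pri <- match(records$source, occ_sources)
  records |>
    dplyr::mutate(
      .order = dplyr::row_number(),
      .completeness = as.integer(!is.na(.data$flag)) +
        as.integer(!is.na(.data$basis_of_record)),
      .priority = pri
    ) |>
    dplyr::group_by(
      .data$taxon_id, .data$lon, .data$lat, .data$year, .data$month
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$.completeness), .data$.priority, .data$.order,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order", -".completeness", -".priority")
}

#' Read / write occurrence CSV
#'
#' External CSV layout mirrors the field convention: columns `taxon_id`,
#' `lon`, `lat`, `year`, `month`, `basisOfRecord`, `source`, `original_flags`
#' (semicolon-joined) and `GOODOCC` (1 / 0 / empty for unflagged).
#'
#' @param path File path.
#' @return `read_occurrences()` returns the internal occurrence tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(taxon_id = "character"))
  tibble::tibble(
    taxon_id = df$taxon_id,
    lon = as.numeric(df$lon), lat = as.numeric(df$lat),
    year = suppressWarnings(as.integer(df$year)),
    month = suppressWarnings(as.integer(df$month)),
    basis_of_record = dplyr::na_if(as.character(df$basisOfRecord), ""),
    source = df$source,
    original_flags = ifelse(is.na(df$original_flags), "", df$original_flags),
    flag = suppressWarnings(as.integer(df$GOODOCC))
  )
}

#' @rdname read_occurrences
#' @param records Occurrence tibble.
#' @export
write_occurrences <- function(records, path) {
  records <- as_occurrence_tbl(records)
  out <- data.frame(
    taxon_id = records$taxon_id,
    lon = records$lon, lat = records$lat,
    year = records$year, month = records$month,
    basisOfRecord = ifelse(is.na(records$basis_of_record), "",
                           records$basis_of_record),
    source = records$source,
    original_flags = records$original_flags,
    GOODOCC = ifelse(is.na(records$flag), "", as.character(records$flag))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
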