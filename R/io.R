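#' Validate a long peak-area table and normalise time units
#'
#' The peak-area schema is long format, one modified species per row:
#' `site_id`, `chain`, `resnum`, `restype`, `exposure_time`, `time_unit`
#' (`"s"` or `"ms"`), `replicate_id`, `area_unmodified`, `species_label`,
#' `area_modified`. Exposure times are converted to seconds. Rows with
#' negative areas are rejected and collected in the `"rejected"` attribute
#' (with their row numbers) rather than silently dropped.
#'
#' @param df Data frame in the schema above (extra columns are kept).
#' @return Validated tibble with `exposure_time` in seconds and `time_unit`
#'   set to `"s"`; attribute `"rejected"` holds a tibble of rejected rows
#'   with a `row` and `reason` column.
#' @export
as_peak_area_table <- function(df) {
  required <- c("site_id", "chain", "resnum", "restype", "exposure_time",
                "time_unit", "replicate_id", "area_unmodified",
                "species_label", "area_modified")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("peak-area table missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  bad <- !is.finite(df$area_unmodified) | df$area_unmodified < 0 |
    !is.finite(df$area_modified) | df$area_modified < 0 |
    !is.finite(df$exposure_time) | df$exposure_time < 0
  rejected <- df[bad, ]
  if (nrow(rejected)) {
    rejected$row <- which(bad)
    rejected$reason <- "negative or non-finite area/time"
    warning("rejected ", nrow(rejected), " row(s) with negative or ",
            "non-finite values (see attr 'rejected')")
  }
  df <- df[!bad, ]
  df$exposure_time <- df$exposure_time * .time_unit_factor(df$time_unit)
  df$time_unit <- "s"
  attr(df, "rejected") <- rejected
  df
}

#' Read a peak-area CSV
#'
#' Comma-separated, UTF-8, header required; schema as documented in
#' [as_peak_area_table()]. Residue identifiers use author (PDB) numbering.
#'
#' @param path CSV file path.
#' @return Validated peak-area tibble (exposure times in seconds).
#' @export
read_peak_area_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  as_peak_area_table(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a peak-area table to CSV
#'
#' @param table Peak-area tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_area_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run: the configuration (written
#' verbatim), the RNG seed, input file paths with MD5 hashes, and package
#' versions.
#'
#' @param path Output JSON path.
#' @param config Named list of run configuration.
#' @param seed Integer seed used for the run (or `NULL`).
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NULL,
                           inputs = character()) {
  manifest <- list(
    config = config,
    seed = seed,
    inputs = lapply(stats::setNames(inputs, inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    versions = list(
      hrfassay = as.character(utils::packageVersion("hrfassay")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
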