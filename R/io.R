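PEAK_TABLE_COLUMNS <- c("condition_id", "covariate", "peak_id", "conformer",
                        "volume", "volume_sd", "unperturbed")

as_tibble_checked <- function(x, required) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Validate a peak-volume table
#'
#' Checks the standard peak-volume dialect: required columns
#' `condition_id`, `covariate`, `peak_id`, `conformer`, `volume`
#' (optional `volume_sd`, `unperturbed`), conformer labels in
#' {`WT`, `SLIP`} (case-insensitive, normalised to upper case),
#' non-negative volumes, and uniqueness of `peak_id` within each
#' condition. An `intensity` column is accepted in place of `volume` with
#' a warning: peak volumes are the primary observable, heights are
#' treated identically but flagged.
#'
#' @param table A data frame in the peak-volume dialect.
#' @return The validated table as a tibble.
#' @export
validate_peak_table <- function(table) {
  x <- tibble::as_tibble(table)
  if (!"volume" %in% names(x) && "intensity" %in% names(x)) {
    warning("using peak 'intensity' column as 'volume'; volumes are the ",
            "primary observable", call. = FALSE)
    x$volume <- x$intensity
  }
  x <- as_tibble_checked(x, c("condition_id", "covariate", "peak_id",
                              "conformer", "volume"))
  x$conformer <- toupper(as.character(x$conformer))
  bad_conf <- !x$conformer %in% c("WT", "SLIP")
  if (any(bad_conf)) {
    stop("conformer labels must be WT or SLIP; found: ",
         paste(unique(x$conformer[bad_conf]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(x$volume) || anyNA(x$volume) || any(x$volume < 0)) {
    stop("volumes must be non-negative numbers", call. = FALSE)
  }
  if (!is.numeric(x$covariate) || anyNA(x$covariate)) {
    stop("covariate must be numeric (temperature K or ligand µM)",
         call. = FALSE)
  }
  key <- paste(x$condition_id, x$peak_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), c("condition_id", "peak_id")]
    stop("duplicated peak_id within condition: ",
         paste(unique(paste0(dup$condition_id, "/", dup$peak_id)),
               collapse = ", "), call. = FALSE)
  }
  if (!"volume_sd" %in% names(x)) x$volume_sd <- NA_real_
  if (!"unperturbed" %in% names(x)) x$unperturbed <- NA
  x$unperturbed <- as.logical(x$unperturbed)
  x[c(PEAK_TABLE_COLUMNS, setdiff(names(x), PEAK_TABLE_COLUMNS))]
}

#' Read and write peak-volume tables
#'
#' The on-disk dialect is a delimited text file (comma- or tab-delimited,
#' auto-detected from the header line) with exactly the header
#' `condition_id, covariate, peak_id, conformer, volume, volume_sd,
#' unperturbed`. Empty `volume_sd` cells are read as missing.
#' `write_peak_table()` writes the same dialect, so
#' `read_peak_table(write_peak_table(x, f))` round-trips.
#'
#' Two small synthetic example tables ship with the package (a ligand
#' titration and a temperature series with a high-temperature plateau,
#' both generated by [generate_titration()] /
#' [generate_equilibrium_series()] at 3% volume noise).
#'
#' @param path File path.
#' @return `read_peak_table()`: a validated peak-volume tibble.
#' @examples
#' f <- system.file("extdata", "synthetic_titration_peaks.csv",
#'                  package = "foldshift")
#' read_peak_table(f)
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  got <- trimws(strsplit(header, sep, fixed = TRUE)[[1]])
  if (!identical(got, PEAK_TABLE_COLUMNS)) {
    stop("malformed peak-table header in ", path, "\n  expected: ",
         paste(PEAK_TABLE_COLUMNS, collapse = ", "), "\n  found:    ",
         paste(got, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           colClasses = c(condition_id = "character",
                                          covariate = "numeric",
                                          peak_id = "character",
                                          conformer = "character",
                                          volume = "numeric",
                                          volume_sd = "numeric",
                                          unperturbed = "logical"))
  validate_peak_table(raw)
}

#' @param table A peak-volume table.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @rdname read_peak_table
#' @return `write_peak_table()`: `path`, invisibly.
#' @export
write_peak_table <- function(table, path, sep = ",") {
  table <- validate_peak_table(table)
  utils::write.table(table[PEAK_TABLE_COLUMNS], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an equilibrium-measurement table
#'
#' Delimited text with columns `condition_id`, `covariate`, `percent_wt`,
#' `percent_slip`, `sd_percent` (comma- or tab-delimited, auto-detected);
#' `keq` is derived from `percent_wt` when absent.
#'
#' @param path File path.
#' @return A tibble of equilibrium measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, na.strings = c("", "NA"))
  )
  x <- as_tibble_checked(x, c("condition_id", "covariate", "percent_wt"))
  if (!"percent_slip" %in% names(x)) x$percent_slip <- 100 - x$percent_wt
  if (!"keq" %in% names(x)) x$keq <- keq_from_percent(x$percent_wt)
  x
}
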