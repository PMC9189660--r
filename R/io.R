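# Shared table IO: schema-validated CSV readers/writers with commented
# metadata headers, and seed management for the pipeline.

.schemas <- list(
  partition_pairs = list(
    required = c(division_id = "any", I1 = "numeric", I2 = "numeric")),
  cells = list(
    required = c(cell_id = "any", strain = "any", atc_ng_ml = "numeric",
                 total_fluor = "numeric"),
    optional = c(cofactor_uM = "numeric", channel = "any",
                 mean_pixel_intensity = "numeric",
                 pixel_area = "numeric")),
  foldchange = list(
    required = c(cell_id = "any", site_id = "any", position = "any",
                 cofactor_uM = "numeric", tf_copies = "numeric",
                 fold_change = "numeric")),
  growth = list(
    required = c(strain = "any", atc_ng_ml = "numeric",
                 time_h = "numeric", od600 = "numeric"))
)

# Derive total_fluor from mean pixel intensity x pixel area when absent.
#' @noRd
derive_total_fluor <- function(cells) {
  if (!"total_fluor" %in% names(cells)) {
    if (all(c("mean_pixel_intensity", "pixel_area") %in% names(cells))) {
      cells$total_fluor <- cells$mean_pixel_intensity * cells$pixel_area
      warning("total_fluor derived from mean_pixel_intensity * pixel_area",
              call. = FALSE)
    } else {
      stop(paste("cells table needs total_fluor, or both",
                 "mean_pixel_intensity and pixel_area"), call. = FALSE)
    }
  }
  cells
}

#' Read and validate a pipeline CSV table
#'
#' Reads a CSV (skipping `#`-prefixed metadata header lines) and
#' validates it against one of the named schemas: `partition_pairs`,
#' `cells`, `foldchange`, `growth`. Missing required columns are an
#' error; rows with unparseable or invalid numerics (e.g. negative
#' `od600`) are dropped and reported via the `row_report` attribute.
#' A `cells` table lacking `total_fluor` but carrying
#' `mean_pixel_intensity` and `pixel_area` has it derived, with a
#' warning.
#'
#' @param path CSV file path.
#' @param schema_name One of `names(tftitrate:::.schemas)`.
#' @return A validated tibble; attribute `row_report` lists dropped rows
#'   (line number and reason).
#' @export
read_table <- function(path, schema_name) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .schemas[[schema_name]]
  if (is.null(schema))
    stop("unknown schema: ", schema_name, call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (schema_name == "cells") df <- derive_total_fluor(df)
  missing <- setdiff(names(schema$required), names(df))
  if (length(missing) > 0)
    stop(sprintf("schema '%s': missing columns: %s", schema_name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  report <- list()
  bad <- rep(FALSE, nrow(df))
  numeric_cols <- names(schema$required)[schema$required == "numeric"]
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    nonnum <- is.na(vals) & !is.na(df[[col]])
    if (any(nonnum))
      report[[length(report) + 1L]] <-
        tibble(row = which(nonnum), column = col,
               reason = "unparseable numeric")
    bad <- bad | nonnum | is.na(vals)
    df[[col]] <- vals
  }
  if (schema_name == "growth") {
    neg <- !bad & df$od600 < 0
    if (any(neg))
      report[[length(report) + 1L]] <-
        tibble(row = which(neg), column = "od600",
               reason = "negative OD600")
    bad <- bad | neg
  }
  out <- as_tibble(df[!bad, , drop = FALSE])
  attr(out, "row_report") <- if (length(report) > 0)
    dplyr::bind_rows(report) else tibble(row = integer(),
                                         column = character(),
                                         reason = character())
  out
}

#' Write a pipeline CSV table with a commented metadata header
#'
#' Writes `#`-prefixed header lines (package version, seed, and any
#' extra metadata) followed by the CSV body. [read_table()] skips the
#' header transparently.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be NULL).
#' @param meta Named list of extra metadata entries.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, seed = NULL, meta = list()) {
  hdr <- c(sprintf("# tftitrate %s",
                   as.character(utils::packageVersion("tftitrate"))),
           if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
           vapply(names(meta), function(k)
             sprintf("# %s: %s", k, meta[[k]]), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

# Derive a per-stage seed from the global seed; kept < 2^31.
#' @noRd
derive_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 97L + stage_index * 1009L) %%
               .Machine$integer.max)
}
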