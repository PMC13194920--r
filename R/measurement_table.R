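#' Measurement table column order
#'
#' Fixed, deterministic column order of the per-cell measurement CSV.
#' @keywords internal
measurement_columns <- c(
  "image_id", "cell_label", "length_um", "mean_width_um", "surface_um2",
  "volume_um3", "cross_section_um2", "convex_hull_um2", "eccentricity",
  "solidity", "branched", "degenerate", "border_touching"
)

empty_measurement_table <- function() {
  out <- data.frame(
    image_id = character(0), cell_label = integer(0),
    length_um = numeric(0), mean_width_um = numeric(0),
    surface_um2 = numeric(0), volume_um3 = numeric(0),
    cross_section_um2 = numeric(0), convex_hull_um2 = numeric(0),
    eccentricity = numeric(0), solidity = numeric(0),
    branched = logical(0), degenerate = logical(0),
    border_touching = logical(0),
    stringsAsFactors = FALSE
  )
  out[, measurement_columns]
}

#' Write a per-cell measurement table to CSV
#'
#' One row per cell, header row, fixed column order. A write/read round trip
#' reproduces the values to at least 6 significant digits.
#'
#' @param table data.frame with the measurement columns (extra columns are
#'   dropped with a warning; missing metric columns are an error).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  missing <- setdiff(measurement_columns, names(table))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(table), measurement_columns)
  if (length(extra))
    warning("dropping non-standard columns: ", paste(extra, collapse = ", "))
  tab <- table[, measurement_columns, drop = FALSE]
  if (nrow(tab) && anyDuplicated(tab[, c("image_id", "cell_label")]))
    stop("(image_id, cell_label) pairs must be unique")
  utils::write.csv(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell measurement table from CSV
#'
#' @param path CSV written by [write_measurement_table()].
#' @return data.frame in the standard column order.
#' @export
read_measurement_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurement_columns, names(tab))
  if (length(missing))
    stop("not a measurement table, lacks: ", paste(missing, collapse = ", "))
  for (fl in c("branched", "degenerate", "border_touching"))
    tab[[fl]] <- as.logical(tab[[fl]])
  tab[, measurement_columns]
}
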