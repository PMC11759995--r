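# Borehole sample tables: one row per physical soil sample, carrying the 3D
# location (projected metres + depth), six physico-chemical covariates and the
# petroleum-hydrocarbon index target.

#' Canonical channel order of the feature tensor
#'
#' Coordinates first (easting, northing, depth), then the six soil
#' physico-chemical covariates. The target column is `tph`.
#' @export
borehole_features <- function() {
  c("easting", "northing", "depth", "ph", "wet_bulk_density",
    "permeability_coefficient", "organic", "avg_water_yield", "salinity")
}

borehole_columns <- function() c(borehole_features(), "tph")

default_schema <- function() {
  cols <- borehole_columns()
  stats::setNames(as.list(cols), cols)
}

#' Read a borehole sample table
#'
#' Reads a delimiter-separated text file with a header row into a borehole
#' record data frame. Columns are located through `schema`, a named list
#' mapping canonical field names (see [borehole_features()] plus `tph`) to
#' the column names used in the file. Parsing is strict: every mapped cell
#' must be numeric.
#'
#' @param path file path.
#' @param schema named list mapping canonical names to file column names;
#'   defaults to the identity mapping.
#' @param sep field delimiter (default tab).
#' @param target_optional if `TRUE` the `tph` column may be absent (records
#'   intended for prediction only).
#' @return data frame with the canonical columns, one row per sample, in file
#'   order, of class `borehole_records`.
#' @export
read_boreholes <- function(path, schema = default_schema(), sep = "\t",
                           target_optional = FALSE) {
  if (!file.exists(path)) stop("borehole file does not exist: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- borehole_columns()
  out <- list()
  for (field in need) {
    col <- schema[[field]] %||% field
    if (!col %in% names(raw)) {
      if (field == "tph" && target_optional) {
        out[[field]] <- rep(NA_real_, nrow(raw))
        next
      }
      stop("schema error: column '", col, "' (field '", field,
           "') missing from ", path)
    }
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(raw[[col]] %in% c("NA", "")))
    bad <- union(bad, which(is.na(vals) & field != "tph"))
    if (length(bad))
      stop("parse error: non-numeric value '", raw[[col]][bad[1]],
           "' in column '", col, "' at data row ", bad[1])
    out[[field]] <- vals
  }
  rec <- as.data.frame(out)
  validate_boreholes(rec, require_target = FALSE)
  class(rec) <- c("borehole_records", "data.frame")
  rec
}

#' Write a borehole table
#'
#' @param records borehole record data frame.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_boreholes <- function(records, path, sep = "\t") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

validate_boreholes <- function(records, require_target = TRUE) {
  need <- borehole_features()
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing borehole fields: ", paste(miss, collapse = ", "))
  if (any(records$depth < 0, na.rm = TRUE)) stop("negative depth in borehole records")
  for (f in need)
    if (any(!is.finite(records[[f]])))
      stop("non-finite values in covariate '", f, "'")
  if (require_target && any(!is.finite(records$tph)))
    stop("training records must have a finite tph target")
  invisible(records)
}

as_borehole_records <- function(df) {
  validate_boreholes(df, require_target = FALSE)
  if (!"tph" %in% names(df)) df$tph <- NA_real_
  class(df) <- c("borehole_records", "data.frame")
  df
}
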