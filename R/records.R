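#' Assemble a validated table of accident records
#'
#' The accident table is the universe every detector consumes: one row per
#' accident with WGS84 coordinates, two severity outcomes (fatalities and
#' injuries) and one integer-coded column per declared factor.  Missing factor
#' values are admitted as `NA` and are dropped record-wise from any detector
#' run involving that factor.
#'
#' @param records A data.frame with columns `record_id`, `lon`, `lat`, `year`,
#'   `fatalities`, `injuries` and one column per factor named in `coding`.
#' @param coding Named list of [factor_coding()] objects.
#' @return An object of class `"accident_table"` with elements `records` and
#'   `coding`.
#' @seealso [read_accident_csv()], [split_groups()], [stratify()]
#' @export
accident_table <- function(records, coding) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!length(coding) || is.null(names(coding)) || any(!nzchar(names(coding))))
    stop("'coding' must be a named list of factor codings", call. = FALSE)
  for (fc in coding) {
    if (!inherits(fc, "factor_coding"))
      stop("every element of 'coding' must be a factor_coding", call. = FALSE)
  }
  obj <- structure(list(records = records, coding = coding),
                   class = "accident_table")
  validate_accident_table(obj)
  obj
}

required_record_columns <- c("record_id", "lon", "lat", "year",
                             "fatalities", "injuries")

#' Validate an accident table
#'
#' Checks the structural invariants: all required columns present, at least
#' one record, non-negative finite outcomes, coordinates within WGS84 bounds,
#' and every non-missing factor code a member of its declared category set.
#' Violations raise errors that list the offending rows.
#'
#' @param x An [accident_table()].
#' @return `x`, invisibly, if valid.
#' @export
validate_accident_table <- function(x) {
  stopifnot(inherits(x, "accident_table"))
  rec <- x$records
  missing_cols <- setdiff(c(required_record_columns, names(x$coding)),
                          names(rec))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rec) == 0L) stop("accident table must contain at least one record",
                            call. = FALSE)
  bad_rows <- function(flag) paste(which(flag), collapse = ", ")
  for (oc in c("fatalities", "injuries")) {
    v <- rec[[oc]]
    if (!is.numeric(v)) stop("column '", oc, "' must be numeric", call. = FALSE)
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop("invalid ", oc, " (negative or non-finite) in row(s): ",
           bad_rows(bad), call. = FALSE)
    }
  }
  bad <- !is.finite(rec$lon) | abs(rec$lon) > 180 |
         !is.finite(rec$lat) | abs(rec$lat) > 90
  if (any(bad)) {
    stop("coordinates outside WGS84 bounds in row(s): ", bad_rows(bad),
         call. = FALSE)
  }
  for (fn in names(x$coding)) {
    codes <- rec[[fn]]
    bad <- !is.na(codes) & !(codes %in% x$coding[[fn]]$codes)
    if (any(bad)) {
      stop("undeclared category code for factor '", fn, "' in row(s): ",
           bad_rows(bad), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.accident_table <- function(x, ...) {
  rec <- x$records
  cat("Accident table: ", nrow(rec), " records, ",
      length(x$coding), " coded factors\n", sep = "")
  cat("  fatalities: mean ", signif(mean(rec$fatalities), 4),
      ", injuries: mean ", signif(mean(rec$injuries), 4), "\n", sep = "")
  cat("  factors: ", paste(names(x$coding), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.accident_table <- function(x) dim(x$records)

#' Read accident records from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming at least the
#' identifier, coordinate and outcome columns plus every factor declared in
#' `coding`.  Rows violating the coding are rejected with row-level
#' diagnostics (the whole read fails; nothing is silently dropped).
#'
#' @param path CSV file path.
#' @param coding Named list of [factor_coding()] objects, e.g.
#'   [shenzhen_codings()].
#' @return An [accident_table()].
#' @export
read_accident_csv <- function(path, coding) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(c(required_record_columns, names(coding)),
                          names(rec))
  if (length(missing_cols)) {
    stop("CSV ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec$record_id <- as.character(rec$record_id)
  for (fn in names(coding)) rec[[fn]] <- as.integer(rec[[fn]])
  accident_table(rec, coding)
}

#' Write accident records to CSV
#'
#' Writes the record table so that [read_accident_csv()] with the same coding
#' reproduces it exactly (comma separator, `"."` decimal mark, header row).
#'
#' @param table An [accident_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accident_csv <- function(table, path) {
  validate_accident_table(table)
  cols <- c(required_record_columns, names(table$coding))
  utils::write.csv(table$records[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export accident records as GeoJSON points
#'
#' One `Feature` per record with a `Point` geometry (lon, lat) and the
#' outcomes, year and factor codes as properties.  Intended for mapping in
#' external tools.
#'
#' @param table An [accident_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accident_geojson <- function(table, path) {
  validate_accident_table(table)
  rec <- table$records
  prop_cols <- setdiff(names(rec), c("lon", "lat"))
  features <- lapply(seq_len(nrow(rec)), function(i) {
    props <- as.list(rec[i, prop_cols, drop = FALSE])
    props <- lapply(props, function(v) if (is.na(v)) NULL else v)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(rec$lon[i], rec$lat[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Split records into the fatality and injuries-only analysis groups
#'
#' Group 1 collects records with at least one fatality and is analysed on the
#' fatalities outcome; group 2 collects records with no fatalities but at
#' least one injury and is analysed on the injuries outcome.  Records with
#' neither are excluded and counted in the diagnostics.
#'
#' @param table An [accident_table()].
#' @return A list with elements `group1`, `group2` (accident tables or `NULL`
#'   when empty), `excluded` (count of zero-casualty records) and `n` (input
#'   record count).
#' @export
split_groups <- function(table) {
  validate_accident_table(table)
  rec <- table$records
  in1 <- rec$fatalities >= 1
  in2 <- !in1 & rec$injuries >= 1
  excluded <- sum(!in1 & !in2)
  sub <- function(keep) {
    if (!any(keep)) return(NULL)
    accident_table(rec[keep, , drop = FALSE], table$coding)
  }
  g1 <- sub(in1)
  g2 <- sub(in2)
  if (is.null(g1)) warning("group 1 (fatalities) is empty", call. = FALSE)
  if (is.null(g2)) warning("group 2 (injuries only) is empty", call. = FALSE)
  list(group1 = g1, group2 = g2, excluded = excluded, n = nrow(rec))
}

#' Stratify records by a factor
#'
#' Builds the partition of the records induced by the observed categories of
#' one factor (or of the `year` column, which is treated as a detectable
#' factor).  Records with a missing code get an `NA` assignment and do not
#' enter any stratum.
#'
#' @param table An [accident_table()].
#' @param factor Name of a declared factor, or `"year"`.
#' @return An object of class `"stratification"` with elements `source`
#'   (factor names), `assignment` (per-record stratum label, `NA` for
#'   missing), `strata` (data.frame of `label`, `n`) and `n_used`.
#' @export
stratify <- function(table, factor) {
  validate_accident_table(table)
  stopifnot(is.character(factor), length(factor) == 1L)
  if (!factor %in% c(names(table$coding), "year")) {
    stop("unknown factor '", factor, "'", call. = FALSE)
  }
  codes <- table$records[[factor]]
  labels <- ifelse(is.na(codes), NA_character_, paste0(factor, "=", codes))
  new_stratification(source = factor, assignment = labels)
}

new_stratification <- function(source, assignment) {
  present <- !is.na(assignment)
  tab <- table(assignment[present])
  structure(list(source = source,
                 assignment = assignment,
                 strata = data.frame(label = names(tab),
                                     n = as.integer(tab),
                                     stringsAsFactors = FALSE),
                 n_used = sum(present)),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("Stratification by ", paste(x$source, collapse = " ∩ "), ": ",
      nrow(x$strata), " strata over ", x$n_used, " records",
      if (any(is.na(x$assignment))) paste0(" (", sum(is.na(x$assignment)),
                                           " missing)"),
      "\n", sep = "")
  invisible(x)
}

# Coerce a stratification-or-vector argument to a stratification object;
# used by every detector so plain label vectors work too.
as_stratification <- function(strat) {
  if (inherits(strat, "stratification")) return(strat)
  new_stratification(source = "strata", assignment = as.character(strat))
}
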