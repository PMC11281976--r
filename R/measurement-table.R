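META_COLUMNS <- c("specimen_id", "breed", "group", "maturity", "sex", "age",
                  "locality", "source")

#' Construct a measurement table
#'
#' The measurement table is the universal currency of the pipeline: a
#' specimens-by-variables numeric matrix (column order fixed by the catalog)
#' plus one row of specimen metadata per specimen. Missing cells are allowed
#' at this stage; analyses require a complete table (see
#' [filter_complete()]).
#'
#' Validation enforced here: column order matches the catalog; specimen ids
#' are unique; all non-missing linear values are strictly positive (lengths
#' are positive quantities); angle values lie in (0, 360) degrees.
#'
#' @param values Numeric matrix or data.frame, one column per catalog
#'   variable (matched and reordered by name).
#' @param meta data.frame of specimen metadata with at least `specimen_id`;
#'   recognised columns are `specimen_id, breed, group, maturity, sex, age,
#'   locality, source` (missing ones are filled with `NA`; `maturity`
#'   defaults to `"unknown"`).
#' @param catalog A [variable_catalog].
#' @return A `measurement_table`: list with elements `values`, `meta`,
#'   `catalog`.
#' @export
measurement_table <- function(values, meta, catalog) {
  stopifnot(inherits(catalog, "variable_catalog"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing_cols <- setdiff(catalog$abbreviation, colnames(values))
  if (length(missing_cols)) {
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
  }
  values <- values[, catalog$abbreviation, drop = FALSE]

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$specimen_id)) stop("meta lacks required column specimen_id")
  meta$specimen_id <- as.character(meta$specimen_id)
  if (nrow(meta) != nrow(values)) {
    stop("meta has ", nrow(meta), " rows but values has ", nrow(values))
  }
  dup <- unique(meta$specimen_id[duplicated(meta$specimen_id)])
  if (length(dup)) {
    stop("duplicate specimen_id(s): ", paste(dup, collapse = ", "))
  }
  for (col in META_COLUMNS) {
    if (is.null(meta[[col]])) {
      meta[[col]] <- if (col == "maturity") "unknown" else NA_character_
    }
  }
  meta <- meta[, META_COLUMNS]
  rownames(values) <- meta$specimen_id
  rownames(meta) <- NULL

  lin <- linear_variables(catalog)
  bad_lin <- values[, lin, drop = FALSE] <= 0
  if (any(bad_lin, na.rm = TRUE)) {
    stop("non-positive linear measurement(s) in specimen(s): ",
         paste(unique(rownames(values)[which(bad_lin, arr.ind = TRUE)[, 1]]),
               collapse = ", "))
  }
  ang <- angle_variables(catalog)
  if (length(ang)) {
    bad_ang <- values[, ang, drop = FALSE] <= 0 | values[, ang, drop = FALSE] >= 360
    if (any(bad_ang, na.rm = TRUE)) {
      stop("angle measurement(s) outside (0, 360) in specimen(s): ",
           paste(unique(rownames(values)[which(bad_ang, arr.ind = TRUE)[, 1]]),
                 collapse = ", "))
    }
  }
  structure(list(values = values, meta = meta, catalog = catalog),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(sprintf("Measurement table: %d specimens x %d variables ('%s'), %d missing cell(s)\n",
              nrow(x$values), ncol(x$values),
              catalog_structure(x$catalog), n_missing))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && length(dropped)) {
    cat(sprintf("  (%d specimen(s) dropped by the last filter)\n", length(dropped)))
  }
  invisible(x)
}

#' Number of specimens in a measurement table
#' @param x A `measurement_table`.
#' @return Integer count of specimens (rows).
#' @export
n_specimens <- function(x) nrow(x$values)

#' Specimens dropped by the most recent filtering step
#' @param x A `measurement_table` returned by [filter_complete()] or
#'   [filter_mature()].
#' @return Character vector of dropped specimen ids (empty if none).
#' @export
dropped_specimens <- function(x) {
  d <- attr(x, "dropped")
  if (is.null(d)) character(0) else d
}

#' Read a measurement table from a delimited or spreadsheet file
#'
#' CSV (or TSV) with a header of variable abbreviations plus metadata columns
#' is the canonical interchange format; `.xlsx` files are read through the
#' readxl package when available (read-only). Cells that do not parse as
#' numbers, non-positive linear values, and angles outside (0, 360) are
#' coerced to missing with a warning, so a single bad cell costs at most one
#' specimen downstream (listwise deletion in [filter_complete()]), never the
#' run.
#'
#' @param path File to read.
#' @param catalog A [variable_catalog]; every abbreviation must resolve to a
#'   column (possibly through `dialect`).
#' @param dialect Optional named character vector mapping catalog
#'   abbreviations to column names in the file, for files with non-standard
#'   headers.
#' @param sep Field separator for text files (`","` default; `"\t"` for TSV).
#' @return A validated `measurement_table`.
#' @export
read_measurements <- function(path, catalog, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the readxl package; ",
           "export the sheet to CSV instead")
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  }

  cols <- catalog$abbreviation
  file_col <- if (is.null(dialect)) {
    stats::setNames(cols, cols)
  } else {
    out <- stats::setNames(cols, cols)
    out[names(dialect)] <- dialect
    out
  }
  absent <- cols[!file_col[cols] %in% names(df)]
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  if (!"specimen_id" %in% names(df)) stop("missing required column(s): specimen_id")

  values <- matrix(NA_real_, nrow(df), length(cols),
                   dimnames = list(NULL, cols))
  n_coerced <- 0L
  for (ab in cols) {
    raw <- df[[file_col[[ab]]]]
    num <- suppressWarnings(as.numeric(raw))
    unparseable <- !is.na(raw) & raw != "" & is.na(num)
    n_coerced <- n_coerced + sum(unparseable)
    kind <- catalog$kind[catalog$abbreviation == ab]
    if (kind == "linear") {
      bad <- !is.na(num) & num <= 0
    } else {
      bad <- !is.na(num) & (num <= 0 | num >= 360)
    }
    n_coerced <- n_coerced + sum(bad)
    num[bad] <- NA_real_
    values[, ab] <- num
  }
  if (n_coerced > 0) {
    warning(n_coerced, " cell(s) unparseable or out of range; set to missing")
  }
  meta <- df[, intersect(META_COLUMNS, names(df)), drop = FALSE]
  measurement_table(values, meta, catalog)
}

#' Write a measurement table to CSV
#'
#' Values are serialized with 17 significant digits so that a
#' read-write-read round trip reproduces every finite cell bit-for-bit and
#' preserves the missingness pattern.
#'
#' @param x A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  vals <- apply(x$values, 2, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, colnames(x$values)))
  df <- cbind(x$meta, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Retain only specimens with complete measurements
#'
#' Listwise deletion over the catalog variables: a specimen with any missing
#' cell is excluded, mirroring the study-design rule that incompletely
#' measured individuals do not enter the multivariate analyses. No
#' imputation is performed.
#'
#' @param x A `measurement_table`.
#' @return The filtered table; dropped specimen ids are attached as the
#'   `"dropped"` attribute (see [dropped_specimens()]). Erroring when no
#'   specimen survives, since downstream PCA is undefined on an empty table.
#' @export
filter_complete <- function(x) {
  keep <- stats::complete.cases(x$values)
  if (!any(keep)) stop("no specimen has complete measurements")
  out <- measurement_table(x$values[keep, , drop = FALSE],
                           x$meta[keep, , drop = FALSE], x$catalog)
  attr(out, "dropped") <- x$meta$specimen_id[!keep]
  out
}

#' Retain only skeletally mature specimens
#'
#' The study design admits only confirmed-mature individuals (fully erupted
#' third upper molars). Specimens with `maturity == "unknown"` are dropped
#' by default — maturity must be positively established — but can be kept
#' with `unknown = "keep"`.
#'
#' @param x A `measurement_table`.
#' @param unknown `"drop"` (default) or `"keep"` for specimens whose
#'   maturity is not recorded.
#' @return The filtered table with dropped ids in the `"dropped"` attribute.
#'   An empty result is allowed here (it is caught by later stages).
#' @export
filter_mature <- function(x, unknown = c("drop", "keep")) {
  unknown <- match.arg(unknown)
  mat <- x$meta$maturity
  keep <- mat == "mature"
  if (unknown == "keep") keep <- keep | mat == "unknown"
  keep[is.na(keep)] <- FALSE
  out <- structure(list(values = x$values[keep, , drop = FALSE],
                        meta = x$meta[keep, , drop = FALSE],
                        catalog = x$catalog),
                   class = "measurement_table")
  rownames(out$meta) <- NULL
  attr(out, "dropped") <- x$meta$specimen_id[!keep]
  out
}

#' Concatenate two measurement tables
#'
#' Used to assemble an analysis dataset from several sources (newly measured
#' specimens, literature data, a comparative sample). Both tables must share
#' the same catalog; specimen ids must not collide. Per-row provenance
#' travels in the `source` metadata column.
#'
#' @param a,b `measurement_table`s over identical catalogs.
#' @return The concatenated `measurement_table` with `n_specimens(a) +
#'   n_specimens(b)` rows.
#' @export
merge_tables <- function(a, b) {
  if (!same_catalog(a$catalog, b$catalog)) {
    stop("cannot merge: measurement tables have different catalogs")
  }
  clash <- intersect(a$meta$specimen_id, b$meta$specimen_id)
  if (length(clash)) {
    stop("specimen_id collision(s): ", paste(clash, collapse = ", "))
  }
  measurement_table(rbind(a$values, b$values),
                    rbind(a$meta, b$meta), a$catalog)
}

#' Reassign analysis groups from a breed-to-group mapping
#'
#' Group membership is an analysis choice, not a property of the data, so it
#' lives in configuration: a named character vector mapping breed tokens to
#' group labels. Breeds absent from the map fall into `default_group`.
#'
#' @param x A `measurement_table`.
#' @param group_map Named character vector, `names` = breed tokens,
#'   values = group labels. `NULL` leaves groups untouched.
#' @param default_group Label for unmapped breeds.
#' @return The table with `meta$group` rewritten.
#' @export
assign_groups <- function(x, group_map, default_group = "Comparative") {
  if (is.null(group_map)) return(x)
  g <- unname(group_map[x$meta$breed])
  g[is.na(g)] <- default_group
  x$meta$group <- g
  x
}
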