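#' Variable catalogs for traditional morphometric measurement sets
#'
#' A variable catalog is the ordered list of measurement variables for one
#' anatomical structure: abbreviation, full name, kind (`linear` or `angle`),
#' units (`mm` for linear distances, `degrees` for angles) and an anatomical
#' definition. Catalogs validate measurement tables and decide which columns
#' enter the geometric-mean size proxy (linear variables only).
#'
#' Three catalogs ship with the package, covering the equid structures the
#' workflow was developed for:
#' \describe{
#'   \item{`cranium`}{9 linear measurements (BL, SBL, PL, MDL, PW, SI, CRL,
#'     FL, SW).}
#'   \item{`bony_labyrinth`}{7 linear measurements of the inner-ear cavity
#'     (C0--C3 canal/cochlea lengths, overall labyrinth length, crus commune
#'     length and circumference).}
#'   \item{`brain_endocast`}{13 measurements: 9 linear plus 4 angles (IHA,
#'     HPA, CSA, OFA). Angles are size-free by construction and are never
#'     standardized by the geometric mean.}
#' }
#'
#' @param structure One of `"cranium"`, `"bony_labyrinth"`, `"brain_endocast"`.
#' @return A `variable_catalog`: a data.frame with columns `abbreviation`,
#'   `name`, `kind`, `units`, `description` and a `structure` attribute.
#' @examples
#' cat9 <- standard_catalog("cranium")
#' nrow(cat9)
#' linear_variables(standard_catalog("brain_endocast"))
#' @export
standard_catalog <- function(structure = c("cranium", "bony_labyrinth",
                                           "brain_endocast")) {
  structure <- match.arg(structure)
  path <- system.file("extdata", paste0("catalog_", structure, ".csv"),
                      package = "lsrmorph", mustWork = TRUE)
  read_catalog(path, structure = structure)
}

#' Read a variable catalog from a CSV file
#'
#' The file must have columns `abbreviation`, `name`, `kind`, `units`,
#' `description`. User-supplied catalogs let the pipeline run on measurement
#' sets other than the three shipped ones.
#'
#' @param path CSV file path.
#' @param structure Label for the anatomical structure the catalog describes.
#' @return A `variable_catalog`.
#' @export
read_catalog <- function(path, structure = "custom") {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  variable_catalog(df, structure = structure)
}

#' Construct and validate a variable catalog
#'
#' @param variables data.frame with columns `abbreviation`, `name`, `kind`,
#'   `units`, `description` (the last two optional; units are filled from
#'   kind when absent).
#' @param structure Structure label.
#' @return A `variable_catalog`.
#' @export
variable_catalog <- function(variables, structure = "custom") {
  required <- c("abbreviation", "name", "kind")
  missing <- setdiff(required, names(variables))
  if (length(missing)) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "))
  }
  variables$kind <- as.character(variables$kind)
  bad_kind <- setdiff(unique(variables$kind), c("linear", "angle"))
  if (length(bad_kind)) {
    stop("unknown variable kind(s): ", paste(bad_kind, collapse = ", "))
  }
  if (anyDuplicated(variables$abbreviation)) {
    stop("duplicate abbreviation(s) in catalog: ",
         paste(unique(variables$abbreviation[duplicated(variables$abbreviation)]),
               collapse = ", "))
  }
  if (is.null(variables$units)) {
    variables$units <- ifelse(variables$kind == "angle", "degrees", "mm")
  }
  # kind fixes units: lengths in mm, angles in degrees
  ok <- (variables$kind == "linear" & variables$units == "mm") |
        (variables$kind == "angle" & variables$units == "degrees")
  if (!all(ok)) {
    stop("units inconsistent with kind for: ",
         paste(variables$abbreviation[!ok], collapse = ", "))
  }
  if (is.null(variables$description)) variables$description <- ""
  out <- variables[, c("abbreviation", "name", "kind", "units", "description")]
  rownames(out) <- NULL
  structure(out, structure = structure,
            class = c("variable_catalog", "data.frame"))
}

#' Abbreviations of the linear (size-carrying) variables of a catalog
#' @param catalog A `variable_catalog`.
#' @return Character vector of abbreviations with `kind == "linear"`.
#' @export
linear_variables <- function(catalog) {
  catalog$abbreviation[catalog$kind == "linear"]
}

#' Abbreviations of the angle variables of a catalog
#' @param catalog A `variable_catalog`.
#' @return Character vector of abbreviations with `kind == "angle"`.
#' @export
angle_variables <- function(catalog) {
  catalog$abbreviation[catalog$kind == "angle"]
}

catalog_structure <- function(catalog) attr(catalog, "structure")

same_catalog <- function(a, b) {
  identical(a$abbreviation, b$abbreviation) && identical(a$kind, b$kind)
}

#' @export
print.variable_catalog <- function(x, ...) {
  cat(sprintf("Variable catalog '%s': %d variables (%d linear, %d angle)\n",
              catalog_structure(x), nrow(x),
              sum(x$kind == "linear"), sum(x$kind == "angle")))
  print.data.frame(x[, c("abbreviation", "name", "kind", "units")], ...)
  invisible(x)
}
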