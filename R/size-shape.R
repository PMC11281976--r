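#' Geometric mean of a set of positive measurements
#'
#' The nth root of the product of n measurements, the classic overall-size
#' proxy for a specimen when no body-size datum is available and no single
#' variable should be privileged. Computed in log space,
#' `exp(mean(log(x)))`, for numerical stability with many or large
#' measurements.
#'
#' @param x Numeric vector of strictly positive linear measurements. Angle
#'   variables must be excluded by the caller: angles do not scale with size
#'   and have no place in a size proxy.
#' @return Scalar geometric mean, in the units of `x`.
#' @examples
#' geometric_mean(c(2, 8))      # 4
#' geometric_mean(c(1, 10, 100)) # 10
#' @export
geometric_mean <- function(x) {
  if (length(x) < 1) stop("geometric mean of an empty vector is undefined")
  if (anyNA(x)) stop("missing value in geometric mean input; filter incomplete specimens first")
  if (any(x <= 0)) stop("geometric mean requires strictly positive inputs")
  exp(mean(log(x)))
}

#' Per-specimen geometric-mean size proxy
#'
#' Computes the geometric mean of every specimen over the catalog's *linear*
#' variables (angles are size-free and excluded) together with its natural
#' logarithm, the size axis used by the allometry test.
#'
#' @param x A complete `measurement_table`.
#' @return A `size_vector`: data.frame with columns `specimen_id`, `gm`
#'   (mm), `log_gm` (natural log).
#' @export
size_vector <- function(x) {
  lin <- linear_variables(x$catalog)
  if (!length(lin)) stop("catalog has no linear variables; size proxy undefined")
  vals <- x$values[, lin, drop = FALSE]
  if (anyNA(vals)) {
    stop("table has missing linear values; apply filter_complete() first")
  }
  gm <- exp(rowMeans(log(vals)))
  out <- data.frame(specimen_id = x$meta$specimen_id, gm = gm,
                    log_gm = log(gm), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("size_vector", "data.frame")
  out
}

new_shape_matrix <- function(values, catalog, treatment, size = NULL) {
  structure(list(values = values, catalog = catalog,
                 treatment = treatment, size = size),
            class = "shape_matrix")
}

#' @export
print.shape_matrix <- function(x, ...) {
  cat(sprintf("Shape matrix (treatment = %s): %d specimens x %d variables ('%s')\n",
              x$treatment, nrow(x$values), ncol(x$values),
              catalog_structure(x$catalog)))
  invisible(x)
}

#' Form treatment: raw measurements
#'
#' The identity treatment. Raw values carry both size and shape; its PCA
#' axis 1 is typically dominated by overall size.
#'
#' @param x A complete `measurement_table`.
#' @return A `shape_matrix` with `treatment = "form"` (no size vector
#'   attached: size has not been factored out).
#' @export
form_treatment <- function(x) {
  if (anyNA(x$values)) stop("table has missing values; apply filter_complete() first")
  new_shape_matrix(x$values, x$catalog, "form")
}

#' Mosimann log shape ratios
#'
#' For each specimen, every linear measurement is replaced by the natural
#' log of its ratio to the specimen's geometric mean, `log(x_j / GM)`. The
#' resulting linear shape variables sum to zero within each specimen —
#' `sum_j log(x_j/GM) = log(prod x_j) - n log(GM) = 0` — and are invariant
#' to uniform rescaling of the specimen. Angle variables are already
#' size-free and are passed through unchanged (never standardized).
#'
#' @param x A complete `measurement_table`.
#' @return A `shape_matrix` with `treatment = "log_shape_ratio"` and the
#'   [size_vector()] used attached as `$size`.
#' @export
log_shape_ratios <- function(x) {
  sv <- size_vector(x)
  lin <- linear_variables(x$catalog)
  out <- x$values
  out[, lin] <- log(x$values[, lin, drop = FALSE] / sv$gm)
  new_shape_matrix(out, x$catalog, "log_shape_ratio", size = sv)
}

#' Allometry-free shape: residuals from regression on size
#'
#' Removes the size-predictable component of every variable by ordinary
#' least squares of the raw variable on the specimen geometric mean
#' (intercept + slope), returning the residual matrix. Fitting each response
#' separately is identical to taking the residual matrix of the multivariate
#' linear model of all variables on GM, since multivariate OLS residuals are
#' computed per response. Every residual column has mean zero and zero
#' sample covariance with GM.
#'
#' @param x A complete `measurement_table` with at least 3 specimens (with
#'   2 specimens a two-parameter fit is saturated and residuals are
#'   identically zero).
#' @param include_angles Residualize angle variables too (default `TRUE`:
#'   the full set of raw variables is regressed on size). With `FALSE`,
#'   angles are passed through raw as in [log_shape_ratios()].
#' @return A `shape_matrix` with `treatment = "allometry_free"` and the size
#'   vector attached.
#' @export
allometry_free <- function(x, include_angles = TRUE) {
  if (anyNA(x$values)) stop("table has missing values; apply filter_complete() first")
  if (nrow(x$values) < 3) {
    stop("allometry-free residuals need at least 3 specimens")
  }
  sv <- size_vector(x)
  if (stats::var(sv$gm) == 0) {
    stop("geometric mean has zero variance; residualization on size is undefined")
  }
  cols <- if (include_angles) colnames(x$values) else linear_variables(x$catalog)
  gm <- sv$gm
  resid <- stats::resid(stats::lm(x$values[, cols, drop = FALSE] ~ gm))
  resid <- matrix(resid, nrow = nrow(x$values),
                  dimnames = list(rownames(x$values), cols))
  out <- x$values
  out[, cols] <- resid
  new_shape_matrix(out, x$catalog, "allometry_free", size = sv)
}

#' Apply a named treatment to a measurement table
#'
#' @param x A complete `measurement_table`.
#' @param treatment `"form"`, `"log_shape_ratio"` or `"allometry_free"`.
#' @param include_angles Passed to [allometry_free()].
#' @return A `shape_matrix`.
#' @export
apply_treatment <- function(x, treatment = c("form", "log_shape_ratio",
                                             "allometry_free"),
                            include_angles = TRUE) {
  treatment <- match.arg(treatment)
  switch(treatment,
         form = form_treatment(x),
         log_shape_ratio = log_shape_ratios(x),
         allometry_free = allometry_free(x, include_angles = include_angles))
}
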