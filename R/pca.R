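#' Principal component analysis of a shape matrix
#'
#' Covariance PCA: columns are centered but not scaled to unit variance,
#' since within one treatment all variables are commensurate (mm, or
#' dimensionless log ratios). Components are computed by singular value
#' decomposition of the centered data matrix via [stats::prcomp()]; the
#' sample covariance uses the n-1 divisor. All components are retained —
#' reporting typically shows PC1-PC2, but truncation is presentation-only.
#' Axes are sign-fixed by [orient_axes()] before return, making outputs
#' reproducible across platforms (the sign of any eigenvector is otherwise
#' arbitrary).
#'
#' @param shape A `shape_matrix` (or plain numeric matrix, in which case
#'   `treatment` labels it).
#' @param use_correlation Use the correlation matrix (unit-variance scaling)
#'   instead of the covariance matrix. Not the default, and non-canonical
#'   for this workflow.
#' @param treatment Label used when `shape` is a bare matrix.
#' @return A `pca_model`: list with `treatment`, `mean_vector`, `loadings`
#'   (variables x components, orthonormal), `eigenvalues` (non-increasing),
#'   `scores` (specimens x components), `pct_variance` (sums to 100), and
#'   `size` (the size vector carried by the shape matrix, if any).
#' @export
fit_pca <- function(shape, use_correlation = FALSE, treatment = NULL) {
  if (inherits(shape, "shape_matrix")) {
    x <- shape$values
    treatment <- shape$treatment
    size <- shape$size
  } else {
    x <- as.matrix(shape)
    if (is.null(treatment)) treatment <- "unspecified"
    size <- NULL
  }
  if (nrow(x) < 2) stop("PCA needs at least 2 specimens")
  if (ncol(x) < 2) stop("PCA needs at least 2 variables")
  if (anyNA(x)) stop("PCA input contains missing cells")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0) {
    stop("total variance is zero for treatment '", treatment,
         "': PCA is degenerate")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = use_correlation)
  model <- structure(list(treatment = treatment,
                          mean_vector = pr$center,
                          loadings = pr$rotation,
                          eigenvalues = pr$sdev^2,
                          scores = pr$x,
                          pct_variance = 100 * pr$sdev^2 / sum(pr$sdev^2),
                          scaled = isTRUE(use_correlation),
                          size = size),
                     class = "pca_model")
  orient_axes(model)
}

#' Deterministic orientation of principal axes
#'
#' The sign of each principal component is arbitrary in any
#' eigendecomposition. This convention makes it deterministic: each
#' component is flipped, if needed, so that its loading of largest absolute
#' value is positive (ties broken by the lowest variable index). Scores are
#' flipped consistently; eigenvalues and explained-variance fractions are
#' untouched. Applying the convention twice is a no-op.
#'
#' @param model A `pca_model`.
#' @return The model with sign-fixed `loadings` and `scores`.
#' @export
orient_axes <- function(model) {
  L <- model$loadings
  for (k in seq_len(ncol(L))) {
    j <- which.max(abs(L[, k]))  # which.max takes the first (lowest index) on ties
    if (L[j, k] < 0) {
      L[, k] <- -L[, k]
      model$scores[, k] <- -model$scores[, k]
    }
  }
  model$loadings <- L
  model
}

#' Project new specimens into a fitted morphospace
#'
#' Centers the rows with the model's mean vector and applies the loadings:
#' `(rows - mean) %*% loadings`. Projecting the training rows reproduces the
#' stored scores; projecting the mean vector itself gives all-zero scores.
#'
#' @param model A `pca_model`.
#' @param new_rows A `shape_matrix` from the same catalog/treatment, or a
#'   numeric matrix/vector with the model's variable names.
#' @return Scores matrix, rows aligned with `new_rows`.
#' @export
project <- function(model, new_rows) {
  x <- if (inherits(new_rows, "shape_matrix")) new_rows$values else new_rows
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  vars <- names(model$mean_vector)
  if (is.null(colnames(x)) || !setequal(colnames(x), vars)) {
    stop("variables of new rows do not match the fitted model")
  }
  x <- x[, vars, drop = FALSE]
  if (model$scaled) {
    stop("projection is only supported for covariance-PCA models")
  }
  sweep(x, 2, model$mean_vector) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(4, length(x$pct_variance))
  cat(sprintf("PCA of %s treatment: %d specimens, %d variables\n",
              x$treatment, nrow(x$scores), nrow(x$loadings)))
  cat("  % variance:",
      paste(sprintf("PC%d %.2f", seq_len(k), x$pct_variance[seq_len(k)]),
            collapse = ", "),
      if (length(x$pct_variance) > k) "..." else "", "\n")
  invisible(x)
}

#' Explained-variance summary of a fitted morphospace
#' @param object A `pca_model`.
#' @param ... Unused.
#' @return data.frame with `component`, `eigenvalue`, `pct_variance`,
#'   `cumulative_pct`.
#' @export
summary.pca_model <- function(object, ...) {
  data.frame(component = paste0("PC", seq_along(object$eigenvalues)),
             eigenvalue = object$eigenvalues,
             pct_variance = object$pct_variance,
             cumulative_pct = cumsum(object$pct_variance),
             row.names = NULL)
}
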