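#' Multivariate allometry test: PC1 scores regressed on log size
#'
#' The multivariate analogue of a bivariate allometry test in the Jolicoeur
#' tradition: the first principal component of the log-shape-ratio PCA
#' captures the dominant direction of shape variation, and its scores are
#' regressed by ordinary least squares on the log geometric mean. The slope
#' is tested against zero with the single-covariate ANOVA F-test on
#' (1, n-2) degrees of freedom — for one covariate the model ANOVA and the
#' slope test are the same test. R-squared (the squared Pearson correlation
#' of PC1 scores and log GM) is always computed and reported together with
#' the significance flag at level `alpha`; consumers that only want R² when
#' the test is significant can filter on the flag.
#'
#' R², the F statistic and the p-value are invariant to the base of the
#' logarithm used for size (the slope scales by `log(10)` under log10) and
#' to the arbitrary sign of PC1.
#'
#' @param scores_pc1 Numeric vector of PC1 scores, one per specimen.
#' @param size A [size_vector()] (or numeric vector of log-GM values)
#'   aligned with `scores_pc1`.
#' @param alpha Significance level for the slope ANOVA (default 0.05).
#' @param treatment Treatment the scores came from. The test is canonical
#'   for `"log_shape_ratio"`; other treatments are allowed but flagged
#'   non-canonical in the output.
#' @param structure Optional label of the anatomical structure, carried into
#'   reports.
#' @return An `allometry_fit`: list with `n`, `slope`, `intercept`,
#'   `r_squared`, `f_stat`, `df`, `p_value`, `alpha`, `significant`,
#'   `treatment`, `canonical`, `structure`.
#' @export
allometry_test <- function(scores_pc1, size, alpha = 0.05,
                           treatment = "log_shape_ratio",
                           structure = NULL) {
  log_gm <- if (inherits(size, "size_vector") || is.data.frame(size)) {
    size$log_gm
  } else {
    as.numeric(size)
  }
  n <- length(scores_pc1)
  if (length(log_gm) != n) stop("scores and size vector have different lengths")
  if (n < 3) stop("allometry test needs at least 3 specimens")
  if (stats::var(log_gm) == 0) stop("log size has zero variance")

  fit <- stats::lm(scores_pc1 ~ log_gm)
  sm <- suppressWarnings(summary(fit))  # warns on an essentially perfect fit
  r2 <- sm$r.squared
  if (r2 < 1) {
    f <- r2 / (1 - r2) * (n - 2)
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  } else {
    f <- Inf
    p <- 0
  }
  structure(list(n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 f_stat = f,
                 df = c(1, n - 2),
                 p_value = p,
                 alpha = alpha,
                 significant = p < alpha,
                 treatment = treatment,
                 canonical = identical(treatment, "log_shape_ratio"),
                 structure = structure),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Allometry test (PC1 ~ log GM%s): n = %d\n",
              if (!is.null(x$structure)) paste0(", ", x$structure) else "",
              x$n))
  cat(sprintf("  slope = %.4f, R² = %s, F(1, %d) = %.2f, p = %.4g (%s at alpha = %g)\n",
              x$slope, format_pct(x$r_squared), x$df[2], x$f_stat, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  if (!x$canonical) {
    cat("  note: non-canonical — scores are not from the log-shape-ratio treatment\n")
  }
  invisible(x)
}

# fraction in [0,1] -> "72.67%"
format_pct <- function(r2) sprintf("%.2f%%", 100 * r2)

#' Tabular and JSON summary of allometry fits across structures
#'
#' Collects one [allometry_test()] fit per anatomical structure into a
#' regression-summary table of the kind shown alongside morphospace
#' figures: structure, n, slope, R² rendered as a percentage with two
#' decimals, p-value and the significance verdict.
#'
#' @param fits A single `allometry_fit` or a list of them; names (or the
#'   fits' `structure` fields) label the rows.
#' @param json_path Optional path; when given the summary is also written as
#'   JSON (empty optional fields omitted).
#' @return data.frame with one row per fit.
#' @export
allometry_report <- function(fits, json_path = NULL) {
  if (inherits(fits, "allometry_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  labels <- names(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lab <- if (!is.null(labels) && nzchar(labels[i])) labels[i]
           else if (!is.null(f$structure)) f$structure
           else paste0("fit", i)
    data.frame(structure = lab, n = f$n, slope = f$slope,
               r_squared = f$r_squared,
               r_squared_pct = format_pct(f$r_squared),
               p_value = f$p_value, significant = f$significant,
               canonical = f$canonical, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(json_path)) {
    payload <- lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      rec <- list(structure = out$structure[i], n = f$n, slope = f$slope,
                  intercept = f$intercept, r_squared = f$r_squared,
                  r_squared_pct = out$r_squared_pct[i],
                  f_stat = f$f_stat, p_value = f$p_value,
                  alpha = f$alpha, significant = f$significant,
                  treatment = f$treatment, canonical = f$canonical)
      rec[!vapply(rec, is.null, logical(1))]
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  out
}
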