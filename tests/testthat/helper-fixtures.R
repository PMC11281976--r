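# fixtures are built in code; nothing is read from disk except what a test writes

toy_catalog <- function(kinds = c("linear", "linear"),
                        abbrev = paste0("V", seq_along(kinds))) {
  variable_catalog(data.frame(abbreviation = abbrev,
                              name = paste("variable", abbrev),
                              kind = kinds, stringsAsFactors = FALSE),
                   structure = "toy")
}

toy_table <- function(values, kinds = rep("linear", ncol(values)),
                      maturity = "mature") {
  values <- as.matrix(values)
  catalog <- toy_catalog(kinds)
  colnames(values) <- catalog$abbreviation
  meta <- data.frame(specimen_id = sprintf("S%02d", seq_len(nrow(values))),
                     maturity = maturity, stringsAsFactors = FALSE)
  measurement_table(values, meta, catalog)
}

# random positive table over a catalog; angles uniform well inside (0, 360)
random_table <- function(n, catalog = standard_catalog("cranium"), seed = 1) {
  set.seed(seed)
  vals <- matrix(NA_real_, n, nrow(catalog),
                 dimnames = list(NULL, catalog$abbreviation))
  for (j in seq_len(nrow(catalog))) {
    vals[, j] <- if (catalog$kind[j] == "linear") {
      exp(rnorm(n, mean = 4 + j / 3, sd = 0.3))
    } else {
      runif(n, 20, 340)
    }
  }
  meta <- data.frame(specimen_id = sprintf("R%03d", seq_len(n)),
                     maturity = "mature", stringsAsFactors = FALSE)
  measurement_table(vals, meta, catalog)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a complete 3-specimen cranial data.frame for IO tests
cranial_df <- function() {
  catalog <- standard_catalog("cranium")
  set.seed(42)
  vals <- matrix(round(exp(rnorm(3 * 9, 5, 0.2)), 2), 3, 9,
                 dimnames = list(NULL, catalog$abbreviation))
  cbind(data.frame(specimen_id = c("A", "B", "C"), breed = "test",
                   maturity = "mature", stringsAsFactors = FALSE),
        as.data.frame(vals))
}
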