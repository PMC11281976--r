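catalog9 <- standard_catalog("cranium")

test_that("a complete CSV reads into a table with no missing cells", {
  path <- write_toy_csv(cranial_df())
  tab <- read_measurements(path, catalog9)
  expect_s3_class(tab, "measurement_table")
  expect_equal(n_specimens(tab), 3)
  expect_equal(sum(is.na(tab$values)), 0)
  expect_equal(colnames(tab$values), catalog9$abbreviation)
})

test_that("blank, unparseable and out-of-range cells become missing with a warning", {
  df <- cranial_df()
  df$BL[2] <- NA           # blank cell
  path <- write_toy_csv(df)
  tab <- read_measurements(path, catalog9)
  expect_equal(sum(is.na(tab$values)), 1)
  expect_true(is.na(tab$values["B", "BL"]))

  df2 <- cranial_df()
  df2$PL[1] <- "n/a"       # unparseable
  df2$SW[3] <- -5          # non-positive length
  expect_warning(tab2 <- read_measurements(write_toy_csv(df2), catalog9),
                 "set to missing")
  expect_equal(sum(is.na(tab2$values)), 2)

  endo <- standard_catalog("brain_endocast")
  df3 <- data.frame(specimen_id = "X", t(setNames(runif(13, 10, 80),
                                                  endo$abbreviation)),
                    check.names = FALSE)
  df3$IHA <- 400           # angle out of (0, 360)
  expect_warning(tab3 <- read_measurements(write_toy_csv(df3), endo),
                 "set to missing")
  expect_true(is.na(tab3$values[1, "IHA"]))
})

test_that("a missing required column is a hard error naming the column", {
  df <- cranial_df()
  df$SW <- NULL
  expect_error(read_measurements(write_toy_csv(df), catalog9), "SW")
})

test_that("duplicate specimen ids are a hard error", {
  df <- cranial_df()
  df$specimen_id <- c("A", "A", "C")
  expect_error(read_measurements(write_toy_csv(df), catalog9),
               "duplicate specimen_id")
})

test_that("a column-mapping dialect resolves non-standard headers", {
  df <- cranial_df()
  names(df)[names(df) == "BL"] <- "basilar.length"
  path <- write_toy_csv(df)
  expect_error(read_measurements(path, catalog9), "BL")
  tab <- read_measurements(path, catalog9, dialect = c(BL = "basilar.length"))
  expect_equal(n_specimens(tab), 3)
})

test_that("write-read round trip preserves values bit-for-bit and missingness", {
  tab <- random_table(15, standard_catalog("brain_endocast"), seed = 7)
  tab$values[3, "MBW"] <- NA
  tab$values[9, "OFA"] <- NA
  tab <- measurement_table(tab$values, tab$meta, tab$catalog)
  path <- tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path, tab$catalog)
  expect_identical(back$values, tab$values)
  expect_identical(back$meta$specimen_id, tab$meta$specimen_id)
})

test_that("filter_complete applies listwise deletion and is idempotent", {
  tab <- random_table(5)
  tab$values[2, "PL"] <- NA
  tab <- measurement_table(tab$values, tab$meta, tab$catalog)
  kept <- filter_complete(tab)
  expect_equal(n_specimens(kept), 4)
  expect_equal(dropped_specimens(kept), "R002")
  # row order preserved
  expect_equal(kept$meta$specimen_id, tab$meta$specimen_id[-2])

  again <- filter_complete(kept)
  expect_identical(again$values, kept$values)
  expect_length(dropped_specimens(again), 0)

  tab$values[] <- NA
  all_missing <- structure(tab, class = "measurement_table")
  expect_error(filter_complete(all_missing), "no specimen")
})

test_that("filter_mature keeps confirmed-mature specimens and reports the rest", {
  tab <- random_table(6)
  tab$meta$maturity <- c("mature", "immature", "unknown",
                         "mature", "mature", "unknown")
  kept <- filter_mature(tab)
  expect_equal(n_specimens(kept), 3)
  expect_setequal(dropped_specimens(kept), c("R002", "R003", "R006"))

  # unknown maturity can be kept by explicit choice
  lenient <- filter_mature(tab, unknown = "keep")
  expect_equal(n_specimens(lenient), 5)

  all_mature <- random_table(4)
  expect_identical(filter_mature(all_mature)$values, all_mature$values)
})

test_that("merge_tables concatenates disjoint tables over one catalog", {
  a <- random_table(10, seed = 1)
  b <- random_table(6, seed = 2)
  b$meta$specimen_id <- sprintf("Q%03d", 1:6)
  b <- measurement_table(b$values, b$meta, b$catalog)
  m <- merge_tables(a, b)
  expect_equal(n_specimens(m), 16)
  expect_equal(m$meta$specimen_id, c(a$meta$specimen_id, b$meta$specimen_id))

  # id collision
  expect_error(merge_tables(a, a), "collision")

  # catalog mismatch
  other <- random_table(3, standard_catalog("bony_labyrinth"))
  expect_error(merge_tables(a, other), "different catalogs")

  # merge with an empty table is the identity
  empty <- filter_mature(a)  # make a structurally valid table, then empty it
  empty$values <- a$values[0, , drop = FALSE]
  empty$meta <- a$meta[0, ]
  m2 <- merge_tables(b, empty)
  expect_identical(m2$values, b$values)
})

test_that("assign_groups maps breeds to analysis groups with a default", {
  tab <- random_table(4)
  tab$meta$breed <- c("skyros", "hokkaido", "shire", "rhodes")
  out <- assign_groups(tab, c(skyros = "Aegean", rhodes = "Aegean",
                              hokkaido = "Japanese"))
  expect_equal(out$meta$group,
               c("Aegean", "Japanese", "Comparative", "Aegean"))
  expect_identical(assign_groups(tab, NULL)$meta$group, tab$meta$group)
})
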