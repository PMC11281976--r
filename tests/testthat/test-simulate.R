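test_that("simulation is deterministic given the seed", {
  cfg <- make_scenario("island_dwarf")
  a <- simulate_measurements(cfg)
  b <- simulate_measurements(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth$specimens, b$truth$specimens)
  c <- simulate_measurements(make_scenario("island_dwarf", seed = 999))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("noiseless isometry makes every linear shape column constant", {
  cfg <- make_scenario("isometric_null")
  cfg$sigma[] <- 0
  shp <- log_shape_ratios(simulate_measurements(cfg)$table)
  ranges <- apply(shp$values[, linear_variables(shp$catalog)], 2,
                  function(col) diff(range(col)))
  expect_lt(max(ranges), 1e-12)
})

test_that("canned scenarios encode their design", {
  iso <- make_scenario("isometric_null")
  expect_true(all(iso$beta == 1))

  dwarf <- make_scenario("island_dwarf")
  expect_gt(max(dwarf$beta), 1)
  expect_lt(min(dwarf$beta), 1)
  means <- setNames(vapply(dwarf$groups, `[[`, numeric(1), "size_log_mean"),
                    vapply(dwarf$groups, `[[`, character(1), "name"))
  expect_lt(means[["island"]], means[["comparative"]])

  two <- make_scenario("two_archipelago")
  expect_gte(length(two$groups), 3)
  expect_equal(anyDuplicated(vapply(two$groups, `[[`, numeric(1),
                                    "size_log_mean")), 0)

  expect_error(make_scenario("volcano"))
})

test_that("ground truth sidecar aligns with the table and stays out of it", {
  sim <- simulate_measurements(make_scenario("two_archipelago"))
  expect_identical(sim$truth$specimens$specimen_id,
                   sim$table$meta$specimen_id)
  expect_identical(sim$truth$specimens$group, sim$table$meta$group)
  expect_false("log_size" %in% colnames(sim$table$values))
  expect_true(all(sim$table$meta$maturity == "mature"))
})

test_that("angle variables are size-free and stay inside (0, 360)", {
  endo <- standard_catalog("brain_endocast")
  cfg <- sim_config(endo,
                    alpha = rep(1, 9), beta = rep(1.1, 9), sigma = rep(0.05, 9),
                    angle_mean = c(IHA = 115, HPA = 130, CSA = 100, OFA = 40),
                    angle_sd = c(IHA = 10, HPA = 10, CSA = 12, OFA = 15),
                    groups = group_spec("g", 200, 3, 0.5), seed = 7)
  sim <- simulate_measurements(cfg)
  ang <- sim$table$values[, angle_variables(endo)]
  expect_true(all(ang > 0 & ang < 360))
  # uncorrelated with latent size (weak check at n = 200)
  cors <- abs(cor(ang, sim$truth$specimens$log_size))
  expect_lt(max(cors), 0.25)
})

test_that("a noiseless allometric table is rank one in shape space", {
  cat3 <- toy_catalog(rep("linear", 3))
  cfg <- sim_config(cat3, alpha = c(1, 1, 1), beta = c(1.2, 1.0, 0.8),
                    sigma = c(0, 0, 0),
                    groups = group_spec("g", 40, 4, 0.3), seed = 5)
  sim <- simulate_measurements(cfg)
  model <- fit_pca(log_shape_ratios(sim$table))
  expect_equal(model$pct_variance[1], 100, tolerance = 1e-8)
  fit <- allometry_test(model$scores[, 1], model$size)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("low-noise island_dwarf recovers the exponent-spread direction", {
  cfg <- make_scenario("island_dwarf")
  cfg$sigma[] <- 0.01
  sim <- simulate_measurements(cfg)
  expect_gte(n_specimens(sim$table), 100)
  model <- fit_pca(log_shape_ratios(sim$table))
  beta_centered <- cfg$beta - mean(cfg$beta)
  load_cor <- cor(model$loadings[names(cfg$beta), 1], beta_centered)
  expect_gt(abs(load_cor), 0.99)
  fit <- allometry_test(model$scores[, 1], model$size)
  expect_gt(fit$r_squared, 0.9)
})

test_that("widening the exponent spread never weakens mean recovered allometry", {
  base_beta <- make_scenario("island_dwarf")$beta
  spread <- base_beta - mean(base_beta)
  scales <- c(0, 1 / 3, 2 / 3, 1)
  mean_r2 <- vapply(scales, function(sc) {
    r2 <- vapply(1:50, function(s) {
      cfg <- make_scenario("island_dwarf", seed = 5000 + s)
      cfg$beta <- 1 + sc * spread
      # smaller groups keep 200 fits quick without changing the design shape
      cfg$groups[[1]]$n <- 40L
      cfg$groups[[2]]$n <- 15L
      sim <- simulate_measurements(cfg)
      model <- fit_pca(log_shape_ratios(sim$table))
      allometry_test(model$scores[, 1], model$size)$r_squared
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  expect_true(all(diff(mean_r2) >= 0))
})

test_that("config validation catches dimension and sign errors", {
  cat3 <- toy_catalog(rep("linear", 3))
  expect_error(sim_config(cat3, alpha = c(1, 1), beta = c(1, 1, 1),
                          sigma = c(0, 0, 0),
                          groups = group_spec("g", 5, 1, 0.1)),
               "alpha")
  expect_error(sim_config(cat3, alpha = rep(1, 3), beta = rep(1, 3),
                          sigma = c(-0.1, 0, 0),
                          groups = group_spec("g", 5, 1, 0.1)),
               "sigma")
  expect_error(group_spec("g", 0, 1, 0.1))
})
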