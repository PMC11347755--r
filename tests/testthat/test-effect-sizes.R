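test_that("pearson_r enforces exclusions and winsorizes perfect fits", {
  expect_warning(r <- pearson_r(1:5, 1:5), "winsorized")
  expect_equal(r, 1 - 1e-6)
  expect_equal(suppressWarnings(pearson_r(1:4, c(2, 4, 6, 8))), 1 - 1e-6)
  expect_error(pearson_r(1:3, 3:1), "less than 4")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  # constructed orthogonal pair
  expect_equal(pearson_r(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
})

test_that("signed ordinal correlation follows the dominants-gain-more
           convention", {
  expect_equal(suppressWarnings(signed_ordinal_r(c(4, 3, 2, 1), 1:4)),
               1 - 1e-6)
  expect_equal(suppressWarnings(signed_ordinal_r(c(1, 2, 3, 4), 1:4)),
               -(1 - 1e-6))
  set.seed(1)
  b <- rnorm(6)
  expect_equal(signed_ordinal_r(b, 1:6), -signed_ordinal_r(-b, 1:6))
})

test_that("foreign statistics convert with the standard formulas", {
  expect_equal(r_from_chi_square(4, 100, 1), 0.2)
  expect_equal(r_from_chi_square(0, 50, 1), 0)
  expect_equal(r_from_chi_square(4, 100, -1), -0.2)
  expect_warning(capped <- r_from_chi_square(60, 50, 1), "capped")
  expect_lt(capped, 1)

  expect_equal(r_from_means_sd(5, 1, 10, 5, 1, 10), 0)
  # d = 2 with equal groups: r = 2 / sqrt(8)
  expect_equal(r_from_means_sd(2, 1, 10, 0, 1, 10), 2 / sqrt(8))
  expect_equal(r_from_means_sd(0, 1, 10, 2, 1, 10), -2 / sqrt(8))
  expect_error(r_from_means_sd(1, 0, 5, 2, 0, 5), "pooled")
})

test_that("fisher_z is the odd increasing atanh with variance 1/(n-3)", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  grid <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-grid), -fisher_z(grid))
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_equal(tanh(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_error(fisher_z(1), "winsorize")
  expect_equal(z_variance(28), 0.04)
  expect_error(z_variance(3), "exceed 3")
})

test_that("aggregation means on the r and steepness scales", {
  expect_equal(aggregate_measures(c(0.2, 0.4)), 0.3)
  expect_equal(aggregate_measures(0.7), 0.7)
  expect_equal(aggregate_steepness(c(0.5, 0.7, 0.9)), 0.7)
  expect_error(aggregate_measures(numeric(0)), "empty")
})

test_that("build_record packs moderators and rejects bad inputs", {
  mods <- list(benefit_category = "direct", duration_months = 24,
               setting = "wild", sex = "female",
               dispersal = "female_philopatry", social_org = "MMG",
               origin = "published", pub_year = 2015)
  rec <- build_record("g1", "sp1", r = c(0.1, 0.3), n = 30,
                      rank_basis = "cardinal", method = "NDS_Dij",
                      steepness = 0.6, moderators = mods)
  expect_equal(rec$r, 0.2)  # two feeding measures averaged
  expect_equal(rec$z_r, atanh(0.2))
  expect_equal(rec$v, 1 / 27)
  expect_error(build_record("g1", "sp1", 0.2, 3, "cardinal", "NDS_Dij",
                            0.6, mods), "less than 4")
  expect_error(build_record("g1", "sp1", 0.2, 30, "cardinal", "NDS_Dij",
                            0.6, mods[-3]), "missing moderator.*setting")
  bad <- mods; bad$setting <- "zoo"
  expect_error(build_record("g1", "sp1", 0.2, 30, "cardinal", "NDS_Dij",
                            0.6, bad), "invalid level")
  nopub <- mods; nopub$pub_year <- NULL
  expect_error(build_record("g1", "sp1", 0.2, 30, "cardinal", "NDS_Dij",
                            0.6, nopub), "pub_year")
})

test_that("benefit categories split direct from indirect types", {
  expect_equal(benefit_category(c("fecundity", "infant_survival",
                                  "mating_success", "feeding_success")),
               c("direct", "direct", "indirect", "indirect"))
  expect_error(benefit_category("longevity"))
})

test_that("observed Fisher Z is unbiased with variance about 1/(n-3)", {
  set.seed(21)
  rho <- 0.5
  n <- 30
  z <- replicate(1000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    atanh(cor(x, y))
  })
  se_mean <- sqrt(1 / (n - 3) / 1000)
  expect_lt(abs(mean(z) - atanh(rho)), 4 * se_mean + 0.01)
  expect_equal(var(z), 1 / (n - 3), tolerance = 0.15)
})

test_that("synthetic group records land near the generating correlation", {
  set.seed(31)
  ab <- seq(2, -2, length.out = 30)
  ben <- simulate_benefits(ab, true_r = 0.5)
  r <- pearson_r(ben$benefit_value, ab)
  expect_lt(abs(atanh(r) - atanh(0.5)), 3 * sqrt(1 / 27))
})
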