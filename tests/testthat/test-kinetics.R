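table1 <- function() {
  read_batch_timeseries(system.file("extdata", "table1_batch.csv",
                                    package = "phbflux", mustWork = TRUE))
}

test_that("OD conversion is the stated linear calibration", {
  expect_equal(od_to_biomass(1.0), 0.365)
  expect_equal(od_to_biomass(0), 0)
  expect_equal(od_to_biomass(2.0), 0.730)
  expect_error(od_to_biomass(-0.1), "non-negative")
})

test_that("growth-rate fit recovers an exact exponential to machine precision", {
  t <- seq(0, 10, by = 1)
  df <- batch_timeseries(data.frame(
    time = t, dry_weight = 0.05 * exp(0.30 * t),
    phb_content = 70, succinate = rev(seq(5, 25, length.out = length(t)))))
  g <- fit_growth_rate(df)
  expect_equal(g$mu, 0.30, tolerance = 1e-10)
  expect_lt(g$se, 1e-10)
})

test_that("constant biomass gives slope zero and a warning about fit quality", {
  df <- batch_timeseries(data.frame(
    time = 0:5, dry_weight = rep(0.2, 6), phb_content = 70,
    succinate = seq(25, 20, length.out = 6)))
  g <- suppressWarnings(fit_growth_rate(df, window = 1:6))
  expect_equal(g$mu, 0, tolerance = 1e-12)
})

test_that("growth-rate fit validates its window and inputs", {
  df <- batch_timeseries(data.frame(
    time = 0:3, dry_weight = c(0.1, 0.2, 0.4, 0.8), phb_content = 0,
    succinate = c(25, 24, 22, 18)))
  expect_error(fit_growth_rate(df, window = 1:2), "at least 3")
  df2 <- df; df2$dry_weight[2] <- 0
  expect_error(fit_growth_rate(df2, window = 1:4), "positive")
})

test_that("growth-rate slope is invariant to rescaling dry weight", {
  df <- batch_timeseries(data.frame(
    time = 0:6, dry_weight = 0.04 * exp(0.25 * (0:6)) * (1 + 0.02 * sin(0:6)),
    phb_content = 70, succinate = seq(25, 19, length.out = 7)))
  g1 <- fit_growth_rate(df, window = 1:7)
  df$dry_weight <- df$dry_weight * 1000
  g2 <- fit_growth_rate(df, window = 1:7)
  expect_equal(g2$mu, g1$mu, tolerance = 1e-12)
})

test_that("yield fit recovers an exact linear coupling", {
  t <- 0:6
  x <- 0.04 * exp(0.232 * t)
  s <- 25 - 1000 * (x - 0.04) / 50
  df <- batch_timeseries(data.frame(time = t, dry_weight = x,
                                    phb_content = 70, succinate = s))
  y <- fit_yield(df)
  expect_equal(y$yield_xs, 50, tolerance = 1e-8)
  # degenerate: no consumption
  df$succinate <- rep(25, 7)
  expect_error(fit_yield(df), "consumption")
})

test_that("specific uptake is 1000 mu over yield", {
  expect_equal(specific_uptake(0.232, 48.4), 4.79, tolerance = 1e-2)
  expect_equal(specific_uptake(0, 48.4), 0)
  expect_equal(specific_uptake(0.3, 50), 6.0)
  expect_error(specific_uptake(0.2, 0), "positive")
})

test_that("PHB production rate follows mu times content over monomer mass", {
  r <- phb_specific_rate(0.232, 70)
  expect_equal(r$mass_rate, 16.24, tolerance = 1e-3)
  expect_equal(r$molar_rate, 16.24 / 96, tolerance = 1e-3)
  expect_equal(phb_specific_rate(0, 70)$mass_rate, 0)
  expect_equal(phb_specific_rate(0.232, 0)$molar_rate, 0)
})

test_that("accumulation rate converts a content jump to molar units", {
  expect_equal(accumulation_rate(0, 78, 0.5), 1.625, tolerance = 1e-12)
  expect_equal(accumulation_rate(0, 78.4, 0.5), 1.6333, tolerance = 1e-4)
  expect_equal(accumulation_rate(50, 50, 1), 0)
  expect_error(accumulation_rate(0, 78, 0), "positive")
})

test_that("Pirt regression recovers the maintenance intercept", {
  mu <- c(0.05, 0.1, 0.2)
  qs <- mu / 50 * 1000 + 2.0
  p <- pirt_maintenance(mu, qs)
  expect_equal(p$m_s, 2.0, tolerance = 1e-10)
  qs0 <- mu / 50 * 1000
  expect_equal(pirt_maintenance(mu, qs0)$m_s, 0, tolerance = 1e-10)
  expect_error(pirt_maintenance(c(0.1, 0.2), c(1, 2)), "at least 3")
  # noisy: intercept within 3 se of truth
  set.seed(7)
  mu_n <- seq(0.02, 0.3, length.out = 20)
  qs_n <- mu_n / 45 * 1000 + 1.5 + rnorm(20, 0, 0.05)
  pn <- pirt_maintenance(mu_n, qs_n)
  expect_lt(abs(pn$m_s - 1.5), 3 * pn$se)
})

test_that("thiolase rate sensitivity is quadratic in acetyl-CoA", {
  expect_equal(thiolase_sensitivity(4), 16)
  expect_equal(thiolase_sensitivity(1), 1)
  expect_equal(thiolase_sensitivity(2), 4)
  expect_error(thiolase_sensitivity(0), "positive")
})

test_that("rate estimates satisfy the uptake and molar-mass identities", {
  ts <- table1()
  for (w in list("auto", 3:9)) {
    r <- suppressWarnings(estimate_rates(ts, window = w))
    expect_equal(r$q_s, 1000 * r$mu / r$yield_xs, tolerance = 1e-12)
    expect_equal(r$q_phb_molar, r$q_phb_mass / 96, tolerance = 1e-12)
  }
})

test_that("the timeseries reader enforces schema and units", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time_h,dry_weight_g_per_L,phb_mg_per_g",
               "0,0.04,0", "1,0.05,70"), path)
  expect_error(read_batch_timeseries(path), "succinate_mM")
  ts <- table1()
  expect_s3_class(ts, "phb_timeseries")
  expect_identical(nrow(ts), 9L)
  expect_identical(ts$dry_weight[1], 0.04)
  expect_identical(ts$succinate[9], 0.9)
  expect_true("dry_weight_sd" %in% names(ts))
})

test_that("time series validation rejects disorder and negatives", {
  expect_error(batch_timeseries(data.frame(
    time = c(0, 2, 1), dry_weight = 1, phb_content = 0, succinate = 25)),
    "increasing")
  expect_error(batch_timeseries(data.frame(
    time = 0:2, dry_weight = c(1, -1, 1), phb_content = 0, succinate = 25)),
    "non-negative")
})
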