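# Generative model of per-cell fluorescence: calibration, simulation,
# moment structure.

test_that("calibration inverts D and S in closed form", {
  expect_equal(calibrate_from_ds(100, 10, 1, 1),
               list(spur_mean = 0, spur_sd = 0))
  cal <- calibrate_from_ds(100, 10, 2.13, 2.15)
  expect_equal(cal$spur_mean, 113)
  expect_equal(cal$spur_sd, 10 * sqrt(2.15^2 - 1), tolerance = 1e-12)
  expect_equal(cal$spur_sd, 19.0329, tolerance = 1e-4)
})

test_that("sub-unity targets clamp to the ideal reporter with a warning", {
  expect_warning(cal <- calibrate_from_ds(100, 10, 1.07, 0.97),
                 "clamped")
  expect_equal(cal$spur_mean, 7)
  expect_equal(cal$spur_sd, 0)
  expect_warning(cal2 <- calibrate_from_ds(100, 10, 0.9, 1.2), "clamped")
  expect_equal(cal2$spur_mean, 0)
  expect_true(cal2$spur_sd > 0)
})

test_that("calibration rejects nonpositive AF parameters", {
  expect_error(calibrate_from_ds(0, 10, 2, 2), "af_mean")
  expect_error(calibrate_from_ds(100, -1, 2, 2), "af_sd")
  expect_error(calibrate_from_ds(100, 10, 0, 2), "d_target")
})

test_that("forward simulation reproduces calibrated D and S", {
  cal <- calibrate_from_ds(100, 10, 2.13, 2.15)
  ev <- scenario("ev", af_mean = 100, af_sd = 10,
                 spur_mean = cal$spur_mean, spur_sd = cal$spur_sd)
  af <- scenario("af", af_mean = 100, af_sd = 10)
  ds <- compute_ds(population_distribution(ev, 2e5, seed = 1),
                   population_distribution(af, 2e5, seed = 2),
                   n_boot = 400, seed = 3)
  expect_lt(abs(ds$D - 2.13), 3 * ds$d_se)
  expect_lt(abs(ds$S - 2.15), 3 * ds$s_se)
})

test_that("simulation is reproducible and honours edge cases", {
  sc <- scenario("ev", spur_mean = 50, spur_sd = 20)
  p1 <- simulate_population(sc, 100, seed = 42)
  p2 <- simulate_population(sc, 100, seed = 42)
  expect_identical(p1$total_values, p2$total_values)
  p0 <- simulate_population(sc, 0, seed = 1)
  expect_equal(p0$n, 0)
  expect_length(p0$total_values, 0)
  expect_length(p0$af_values, 0)
})

test_that("closed spurious pathway leaves only autofluorescence", {
  sc <- scenario("star", spur_mean = 113, spur_sd = 19, readthrough = 0)
  pop <- simulate_population(sc, 1e5, seed = 7)
  expect_lt(abs(mean(pop$total_values) - 100) / 100, 0.01)
})

test_that("components add in mean and variance without interference", {
  sc <- scenario("full", af_mean = 100, af_sd = 25,
                 spur_mean = 60, spur_sd = 30, readthrough = 0.7,
                 prom_mean = 40, prom_sd = 15)
  pop <- simulate_population(sc, 1e6, seed = 11)
  mu_true <- 100 + 0.7 * 60 + 40
  var_true <- 25^2 + 0.7^2 * 30^2 + 15^2
  n <- pop$n
  # 3-SE bounds from the usual large-sample formulas
  se_mu <- sqrt(var_true / n)
  kurt_margin <- 3 * sqrt(3 * var_true^2 / n)  # conservative Var(s^2) bound
  expect_lt(abs(mean(pop$total_values) - mu_true), 3 * se_mu)
  expect_lt(abs(stats::var(pop$total_values) - var_true), kurt_margin)
  # invariant: total = af + rho * spur + prom (no interference realized)
  expect_equal(pop$total_values,
               pop$af_values + 0.7 * pop$spur_values + pop$prom_values,
               tolerance = 1e-12)
})

test_that("D and S are invariant under rescaling of the AU baseline", {
  mk <- function(c_) {
    ev <- scenario("ev", af_mean = 100 * c_, af_sd = 25 * c_,
                   spur_mean = 113 * c_, spur_sd = 47.6 * c_)
    af <- scenario("af", af_mean = 100 * c_, af_sd = 25 * c_)
    ds <- compute_ds(population_distribution(ev, 5e4, seed = 5),
                     population_distribution(af, 5e4, seed = 6),
                     n_boot = 200, seed = 7)
    c(ds$D, ds$S)
  }
  expect_equal(mk(1), mk(7.3), tolerance = 0.02)
})

test_that("interference suppresses the fusion mean below the EV mean", {
  ev <- scenario("ev", spur_mean = 113, spur_sd = 47.6)
  fusion <- scenario("fusion", spur_mean = 113, spur_sd = 47.6,
                     prom_mean = 10, prom_sd = 5,
                     gamma_s = 0.5, gamma_p = 0.5,
                     interference_extra_cv = 0.3)
  pe <- simulate_population(ev, 5e4, seed = 1)
  pf <- simulate_population(fusion, 5e4, seed = 2)
  expect_lt(mean(pf$total_values), mean(pe$total_values))
})

test_that("scenario validation enforces the parameter domains", {
  expect_error(scenario("x", readthrough = 1.2), "readthrough")
  expect_error(scenario("x", af_mean = -1), "af_mean")
  expect_error(scenario("x", gamma_s = -0.1), "gamma_s")
  expect_error(scenario(""), "name")
})

test_that("populations export to a tidy per-cell table", {
  sc <- scenario("ev", spur_mean = 50, spur_sd = 20, prom_mean = 5,
                 prom_sd = 2)
  pop <- simulate_population(sc, 25, seed = 3, replicate_id = "rep2")
  df <- as.data.frame(pop)
  expect_equal(nrow(df), 25)
  expect_named(df, c("cell_id", "replicate_id", "scenario", "od600",
                     "af", "spur", "prom", "total"))
  expect_equal(df$total, pop$total_values)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, path)
  back <- read.csv(path)
  expect_equal(back$total, pop$total_values, tolerance = 1e-9)
})
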