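# Interference detection and dark-noise deconvolution.

test_that("interference verdicts follow the CI invariant", {
  cat_ <- builtin_scenarios()
  d <- function(nm, n, s) population_distribution(cat_[[nm]], n, s)
  ir <- detect_interference(d("PrapE_amy@OD6", 3000, 1),
                            d("pGFPamy@OD6", 3000, 2), seed = 3)
  expect_equal(ir$verdict, "INTERFERENCE")
  expect_lt(ir$delta_mu_ci[2], 0)
  ir2 <- detect_interference(d("PrapE_Star@OD6", 3000, 4),
                             d("pGFP_Star@OD6", 3000, 5), seed = 6)
  expect_equal(ir2$verdict, "ACTIVE_PROMOTER")
  expect_gt(ir2$delta_mu_ci[1], 0)
  ir3 <- detect_interference(d("PrapE_Star@OD2.5", 3000, 7),
                             d("pGFP_Star@OD2.5", 3000, 8), seed = 9)
  expect_equal(ir3$verdict, "INDISTINGUISHABLE")
})

test_that("promoter-off comparisons control the false-positive rate", {
  sc <- builtin_scenario("pGFP_Star@OD2.5")
  seeds <- matrix(derive_seeds(555, 3 * 80), ncol = 3)
  verdicts <- vapply(seq_len(80), function(r) {
    detect_interference(population_distribution(sc, 800, seeds[r, 1]),
                        population_distribution(sc, 800, seeds[r, 2]),
                        n_boot = 400, seed = seeds[r, 3])$verdict
  }, character(1))
  rate <- mean(verdicts != "INDISTINGUISHABLE")
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 80))
})

test_that("moment deconvolution recovers a known additive signal", {
  set.seed(10)
  ev_pop <- rgamma(2e4, 16, scale = 6.25) + rgamma(2e4, 35.2, scale = 3.2)
  sig <- rgamma(2e4, 6.25, scale = 8)  # mean 50, sd 20
  fusion <- dist_of(rgamma(2e4, 16, scale = 6.25) +
                      rgamma(2e4, 35.2, scale = 3.2) + sig, "fusion")
  ev <- dist_of(ev_pop, "ev")
  res <- deconvolve_moments(fusion, ev)
  expect_true(res$valid)
  n <- 2e4
  se_mean <- sqrt(stats::var(fusion$values) / n + stats::var(ev$values) / n)
  expect_lt(abs(res$signal_mean - mean(sig)), 3 * se_mean)
  expect_equal(sqrt(res$signal_var), 20, tolerance = 0.1)
})

test_that("a constant shift deconvolves to a delta signal", {
  set.seed(11)
  v <- rgamma(5000, 16, scale = 6.25)
  ev <- dist_of(v, "ev")
  fusion <- dist_of(v + 35, "fusion")
  res <- deconvolve_moments(fusion, ev)
  expect_equal(res$signal_mean, 35)
  expect_equal(res$signal_var, 0, tolerance = 1e-9)
})

test_that("interference flags the moment deconvolution invalid", {
  set.seed(12)
  ev <- dist_of(rgamma(5000, 20, scale = 10), "ev")
  fusion <- dist_of(rgamma(5000, 20, scale = 8), "fusion")  # lower mean
  expect_warning(res <- deconvolve_moments(fusion, ev), "interference")
  expect_false(res$valid)
  expect_lt(res$signal_mean, 0)
})

test_that("density deconvolution of identical samples concentrates at zero", {
  set.seed(13)
  v <- rnorm(5000, 100, 0.5)
  d <- dist_of(v)
  res <- deconvolve_density(d, d, grid_spec = list(lo = -10, hi = 10, n = 21),
                            reg = 1e-8)
  h <- res$diagnostics$grid_step
  mass_near_0 <- sum(res$density_values[abs(res$density_grid) <= h + 1e-9]) * h
  expect_gte(mass_near_0, 0.9)
})

test_that("density deconvolution recovers a known gamma signal", {
  set.seed(14)
  n <- 3e4
  noise <- function() rgamma(n, 16, scale = 6.25) + rgamma(n, 35.2, scale = 3.2)
  sig <- rgamma(n, 6.25, scale = 8)  # mean 50, sd 20
  fusion <- dist_of(noise() + sig, "fusion")
  ev <- dist_of(noise(), "ev")
  res <- deconvolve_density(fusion, ev)
  expect_lt(abs(res$signal_mean - 50) / 50, 0.05)
  expect_equal(sum(diff(res$density_grid) *
                     (res$density_values[-1] +
                        res$density_values[-length(res$density_values)]) / 2),
               1, tolerance = 1e-6)
  # moment consistency on additive data
  mom <- deconvolve_moments(fusion, ev)
  expect_lt(abs(res$signal_mean - mom$signal_mean),
            2 * res$diagnostics$grid_step)
})

test_that("deconvolution input contracts are enforced", {
  set.seed(15)
  d <- dist_of(rnorm(500, 10))
  small <- dist_of(rnorm(50, 10))
  expect_error(deconvolve_density(d, d, reg = 0), "reg")
  expect_error(deconvolve_density(small, d), "at least 100")
  expect_error(deconvolve_moments(dist_of(1), d), "at least 2")
})
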