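# D/S statistics, replicate aggregation, histogram export.

test_that("identical distributions give D = 1 and S = 1 exactly", {
  set.seed(1)
  v <- rgamma(500, 16, scale = 6.25)
  ds <- compute_ds(dist_of(v, "EV"), dist_of(v, "AF"), n_boot = 100, seed = 1)
  expect_identical(ds$D, 1)
  expect_identical(ds$S, 1)
})

test_that("D and S are the ratio of means and of standard deviations", {
  af <- dist_of(c(90, 100, 110), "AF")
  ev <- dist_of(c(180, 200, 220), "EV")
  ds <- compute_ds(ev, af, n_boot = 100, seed = 2)
  expect_equal(ds$D, 2)
  expect_equal(ds$S, 2)
  expect_true(ds$d_ci[1] <= ds$D && ds$D <= ds$d_ci[2])
  expect_true(ds$s_ci[1] <= ds$S && ds$S <= ds$s_ci[2])
})

test_that("degenerate references are rejected", {
  expect_error(compute_ds(dist_of(c(1, 2)), dist_of(c(0, 0))), "degenerate")
  expect_error(compute_ds(dist_of(c(1, 2)), dist_of(c(-5, -7))), "degenerate")
  expect_error(compute_ds(dist_of(1), dist_of(c(1, 2))), "at least 2")
})

test_that("bootstrap CIs are seeded and reproducible", {
  set.seed(3)
  ev <- dist_of(rgamma(300, 10, scale = 20))
  af <- dist_of(rgamma(300, 16, scale = 6.25))
  a <- compute_ds(ev, af, n_boot = 300, seed = 7)
  b <- compute_ds(ev, af, n_boot = 300, seed = 7)
  expect_identical(a$d_ci, b$d_ci)
  expect_identical(a$s_ci, b$s_ci)
})

test_that("bootstrap CI covers the true D at nominal-ish rate", {
  ev_sc <- scenario("ev", spur_mean = 113, spur_sd = 47.6)
  af_sc <- scenario("af")
  d_true <- 2.13
  seeds <- derive_seeds(1234, 3 * 150)
  covered <- vapply(seq_len(150), function(r) {
    ds <- compute_ds(
      population_distribution(ev_sc, 1500, seeds[3 * r - 2]),
      population_distribution(af_sc, 1500, seeds[3 * r - 1]),
      n_boot = 400, seed = seeds[3 * r])
    ds$d_ci[1] <= d_true && d_true <= ds$d_ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("an ideal reporter is statistically indistinguishable from 1", {
  star <- builtin_scenario("pGFP_Star@OD5")
  ds <- benchmark_population(star, n = 5000, seed = 99, n_boot = 1000)
  expect_true(ds$d_ci[1] <= 1 && 1 <= ds$d_ci[2])
  expect_true(ds$s_ci[1] <= 1 && 1 <= ds$s_ci[2])
})

test_that("asymptotic D increases with the spurious mean", {
  ds_at <- function(sm) {
    ev <- scenario("ev", spur_mean = sm, spur_sd = 20)
    benchmark_population(ev, n = 2e5, seed = 17, n_boot = 50)$D
  }
  d <- vapply(c(20, 60, 120), ds_at, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("replicate aggregation computes mean and SEM", {
  mk <- function(d, s) {
    structure(list(D = d, S = s, n_ev = 10L, n_af = 10L,
                   d_ci = c(d, d), s_ci = c(s, s), d_se = 0, s_se = 0,
                   conf = 0.95, n_boot = 0L,
                   ev_condition = "EV", af_condition = "AF"),
              class = "ds_benchmark")
  }
  agg <- aggregate_replicates(lapply(c(2.0, 2.1, 2.2, 2.3), mk, s = 1))
  expect_equal(agg$mean_D, 2.15)
  expect_equal(agg$sem_D, 0.06455, tolerance = 1e-4)
  single <- aggregate_replicates(list(mk(2, 2)))
  expect_true(is.na(single$sem_D))
  same <- aggregate_replicates(lapply(c(2, 2, 2), mk, s = 2))
  expect_equal(same$sem_D, 0)
  expect_error(aggregate_replicates(list()), "empty")
})

test_that("histogram export uses half-open bins that conserve mass", {
  d <- dist_of(c(1, 1, 2))
  h <- export_histogram(d, bin_width = 1, origin = 1)
  expect_equal(h$count, c(2, 1))
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$bin_left, c(1, 2))
  # bin-midpoint mean is within half a bin of the true mean
  set.seed(4)
  d2 <- dist_of(rgamma(2000, 9, scale = 30))
  for (w in c(5, 20)) {
    h2 <- export_histogram(d2, bin_width = w)
    expect_equal(sum(h2$count), d2$n)
    mids <- (h2$bin_left + h2$bin_right) / 2
    expect_lt(abs(sum(mids * h2$frequency) - d2$mu), w / 2)
  }
  expect_error(export_histogram(d, bin_width = -1), "bin_width")
})

test_that("benchmark reports label their uncertainty type", {
  set.seed(5)
  ev <- dist_of(rgamma(400, 10, scale = 20), "EV")
  af <- dist_of(rgamma(400, 16, scale = 6.25), "AF")
  one <- compute_ds(ev, af, n_boot = 200, seed = 1)
  two <- compute_ds(ev, af, n_boot = 200, seed = 2)
  rep_df <- benchmark_report(list(
    list(vector = "pX", channel = "GFP", od600 = 5, results = list(one)),
    list(vector = "pY", channel = "GFP", od600 = 5,
         results = list(one, two))))
  expect_equal(rep_df$unc_type, c("bootstrap_ci_halfwidth", "sem"))
  expect_equal(rep_df$k_replicates, c(1L, 2L))
})
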