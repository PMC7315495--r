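test_that("a one-replicate scenario reproduces the public estimators", {
  d <- study_design(timing = 0.75, n_new = 550)
  eff <- study_effects()
  tr <- trend_spec("step", 0.08)
  s <- run_scenario(d, eff, tr, n_reps = 1, seed = 42)
  set.seed(42)
  td <- simulate_trial(d, eff, tr)
  expect_equal(s$mean_est[s$method == "WLS_all"],
               unname(wls_stagewise(td, d, "all")$delta_hat))
  expect_equal(s$mean_est[s$method == "WLS_s2"],
               unname(wls_stagewise(td, d, "s2")$delta_hat))
  expect_equal(s$mean_est[s$method == "Ma1"],
               unname(regression_fit(td, d, "Ma1")$delta_hat))
  expect_equal(s$mean_est[s$method == "Mb1"],
               unname(regression_fit(td, d, "Mb1")$delta_hat))
  expect_equal(s$mean_est[s$method == "Z_concurrent"],
               unname(z_test(td, d, 2, "concurrent")$delta_hat))
  expect_equal(s$mean_est[s$method == "Z_all" & s$arm == 1],
               unname(z_test(td, d, 1, "all")$delta_hat))
})

test_that("scenario summaries are reproducible and respect the rMSE identity", {
  d <- small_design(n0 = 40, n_new = 20)
  eff <- study_effects()
  s1 <- run_scenario(d, eff, n_reps = 200, seed = 9)
  s2 <- run_scenario(d, eff, n_reps = 200, seed = 9)
  expect_identical(s1, s2)
  expect_equal(s1$rmse^2, s1$bias^2 + s1$sd_est^2, tolerance = 1e-12)
  expect_true(all(s1$reject_rate >= 0 & s1$reject_rate <= 1))
  expect_true(all(s1$rmse >= abs(s1$bias)))
  # the caller's RNG stream is untouched by a seeded scenario run
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(run_scenario(d, eff, n_reps = 5, seed = 77))
  expect_identical(rnorm(1), before)
})

test_that("per-scenario seeds are order- and subset-independent", {
  g <- scenario_grid(timings = c(0.25, 0.75), n_new_options = c(n0 = 550))
  tr <- data.frame(family = "step", lambda = 0.04)
  full <- run_study(grid = g, trends = tr, n_reps = 50, seed = 5,
                    methods = "WLS_all")
  part <- run_study(grid = g[2, ], trends = tr, n_reps = 50, seed = 5,
                    methods = "WLS_all")
  expect_equal(part$bias,
               full$bias[full$timing == 0.75], tolerance = 1e-14)
})

test_that("null rejection rates are nominal for every analysis approach", {
  d <- study_design(timing = 0.5, n_new = 275)
  s <- run_scenario(d, effect_spec(0, c(0, 0)), trend_spec("none"),
                    n_reps = 4000, seed = 31)
  se <- sqrt(0.05 * 0.95 / 4000)
  for (i in seq_len(nrow(s)))
    expect_lt(abs(s$reject_rate[i] - 0.05), 3 * se)
})

test_that("step-trend biases match their analytic expectations", {
  # WLS_all: E[bias of delta2_hat] = c * lambda * timing with c the GLS
  # weight of the added-arm contrast; WLS_s2/Ma2/Mb2 stay unbiased
  d <- study_design(timing = 0.75, n_new = 550)
  eff <- study_effects()
  lam <- 0.08
  s <- run_scenario(d, eff, trend_spec("step", lam), n_reps = 2000,
                    seed = 13, methods = c("WLS_all", "WLS_s2", "Ma2", "Mb2"))
  st <- ncctrial:::wls_structure(d, "all")
  Si <- solve(st$Sigma)
  P <- solve(crossprod(st$D, Si %*% st$D)) %*% crossprod(st$D, Si)
  expected <- P[2, 3] * lam * d$timing
  got <- s[s$method == "WLS_all" & s$arm == 2, ]
  expect_lt(abs(got$bias - expected), 3 * got$mc_se_bias)
  for (m in c("WLS_s2", "Ma2", "Mb2")) {
    row <- s[s$method == m & s$arm == 2, ]
    expect_lt(abs(row$bias), 3 * row$mc_se_bias)
  }
})

test_that("initial-arm inference is unaffected by a trend", {
  d <- study_design(timing = 0.5, n_new = 550)
  eff <- study_effects()
  for (tr in list(trend_spec("linear", 0.08), trend_spec("step", 0.08))) {
    s <- run_scenario(d, eff, tr, n_reps = 2500, seed = 17,
                      methods = c("WLS_all", "Ma1"))
    h1 <- s[s$arm == 1, ]
    expect_lt(max(abs(h1$bias)), 3 * max(h1$mc_se_bias))
    p80 <- ztest_power(0.15, 1, 550, 550)
    expect_lt(max(abs(h1$reject_rate - p80)),
              3 * sqrt(p80 * (1 - p80) / 2500))
  }
})

test_that("a negative trend deflates the added-arm error rate", {
  d <- study_design(timing = 0.75, n_new = 550)
  null_eff <- effect_spec(0, c(0, 0))
  s <- run_scenario(d, null_eff, trend_spec("step", -0.08), n_reps = 2000,
                    seed = 23, methods = "WLS_all")
  row <- s[s$arm == 2, ]
  expect_lt(row$reject_rate + 3 * row$mc_se_reject, 0.05)
})

test_that("table-1 style summaries apply the zero-reporting convention", {
  # zero_tol widened to the Monte-Carlo noise floor of this small run
  t1 <- reproduce_table1(n_reps = 300, seed = 3, trends = "step",
                         lambdas = 0.08, methods = c("WLS_all", "WLS_s2"),
                         zero_tol = 0.015)
  expect_identical(names(t1), c("trend", "lambda", "method", "max_abs_bias",
                                "median_abs_bias"))
  expect_equal(nrow(t1), 2L)
  # concurrent-only GLS is unbiased: its cell collapses to exactly zero
  expect_equal(t1$max_abs_bias[t1$method == "WLS_s2"], 0)
  # the all-control bias at this trend size is far above the threshold
  expect_gt(t1$max_abs_bias[t1$method == "WLS_all"], 0.04)
  detail <- attr(t1, "detail")
  expect_equal(nrow(detail[detail$method == "WLS_all" & detail$arm == 2, ]),
               9L)
})

test_that("surface and rMSE reproductions expose the documented orderings", {
  g <- scenario_grid(timings = 0.5, n_new_options = c(n0 = 550))
  surf <- reproduce_power_and_error_surfaces(
    n_reps = 800, seed = 11, trends = c("none", "step"), lambdas = 0.08,
    regimes = "null", methods = c("WLS_all", "WLS_s2"), grid = g)
  base <- surf[surf$trend == "none", ]
  stepped <- surf[surf$trend == "step", ]
  # a positive step inflates the all-control type-I error, not WLS_s2
  t1_all <- stepped$reject_rate[stepped$method == "WLS_all" &
                                  stepped$arm == 2]
  expect_gt(t1_all, 0.05 + 3 * sqrt(0.05 * 0.95 / 800))
  t1_s2 <- stepped$reject_rate[stepped$method == "WLS_s2" &
                                 stepped$arm == 2]
  expect_lt(abs(t1_s2 - 0.05), 3 * sqrt(0.05 * 0.95 / 800))

  rm <- reproduce_rmse_tables(n_reps = 800, seed = 11, trends = "step",
                              lambdas = 0.08,
                              methods = c("WLS_all", "Ma1", "Mb2"),
                              grid = g)
  # Mb2 discards the most data: largest rMSE; step trend pushes the
  # all-control rMSE above Ma1's at this lambda
  expect_gt(rm$rmse[rm$method == "Mb2"], rm$rmse[rm$method == "Ma1"])
  expect_gt(rm$rmse[rm$method == "WLS_all"], rm$rmse[rm$method == "Ma1"])
})

test_that("halving the Monte-Carlo error needs four times the replicates", {
  d <- small_design(n0 = 60, n_new = 30)
  eff <- study_effects()
  s1 <- run_scenario(d, eff, n_reps = 400, seed = 19, methods = "Z_all")
  s4 <- run_scenario(d, eff, n_reps = 1600, seed = 29, methods = "Z_all")
  ratio <- s1$mc_se_bias[1] / s4$mc_se_bias[1]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("run manifests serialise the seed and grid", {
  f <- tempfile(fileext = ".json")
  write_run_manifest(f, seed = 99, grid = scenario_grid(timings = 0.5))
  got <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(got$seed, 99)
  expect_equal(nrow(got$grid), 3L)
  expect_equal(got$package, "ncctrial")
  unlink(f)
})
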