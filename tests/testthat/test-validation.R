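# Agreement statistics and the virtual experiments.

test_that("Kendall tau handles perfect concordance, reversal and ties", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1)
  expect_equal(kendall_tau(1:5, 5:1)$tau, -1)
  expect_error(kendall_tau(rep(1, 5), 1:5), class = "tremorcv_error_degenerate")
  expect_error(kendall_tau(1:3, 1:4), class = "tremorcv_error_input")
  expect_error(kendall_tau(c(1, NA, 3), c(1, 2, 3)),
               class = "tremorcv_error_input")
})

test_that("Kendall tau matches the O(n^2) pair-count oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(3:50, 1L)
    x <- sample(1:8, n, replace = TRUE)   # integer draws force ties
    y <- x + sample(-3:3, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(kendall_tau(x, y)$tau, oracle_kendall_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- stats::rlnorm(20, 2, 1)
  y <- x * exp(stats::rnorm(20, 0, 0.5))
  expect_equal(kendall_tau(x, y)$tau, kendall_tau(log(x), y)$tau)
  expect_equal(kendall_tau(x, y)$tau, kendall_tau(x, sqrt(y))$tau)
})

test_that("amplitude error metrics compute absolute, relative and log errors", {
  m <- amplitude_error_metrics(c(10, 20, 30), c(10, 20, 30))
  expect_equal(m$median_abs_error, 0)
  expect_equal(m$median_rel_error_pct, 0)

  m2 <- amplitude_error_metrics(2 * c(5, 10, 50), c(5, 10, 50))
  expect_equal(m2$median_rel_error_pct, 100)
  expect_equal(m2$table$log_truth, log(c(5, 10, 50)))

  m3 <- amplitude_error_metrics(c(NA, 12, 9), c(10, 10, 10))
  expect_equal(m3$n, 2L)
  expect_equal(m3$n_missing, 1L)
  expect_error(amplitude_error_metrics(c(1, 2), c(0, 1)),
               class = "tremorcv_error_input")
})

test_that("systematic-error test flags amplitude-dependent errors", {
  set.seed(8)
  truth <- stats::rlnorm(20, 2, 1)
  prop <- systematic_error_test(truth, 0.1 * truth)
  expect_equal(prop$tau, 1)
  expect_true(prop$significant)

  indep <- systematic_error_test(truth, stats::rlnorm(20, 0, 0.3))
  expect_lt(abs(indep$tau), 0.35)
  expect_false(indep$significant)

  expect_error(systematic_error_test(truth, rep(2, 20)),
               class = "tremorcv_error_degenerate")
})

test_that("group comparison screens normality and reports the test used", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 3.3, 2.8, 4.0)
  same <- group_compare(list(a = x, b = x))
  expect_equal(same$p_value, 1)

  set.seed(21)
  base <- stats::rnorm(20)
  shifted <- base + 10 * stats::sd(base)
  res <- group_compare(list(a = shifted, b = base))
  expect_lt(res$p_value, 0.01)
  expect_true(res$method %in% c("paired t-test", "Wilcoxon signed-rank"))

  expect_error(group_compare(list(a = 1:2, b = 1:2)),
               class = "tremorcv_error_too_few_subjects")
  expect_error(group_compare(list(a = 1:5, b = 1:4)),
               class = "tremorcv_error_unequal_pairing")
  three <- group_compare(list(a = base, b = shifted, c = base + 1))
  expect_true(three$method %in% c("one-way ANOVA", "Kruskal-Wallis"))
})

test_that("angle sweep reproduces the accuracy/amplitude trade-off", {
  res <- run_angle_sweep(sim_config(duration = 10),
                         noise_model(seed = 4L), grid_step = 45)
  expect_s3_class(res, "angle_sweep_result")
  expect_equal(nrow(res), 5L * 3L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))

  top <- res$accuracy[res$elevation == -90]
  frontal <- res$accuracy[res$elevation == 0]
  expect_gt(mean(top), mean(frontal))
  # frontal views: too many dropouts, amplitude not estimable
  expect_true(all(is.na(res$median_amplitude[res$elevation == 0])))

  ok <- is.finite(res$median_amplitude)
  expect_gte(sum(ok), 3L)
  expect_lt(kendall_tau(res$accuracy[ok], res$median_amplitude[ok])$tau, 0)
})

test_that("flat confidence model yields a flat accuracy map", {
  res <- run_angle_sweep(sim_config(duration = 5),
                         noise_model(confidence_view_exponent = 0,
                                     confidence_noise_sd = 0, seed = 1L),
                         grid_step = 90)
  expect_equal(stats::sd(res$accuracy), 0)
})

test_that("ramp experiment tracks the envelope, x/y better than with depth", {
  res <- run_ramp_experiment(noise = noise_model(seed = 2L))
  tab <- res$table
  tau <- stats::setNames(tab$tau, tab$variant)
  expect_gt(tau[["OMC_XYZ"]], 0.95)
  expect_gte(tau[["MP_NORM_XY"]], tau[["MP_NORM_XYZ"]])
  expect_gte(tau[["MP_WORLD_XY"]], tau[["MP_WORLD_XYZ"]])
  expect_gt(tau[["MP_NORM_XY"]], 0.7)

  z <- res$sequences$MP_NORM_XY$z_amplitude
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("per-swing amplitudes follow a ramping envelope (normalized input)", {
  scene <- synthesize_scene(sim_config(amplitude_start = 0, amplitude_end = 20),
                            noise = noise_model(seed = 6L))
  sw <- estimate_amplitude(scene$mp_norm, "MP_NORM_XY")
  env <- stats::approx(scene$world$timestamps, 2 * scene$true_envelope_mm,
                       xout = sw$swing_times, rule = 2)$y
  expect_gt(kendall_tau(sw$swing_amplitudes, env)$tau, 0.8)
})
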