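test_that("p fit is the closed-form 1/mean with working bootstrap", {
  h <- blink_histogram(c(1, 1, 2, 2, 3, 3))    # mean 2
  expect_equal(fit_p(h, B = 0)$p, 0.5)
  expect_equal(fit_p(blink_histogram(rep(1, 10)), B = 0)$p, 1)

  sim <- sim_blink_counts(2000, cfg_monomers(seed = 5))
  f <- fit_p(sim$hist, B = 200, seed = 2)
  expect_lt(f$ci$lower, 0.34)
  expect_gt(f$ci$upper, 0.34)
  expect_equal(f$mean_n, 1 / f$p)
})

test_that("q fit is self-consistent and flags the degenerate boundary", {
  p <- 0.27
  counts <- pmf_dimer(1:50, p, 0.35) * 1000
  counts[50] <- counts[50] + (1 - sum(pmf_dimer(1:50, p, 0.35))) * 1000
  f <- fit_q(counts, p, B = 0)
  expect_equal(f$q, 0.35, tolerance = 1e-6)
  expect_true(f$converged)

  f1 <- fit_q(blink_histogram(rep(1, 200)), p, B = 0)
  expect_false(f1$converged)
  expect_gt(f1$q, 0.99)
})

test_that("q fit recovers the detection efficiency of simulated dimers", {
  q_true <- d_to_q(0.64)
  qs <- vapply(1:20, function(s) {
    sim <- sim_blink_counts(5000, cfg_mixture(seed = s, f_dimer = 1))
    fit_q(sim$hist, p = 0.27, B = 0)$q
  }, numeric(1))
  expect_gte(mean(abs(qs - q_true) <= 0.02), 0.95)
})

test_that("mixture fit recovers observed weight and corrects detectability", {
  p <- 0.27; d_abs <- 0.64; q <- d_to_q(d_abs)
  mono <- pmf_appearances(1:50, 1, p)
  dim2 <- pmf_dimer(1:50, p, q)
  exact <- 0.5 * mono + 0.5 * dim2
  exact[50] <- exact[50] + (1 - sum(exact))
  f <- fit_mixture(exact * 4000, p, d_abs, B = 0)
  expect_equal(f$fractions_observed[["dimer"]], 0.5, tolerance = 1e-6)
  expect_equal(sum(f$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(f$fractions_observed), 1, tolerance = 1e-9)

  # closed-form detectability weighting at the study photophysics
  expect_equal(true_to_observed_fraction(0.71, 0.64), 0.7690, tolerance = 1e-4)
  for (ft in c(0.05, 0.3, 0.71, 0.95))
    expect_equal(observed_to_true_fraction(
      true_to_observed_fraction(ft, d_abs), d_abs), ft, tolerance = 1e-12)
})

test_that("detectability correction inverts the simulator's thinning", {
  # Monte-Carlo oracle: label/detect protomers of a 71% dimer population
  # and measure the dimer fraction among observable clusters
  f_true <- 0.71; d_abs <- 0.64
  obs <- with_seed(11, {
    size <- ifelse(stats::runif(2e5) < f_true, 2L, 1L)
    det <- stats::rbinom(2e5, size, d_abs)
    mean(size[det >= 1] == 2L)
  })
  expect_equal(obs, true_to_observed_fraction(f_true, d_abs), tolerance = 0.005)

  # the generator's rejection rate matches the analytic detection mass
  sim <- sim_blink_counts(20000, cfg_mixture(seed = 2, f_dimer = 0.71))
  n_rej <- attr(sim$truth, "n_rejected")
  p_det <- f_true * (1 - (1 - d_abs)^2) + (1 - f_true) * d_abs
  expect_equal(20000 / (20000 + n_rej), p_det, tolerance = 0.02)
  # and the observed dimer share among generated clusters matches
  expect_equal(mean(sim$truth$size == 2),
               true_to_observed_fraction(f_true, d_abs), tolerance = 0.01)
})

test_that("bootstrap intervals are deterministic, sane and guarded", {
  h <- blink_histogram(rep(2, 50))
  est <- function(hh) hh$total_clusters / sum(seq_len(hh$n_max) * hh$counts)
  ci <- bootstrap_ci(h, est, B = 200, seed = 4)
  expect_equal(ci$lower, ci$upper)          # one-bin histogram: zero width
  expect_equal(ci$sd, 0)

  sim <- sim_blink_counts(3000, cfg_monomers(seed = 8))
  a <- bootstrap_ci(sim$hist, est, B = 150, seed = 9)
  b <- bootstrap_ci(sim$hist, est, B = 150, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_ci(h, est, B = 50), class = "qp_parameter_error")
})

test_that("bootstrap CIs achieve near-nominal coverage for p", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_blink_counts(1500, cfg_monomers(seed = 1000 + s))
    f <- fit_p(sim$hist, B = 150, seed = s)
    f$ci$lower <= 0.34 && 0.34 <= f$ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("mixture bootstrap CIs cover the generating dimer fraction", {
  hits <- vapply(1:60, function(s) {
    sim <- sim_blink_counts(2000, cfg_mixture(seed = 2000 + s, f_dimer = 0.71))
    f <- fit_mixture(sim$hist, 0.27, 0.64, B = 150, seed = s)
    f$ci$dimer_true$lower <= 0.71 && 0.71 <= f$ci$dimer_true$upper
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
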