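# Shrinkage bookkeeping, evidence accumulation, posterior summaries and the
# evidence-comparison helpers.

test_that("shrinkage follows the expectation law", {
  expect_equal(shrinkage_lnX(0, 100), 0)
  expect_equal(exp(shrinkage_lnX(100, 100)), exp(-1))
  expect_equal(exp(shrinkage_lnX(2, 2000)), 0.9990005, tolerance = 1e-7)
  expect_error(shrinkage_lnX(-1, 10))
})

test_that("trapezoid weights take half the enclosing difference", {
  expect_equal(trapezoid_weight(0.9, 0.7), 0.1)
  K <- 100
  # first step with X0 = 1
  expect_equal(trapezoid_weight(1, exp(-2 / K)), 0.5 * (1 - exp(-2 / K)))
  # geometric chain: dX_m = sinh(1/K) exp(-m/K)
  m <- 17
  expect_equal(trapezoid_weight(exp(-(m - 1) / K), exp(-(m + 1) / K)),
               sinh(1 / K) * exp(-m / K), tolerance = 1e-14)
  expect_error(trapezoid_weight(0.5, 0.7), "bookkeeping")
})

test_that("volume weights and the live remainder partition the prior mass", {
  for (K in c(10, 250)) for (M in c(1, 2, 57, 2000)) {
    vol <- ln_volume_weights(M, K)
    expect_equal(sum(exp(vol$lnDX)) + exp(vol$ln_remainder), 1,
                 tolerance = 1e-12)
  }
})

test_that("simulated order statistics validate E[ln X_m] = -m/K", {
  # literal simulation: K uniforms, discard the largest, renormalize
  set.seed(51)
  K <- 20; reps <- 8000; M <- 20
  lnX <- matrix(0, reps, M)
  cur <- rep(0, reps)            # ln of current interval length
  for (m in 1:M) {
    mx <- apply(matrix(runif(reps * K), reps, K), 1, max)
    cur <- cur + log(mx)
    lnX[, m] <- cur
  }
  for (m in c(1, K / 2, K)) {
    se <- sd(lnX[, m]) / sqrt(reps)
    expect_lt(abs(mean(lnX[, m]) + m / K), 3 * se)
  }
})

test_that("initial live points have uniform-law moments and determinism", {
  sp <- param_space("x", 0, 1)
  m <- const_model(0)
  set.seed(52)
  lp <- init_live_points(sp, m, NULL, K = 1000)
  expect_lt(abs(mean(lp$points) - 0.5), 0.05)
  expect_lt(abs(lp$sigma - 1 / sqrt(12)), 0.02)
  set.seed(99); a <- init_live_points(sp, m, NULL, K = 50)
  set.seed(99); b <- init_live_points(sp, m, NULL, K = 50)
  expect_identical(a$points, b$points)
  expect_error(init_live_points(sp, m, NULL, K = 1), "K must be")
  dead <- ns_model("dead", loglik = function(a) -Inf, J = 1)
  set.seed(53)
  expect_error(init_live_points(sp, dead, NULL, K = 10), "initialization")
})

test_that("a constant likelihood gives lnE = ln c exactly, H = 0, C_b = 0", {
  for (seed in c(1, 2)) {
    r <- ns_run(const_model(0.7), NULL, param_space("x", -3, 3),
                ns_config(K = 25, cluster = FALSE, runs = 1), seed = seed)
    expect_equal(r$lnE, 0.7, tolerance = 1e-10)
    expect_equal(r$H, 0, tolerance = 1e-10)
    expect_equal(r$C_b, 0, tolerance = 1e-10)
    # weight conservation in log space
    expect_equal(sum(exp(r$ln_w - 0.7)), 1, tolerance = 1e-12)
  }
})

test_that("the dead chain has nondecreasing likelihood", {
  r <- ns_run(gauss_toy_model(), NULL, unit_space(),
              ns_config(K = 100, cluster = FALSE), seed = 54)
  expect_true(all(diff(r$dead$lnL) >= 0))
  expect_true(all(diff(r$dead$lnX) < 0))
})

test_that("information gain and complexity match quadrature oracles", {
  # 1-D Gaussian toy: H and C_b known analytically / by quadrature
  H_ref <- quad_H(function(x) -0.5 * x^2, -10, 10)
  expect_equal(H_ref, 0.5 * log(200 / pi) - 0.5, tolerance = 1e-6)
  set.seed(55)
  r <- ns_run(gauss_toy_model(), NULL, unit_space(), ns_config(K = 400))
  expect_lt(abs(r$H - H_ref), 0.15)
  expect_lt(abs(r$C_b - 1), 0.2)
  expect_error(information_gain(numeric(0), numeric(0)), "empty")
  expect_error(bayesian_complexity(numeric(0), numeric(0)), "empty")
})

test_that("posterior summaries use weighted moments and quantiles", {
  # equal weights on {0, 1}
  s <- posterior_summaries(cbind(c(0, 1)), log(c(0.5, 0.5)))
  expect_equal(s$mean, 0.5)
  # weights {0.9, 0.1}: mean 0.1, median 0
  s2 <- posterior_summaries(cbind(c(0, 1)), log(c(0.9, 0.1)))
  expect_equal(s2$mean, 0.1)
  expect_equal(s2$median, 0)
  expect_equal(s2$sd, sqrt(0.09), tolerance = 1e-12)
  # intervals are nested
  set.seed(56)
  s3 <- posterior_summaries(cbind(rnorm(500)), rep(0, 500))
  expect_true(s3$lo99 <= s3$lo95 && s3$lo95 <= s3$lo68)
  expect_true(s3$hi68 <= s3$hi95 && s3$hi95 <= s3$hi99)
  # symmetric posterior: mean and median agree within MC noise
  expect_lt(abs(s3$mean - s3$median), 0.2)
  expect_error(posterior_summaries(cbind(1), -Inf), "all-zero")
})

test_that("repeat-run uncertainty is the sample standard deviation", {
  expect_equal(multi_run_uncertainty(c(0, 2)),
               list(lnE = 1, delta_lnE = sqrt(2)))
  expect_equal(multi_run_uncertainty(rep(1.3, 6))$delta_lnE, 0)
  expect_warning(u1 <- multi_run_uncertainty(0.5), "single run")
  expect_true(is.na(u1$delta_lnE))
  # flat likelihood: identical lnE across runs, delta = 0
  fit <- ns_fit(const_model(2), NULL, param_space("x", 0, 1),
                ns_config(K = 20, runs = 3, cluster = FALSE), seed = 57)
  expect_equal(fit$delta_lnE, 0, tolerance = 1e-10)
  expect_equal(fit$lnE, 2, tolerance = 1e-10)
})

test_that("log Bayes factors combine evidence and prior odds", {
  expect_equal(log_bayes_factor(-5, -5), 0)
  expect_equal(log_bayes_factor(-4.1, -5), 0.9)
  expect_equal(log_bayes_factor(-5, -5, log(2)), log(2))
  expect_error(log_bayes_factor(-Inf, 0), "finite")
})

test_that("jump-counting walks shift the evidence up; Metropolis does not", {
  # narrow unimodal mode: the contour boundary layer is a large fraction of
  # the constrained region, which makes the jump-chain depletion visible
  narrow <- ns_model("narrow", loglik = function(a) -(a[1] - 5)^2 / 0.02,
                     J = 1)
  sp <- unit_space()
  want <- log(sqrt(2 * pi) * 0.1 / 20)
  lnE <- function(unit, N, s) {
    ns_run(narrow, NULL, sp,
           ns_config(K = 150, cluster = FALSE, walk_unit = unit, N = N),
           seed = s)$lnE
  }
  acc <- vapply(1:5, function(s) lnE("acceptances", 20, s), numeric(1))
  pro <- vapply(1:5, function(s) lnE("proposals", 100, s), numeric(1))
  # the jump-counting rule overshoots the analytic value ...
  expect_gt(mean(acc) - want, 0)
  # ... by more than the Metropolis variant does
  expect_gt(mean(acc), mean(pro))
  expect_lt(abs(mean(pro) - want), 0.25)
})
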