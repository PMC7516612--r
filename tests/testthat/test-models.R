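# Likelihoods and the two built-in model families.

test_that("poisson log-likelihood matches closed forms", {
  flat <- ns_model("flat", predict = function(x, a) rep(a[1], length(x)), J = 1)
  # all-zero counts over M bins at rate mu: lnL = -M * mu
  M <- 7; mu <- 1.3
  d0 <- spectrum_data(1:M, counts = rep(0, M))
  expect_equal(poisson_loglike(flat, d0, mu), -M * mu)
  # single bin n = 3, lambda = 2.5
  d1 <- spectrum_data(1, counts = 3)
  expect_equal(poisson_loglike(flat, d1, 2.5), 3 * log(2.5) - 2.5 - log(6),
               tolerance = 1e-12)
  expect_equal(poisson_loglike(flat, d1, 2.5), dpois(3, 2.5, log = TRUE))
})

test_that("poisson log-likelihood is bounded by the saturated model", {
  # saturated value for n = {1, 2}
  sat <- sum(dpois(1:2, 1:2, log = TRUE))
  expect_equal(sat, -2.30686, tolerance = 1e-5)
  two <- ns_model("two", predict = function(x, a) a, J = 2)
  d <- spectrum_data(1:2, counts = 1:2)
  expect_equal(poisson_loglike(two, d, c(1, 2)), sat, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:50) {
    lam <- runif(2, 0.01, 8)
    expect_lte(poisson_loglike(two, d, lam), sat + 1e-12)
  }
})

test_that("poisson conventions: 0 log 0 and zero rate with counts", {
  two <- ns_model("two", predict = function(x, a) a, J = 2)
  d00 <- spectrum_data(1:2, counts = c(0, 2))
  # zero rate on an empty bin contributes nothing
  expect_equal(poisson_loglike(two, d00, c(0, 2)), dpois(2, 2, log = TRUE))
  # zero rate with observed counts is -Inf, not an error
  expect_identical(poisson_loglike(two, spectrum_data(1:2, counts = c(1, 2)),
                                   c(0, 2)), -Inf)
  # a negative rate is an invalid model
  expect_error(poisson_loglike(two, d00, c(-1, 2)), "negative")
})

test_that("gaussian log-likelihood matches closed forms and scales", {
  flat <- ns_model("flat", predict = function(x, a) rep(a[1], length(x)), J = 1)
  M <- 5
  d <- spectrum_data(1:M, y = rep(2, M), sigma = rep(1, M))
  # zero residuals: -M ln sqrt(2 pi)
  expect_equal(gaussian_loglike(flat, d, 2), -M * log(sqrt(2 * pi)),
               tolerance = 1e-12)
  # single point y = 1, f = 0, sigma = 1
  d1 <- spectrum_data(1, y = 1, sigma = 1)
  expect_equal(gaussian_loglike(flat, d1, 0), dnorm(1, log = TRUE))
  expect_equal(gaussian_loglike(flat, d1, 0), -1.418939, tolerance = 1e-6)
  # doubling every sigma with zero residuals lowers lnL by M ln 2
  d2 <- spectrum_data(1:M, y = rep(2, M), sigma = rep(2, M))
  expect_equal(gaussian_loglike(flat, d2, 2),
               gaussian_loglike(flat, d, 2) - M * log(2), tolerance = 1e-12)
})

test_that("both likelihoods are additive over disjoint bin subsets", {
  m <- ns_model("gauss_peaks", npeaks = 1)
  a <- c(0.5, 2, 10, 40)
  set.seed(7)
  x <- 1:20
  cts <- rpois(20, predict(m, x, a))
  full <- spectrum_data(x, counts = cts)
  p1 <- spectrum_data(x[1:8], counts = cts[1:8])
  p2 <- spectrum_data(x[9:20], counts = cts[9:20])
  expect_equal(poisson_loglike(m, full, a),
               poisson_loglike(m, p1, a) + poisson_loglike(m, p2, a),
               tolerance = 1e-10)
  yg <- rnorm(20, predict(m, x, a) + 1, 0.5)
  fg <- spectrum_data(x, y = yg, sigma = rep(0.5, 20))
  g1 <- spectrum_data(x[1:8], y = yg[1:8], sigma = rep(0.5, 8))
  g2 <- spectrum_data(x[9:20], y = yg[9:20], sigma = rep(0.5, 12))
  expect_equal(gaussian_loglike(m, fg, a),
               gaussian_loglike(m, g1, a) + gaussian_loglike(m, g2, a),
               tolerance = 1e-10)
})

test_that("gauss_peaks model evaluates its closed forms", {
  # one peak, bg = 0, at x = x0: A / (w sqrt(2 pi))
  expect_equal(gauss_peaks_model(5, c(0, 2, 5, 10)), 10 / (2 * sqrt(2 * pi)))
  # background only
  expect_equal(gauss_peaks_model(1:4, c(3, 1, 2, 0)), rep(3, 4))
  # value at x0 +/- w is exp(-1/2) of the peak value
  peak <- gauss_peaks_model(5, c(0, 2, 5, 10))
  expect_equal(gauss_peaks_model(7, c(0, 2, 5, 10)), exp(-0.5) * peak,
               tolerance = 1e-12)
  expect_error(gauss_peaks_model(1:3, c(0, -1, 5, 10)), "width")
})

test_that("gauss_peaks is invariant under peak-index permutation", {
  x <- seq(0, 100, by = 0.5)
  a <- c(1, 3, 20, 50, 80, 10, 30, 20)       # bg, w, x0 x 3, A x 3
  perm <- c(1, 2, 2 + c(3, 1, 2), 5 + c(3, 1, 2))
  expect_equal(gauss_peaks_model(x, a), gauss_peaks_model(x, a[perm]),
               tolerance = 1e-12)
  d <- spectrum_data(x, counts = rpois(length(x), gauss_peaks_model(x, a)))
  m <- ns_model("gauss_peaks", npeaks = 3)
  expect_equal(poisson_loglike(m, d, a), poisson_loglike(m, d, a[perm]),
               tolerance = 1e-10)
})

test_that("peak areas integrate to sum(A) over a wide grid", {
  x <- seq(-200, 300, by = 0.05)
  a <- c(2, 4, 30, 60, 90, 120, 150, 200, 250, 100)  # 4 peaks
  f <- gauss_peaks_model(x, a) - 2
  integral <- (sum(f) - (f[1] + f[length(f)]) / 2) * 0.05
  expect_equal(integral, 150 + 200 + 250 + 100, tolerance = 1e-6)
})

test_that("modulated decay model evaluates its closed forms", {
  # modulation off: pure exponential + bg
  t <- c(0, 1, 2.5)
  expect_equal(modulated_decay_model(t, c(2, 3, 0, 1, 0, 0.5)),
               2 * exp(-t / 3) + 0.5, tolerance = 1e-12)
  # boundary value at t = 0, phi = 0
  expect_equal(modulated_decay_model(0, c(2, 3, 0.4, 1, 0, 0)), 2 * 1.4)
  # direct evaluation at t = 0.5 with a half-period cosine
  expect_equal(modulated_decay_model(0.5, c(1, 1, 0.5, 2 * pi, 0, 0)),
               0.5 * exp(-0.5), tolerance = 1e-10)
  expect_equal(modulated_decay_model(0.5, c(1, 1, 0.5, 2 * pi, 0, 0)),
               0.30327, tolerance = 1e-4)
  expect_error(modulated_decay_model(1, c(1, -1, 0, 1, 0, 0)), "lifetime")
})

test_that("model arity strings and parameter-count checks work", {
  m <- ns_model("gauss_peaks:4")
  expect_equal(m$J, 10)
  expect_error(predict(m, 1:5, rep(1, 9)), "expected 10")
  d <- spectrum_data(1:3, counts = c(1, 1, 1))
  flat <- ns_model("flat", predict = function(x, a) rep(a[1], 2), J = 1)
  expect_error(poisson_loglike(flat, d, 1), "mismatch")
})
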