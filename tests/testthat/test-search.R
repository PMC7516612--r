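# The lawn-mower walk, the two fallback strategies, and the escalation
# orchestration.

# a rigged likelihood that accepts inside a box and rejects elsewhere
box_lik <- function(lo, hi) {
  ns_model("box", loglik = function(a) {
    if (all(a >= lo) && all(a <= hi)) 0 else -Inf
  }, J = length(lo))
}

test_that("a walk with nothing to reject takes N clean steps", {
  m <- const_model(1)
  set.seed(21)
  w <- lawn_mower_walk(0.5, 1, sigma = 0.01, lnL_threshold = 0, model = m,
                       f = 0.1, N = 15, lower = -100, upper = 100)
  expect_false(w$escalated)
  expect_equal(w$n_steps, 15)
  expect_equal(w$nt, 0)
  expect_equal(w$n_proposals, 15)
  expect_equal(w$lnL, 1)
})

test_that("walk acceptance matches a brute-force simulation of the rule", {
  # acceptance region [0.4, 0.6] inside [0, 1]; start at the center
  m <- box_lik(0.4, 0.6)
  set.seed(22)
  w <- lawn_mower_walk(0.5, 0, sigma = 1, lnL_threshold = -1, model = m,
                       f = 0.1, N = 2000, lower = 0, upper = 1, Nt = 1e6)
  acc_hat <- w$n_accepted / w$n_proposals
  # oracle: simulate the identical Markov chain in R
  set.seed(122)
  x <- 0.5; nacc <- 0; nprop <- 0
  while (nacc < 2000) {
    p <- x + 0.1 * rnorm(1)
    nprop <- nprop + 1
    if (p >= 0 && p <= 1 && p >= 0.4 && p <= 0.6) { x <- p; nacc <- nacc + 1 }
  }
  acc_ref <- nacc / nprop
  se <- sqrt(acc_ref * (1 - acc_ref) * (1 / w$n_proposals + 1 / nprop))
  expect_lt(abs(acc_hat - acc_ref), 3 * se + 1e-3)
})

test_that("escalation fires when nt reaches Nt and reports the failing point", {
  m <- ns_model("nofit", loglik = function(a) -Inf, J = 1)
  set.seed(23)
  w <- suppressWarnings(
    lawn_mower_walk(0.5, Inf, sigma = 1, lnL_threshold = 0, model = m,
                    f = 0.1, N = 5, lower = 0, upper = 1, nt = 0, Nt = 12))
  expect_true(w$escalated)
  expect_equal(w$nt, 12)
  expect_equal(w$n_proposals, 12)
  expect_equal(w$a, 0.5)          # chain never moved
  expect_false(w$a_fail == 0.5)   # last rejected proposal is reported
})

test_that("out-of-bounds proposals count as failures, not clips", {
  m <- const_model(1)
  set.seed(24)
  # start at the corner with huge steps: most proposals leave the box
  w <- lawn_mower_walk(c(0.01, 0.01), 1, sigma = c(5, 5), lnL_threshold = 0,
                       model = m, f = 1, N = 3, lower = c(0, 0),
                       upper = c(1, 1), Nt = 1e5)
  expect_gt(w$n_proposals, w$n_accepted)   # rejections happened
  expect_true(all(w$a >= 0 & w$a <= 1))     # and were never clipped inside
})

test_that("barycenter fallback draws on the segment and accepts by region", {
  m <- box_lik(c(-1, -1), c(1, 1))   # unit square around the origin
  # degenerate segment: candidate equals the barycenter
  set.seed(25)
  r <- barycenter_fallback(c(0.3, 0.3), c(0.3, 0.3), 0, m,
                           lower = c(-5, -5), upper = c(5, 5))
  expect_equal(r$a, c(0.3, 0.3))
  expect_true(r$success)
  # acceptance probability: a_fail at (2, 0), region = square |x|,|y| <= 1;
  # candidate u*(2,0) is inside iff u < 0.5
  hits <- 0; n <- 4000
  set.seed(26)
  for (i in seq_len(n)) {
    r <- barycenter_fallback(c(2, 0), c(0, 0), 0, m,
                             lower = c(-5, -5), upper = c(5, 5))
    hits <- hits + r$success
  }
  expect_lt(abs(hits / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("coordinate mix enumerates component combinations uniformly", {
  live <- rbind(c(0, 0), c(1, 1))
  m <- const_model(0)
  set.seed(27)
  combos <- replicate(4000, paste(
    coordinate_mix_fallback(live, -1, m)$a, collapse = ","))
  freq <- table(combos) / 4000
  expect_equal(length(freq), 4)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # all live points identical -> candidate identical
  same <- coordinate_mix_fallback(rbind(c(2, 3), c(2, 3)), -1, m)
  expect_equal(same$a, c(2, 3))
})

test_that("coordinate mix preserves the per-coordinate marginals", {
  set.seed(28)
  live <- cbind(rnorm(40), runif(40, 5, 6))
  m <- const_model(0)
  draws <- t(replicate(2000, coordinate_mix_fallback(live, -1, m)$a))
  for (j in 1:2) {
    expect_true(all(draws[, j] %in% live[, j]))
    expect_lt(abs(mean(draws[, j]) - mean(live[, j])),
              3 * sd(live[, j]) / sqrt(2000))
  }
})

test_that("an easy landscape needs no fallbacks or cluster analyses", {
  set.seed(29)
  live <- matrix(runif(40, -1, 1), 20, 2)
  m <- const_model(5)
  res <- find_new_live_point(live, rep(5, 20), lnL_threshold = 0, model = m,
                             space = param_space(c("a", "b"), c(-1, -1),
                                                c(1, 1)),
                             config = ns_config(K = 20, N = 10, f = 0.2))
  expect_equal(res$lnL, 5)
  expect_equal(res$state$nt, 0)
  expect_equal(res$state$n_cluster_analyses, 0)
  expect_length(res$events, 0)
})

test_that("failure injection reproduces the escalation ledger exactly", {
  # likelihood that fails the first `budget` evaluations, then succeeds:
  # drives the orchestrator through a deterministic escalation sequence
  calls <- new.env(); calls$n <- 0
  budget <- 25
  m <- ns_model("rigged", loglik = function(a) {
    calls$n <- calls$n + 1
    if (calls$n <= budget) -Inf else 1
  }, J = 1)
  live <- matrix(runif(10), 10, 1)
  # wide box so no proposal is ever rejected for bounds: every walk failure
  # consumes exactly one rigged likelihood call
  sp <- param_space("x", -100, 100)
  set.seed(30)
  res <- find_new_live_point(live, rep(2, 10), lnL_threshold = 0, model = m,
                             space = sp,
                             config = ns_config(K = 10, N = 5, f = 0.1,
                                                Nt = 10, NNt = 2,
                                                cluster = TRUE))
  # Nt=10, NNt=2: first escalation at 10 walk fails, one fallback try follows;
  # trigger threshold is 20 cumulative walk fails
  ev <- res$events
  expect_equal(ev[1], 1)                       # first escalation
  expect_true(any(ev == 6))                    # cluster analysis fired
  esc_before_cluster <- sum(ev[seq_len(which(ev == 6)[1])] == 1)
  expect_equal(esc_before_cluster, 2)          # exactly at Nt * NNt fails
  expect_equal(res$state$n_cluster_analyses,
               floor(budget / (10 * 2)))       # cumulative-failure bookkeeping
  expect_equal(res$lnL, 1)
})

test_that("returned points always satisfy the constraint and bounds", {
  set.seed(31)
  m <- gauss_toy_model()
  sp <- unit_space()
  live <- matrix(runif(30, -2, 2), 30, 1)
  lnL <- vapply(seq_len(30), function(i) -0.5 * live[i, 1]^2, numeric(1))
  thr <- sort(lnL)[3]
  for (i in 1:40) {
    res <- find_new_live_point(live, lnL, thr, m, space = sp,
                               config = ns_config(K = 30, N = 10, f = 0.3))
    expect_gt(res$lnL, thr)
    expect_true(res$a >= -10 && res$a <= 10)
  }
})

test_that("hard-constraint sampling is uniform above the threshold", {
  # constant likelihood on a 2-D box: stationary distribution of the
  # returned points must be uniform (chi-square on a coarse grid)
  set.seed(32)
  K <- 60
  live <- matrix(runif(2 * K), K, 2)
  m <- const_model(3)
  sp <- param_space(c("x", "y"), c(0, 0), c(1, 1))
  # proposal-counting walk: exact Metropolis, uniform stationary law
  cfg <- ns_config(K = K, N = 150, f = 0.5, cluster = FALSE,
                   walk_unit = "proposals")
  pts <- t(replicate(1200, find_new_live_point(live, rep(3, K), 0, m,
                                               space = sp, config = cfg)$a))
  grid <- 3
  cells <- table(factor(ceiling(pts[, 1] * grid), 1:grid),
                 factor(ceiling(pts[, 2] * grid), 1:grid))
  p <- suppressWarnings(chisq.test(as.vector(cells)))$p.value
  expect_gt(p, 0.001)
})

test_that("cluster labels steer the walk scale", {
  # two well-separated tight clumps with labels: the walk started in a
  # cluster must use that cluster's sigma, not the global one
  set.seed(33)
  live <- rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
                matrix(rnorm(40, 5, 0.01), 20, 2))
  labels <- rep(1:2, each = 20)
  m <- const_model(2)
  sp <- param_space(c("x", "y"), c(-10, -10), c(10, 10))
  cfg <- ns_config(K = 40, N = 5, f = 0.2)
  glob_sd <- apply(live, 2, function(v) sqrt(mean(v^2) - mean(v)^2))
  for (i in 1:20) {
    res <- find_new_live_point(live, rep(2, 40), 0, m, space = sp,
                               config = cfg, labels = labels)
    clu <- labels[res$start_index]
    expect_equal(res$cluster_label, clu)
    members <- live[labels == clu, ]
    expect_equal(res$sigma_used,
                 apply(members, 2, function(v) sqrt(mean(v^2) - mean(v)^2)),
                 tolerance = 1e-7)
    expect_true(all(res$sigma_used < glob_sd / 10))
  }
})
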