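# Core nested-sampling bookkeeping and a single run.

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Expected log prior-volume shrinkage
#'
#' After `m` discards with `K` live points the enclosed prior volume has
#' shrunk, in expectation, to `X_m = exp(-m / K)`; the deterministic
#' expectation form is used throughout the bookkeeping.
#'
#' @param m Step index (>= 0).
#' @param K Number of live points (>= 1).
#' @return `lnX_m = -m / K`.
#' @export
shrinkage_lnX <- function(m, K) {
  if (any(m < 0) || K < 1) stop("need m >= 0 and K >= 1")
  -m / K
}

#' Trapezoid prior-volume weight
#'
#' `dX_m = (X_{m-1} - X_{m+1}) / 2`, the trapezoid-rule slice assigned to the
#' m-th discarded point; computed stably in log space.
#'
#' @param X_prev,X_next Enclosing volumes `X_{m-1} > X_{m+1} >= 0`.
#' @return The slice width.
#' @export
trapezoid_weight <- function(X_prev, X_next) {
  if (any(X_next < 0) || any(X_prev <= X_next))
    stop("bookkeeping error: need X_prev > X_next >= 0")
  # log-space: log(dX) = log(X_prev)+log1p(-X_next/X_prev)-log(2)
  exp(log(X_prev) + log1p(-X_next / X_prev) - log(2))
}

# log trapezoid weights for a full chain of M discards with the end-cap
# partition: dX_1 = 1 - (X_1+X_2)/2, dX_m = (X_{m-1}-X_{m+1})/2 for m >= 2,
# remainder (X_M + X_{M+1})/2. Sums to 1 exactly.
ln_volume_weights <- function(M, K) {
  if (M < 1) stop("empty chain")
  m <- seq_len(M)
  lnDX <- log(sinh(1 / K)) - m / K
  lnDX[1] <- log(1 - 0.5 * (exp(-1 / K) + exp(-2 / K)))
  ln_rem <- log(0.5 * (exp(-M / K) + exp(-(M + 1) / K)))
  list(lnDX = lnDX, ln_remainder = ln_rem)
}

#' Draw the initial live-point set
#'
#' `K` independent uniform draws in the prior box, with log-likelihoods and
#' the per-dimension population standard deviation and barycenter of the
#' set.
#'
#' @param space A [param_space].
#' @param model An [ns_model].
#' @param data A [spectrum_data] (or `NULL` for direct-loglik models).
#' @param K Number of live points (>= 2).
#' @return A list of class `live_points`: `points` (K x J), `lnL`, `sigma`,
#'   `barycenter`.
#' @export
init_live_points <- function(space, model, data = NULL, K) {
  stopifnot_space(space)
  if (K < 2) stop("config error: K must be >= 2")
  J <- space$J
  pts <- matrix(stats::runif(K * J), K, J)
  pts <- sweep(pts, 2, space$upper - space$lower, "*")
  pts <- sweep(pts, 2, space$lower, "+")
  colnames(pts) <- space$names
  spec <- ns_likelihood(model, data)
  lnL <- eval_loglik_batch_cpp(spec, pts)
  if (all(lnL == -Inf))
    stop("initialization error: every initial live point has zero likelihood")
  structure(list(points = pts, lnL = lnL,
                 sigma = sqrt(pmax(colMeans(pts^2) - colMeans(pts)^2, 0)),
                 barycenter = colMeans(pts)),
            class = "live_points")
}

#' Single nested-sampling run
#'
#' Runs the full loop: at each step the worst live point is discarded and
#' recorded with prior-volume weight from the trapezoid rule under the
#' deterministic shrinkage `X_m = exp(-m/K)`, then replaced through
#' [find_new_live_point()]'s search. The run stops when the largest possible
#' remaining contribution `max(L_live) X_m` falls below `stop_tol` times the
#' accumulated evidence; the surviving live points then contribute the final
#' remainder volume `(X_M + X_{M+1})/2`, split evenly, each at its own
#' likelihood, so the volume weights sum to the prior mass 1 exactly.
#'
#' @inheritParams init_live_points
#' @param config An [ns_config].
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return An object of class `ns_run` with the evidence `lnE`, information
#'   gain `H` (nats), Bayesian complexity `C_b`, `best_fit`, per-parameter
#'   `summaries`, the weighted sample set (`samples`, `ln_w`, `lnL`,
#'   `is_live`), the dead-chain bookkeeping (`dead`), search `counters`,
#'   `cluster_history`, and the termination `status`.
#' @export
ns_run <- function(model, data = NULL, space, config = ns_config(),
                   seed = NULL) {
  stopifnot_space(space)
  if (!is.null(seed)) set.seed(seed)
  K <- config$K
  live <- init_live_points(space, model, data, K)
  spec <- ns_likelihood(model, data)
  res <- ns_run_cpp(spec, space$lower, space$upper, unclass(config),
                    live$points, live$lnL)
  if (res$status == 2)
    stop("non-convergence: cluster-analysis cap reached (partial run lost)")
  if (res$status == 3)
    stop("non-convergence: search failure cap reached")
  if (res$status == 1)
    warning("run stopped at max_steps before the termination criterion")
  M <- res$steps
  vol <- ln_volume_weights(M, K)
  ln_w_dead <- res$dead_lnw
  ln_w_live <- res$live_lnL + vol$ln_remainder - log(K)
  samples <- rbind(res$dead, res$live)
  colnames(samples) <- space$names
  ln_w <- c(ln_w_dead, ln_w_live)
  lnL_all <- c(res$dead_lnL, res$live_lnL)
  is_live <- rep(c(FALSE, TRUE), c(M, K))
  lnE <- logsumexp(ln_w)
  H <- information_gain(ln_w, lnL_all, lnE)
  Cb <- bayesian_complexity(ln_w, lnL_all)
  best <- samples[which.max(lnL_all), ]
  out <- list(
    lnE = lnE, H = H, C_b = Cb,
    best_fit = best, lnL_max = max(lnL_all),
    summaries = posterior_summaries(samples, ln_w),
    samples = samples, ln_w = ln_w, lnL = lnL_all, is_live = is_live,
    dead = list(a = res$dead, lnL = res$dead_lnL,
                lnX = -seq_len(M) / K, ln_w = ln_w_dead),
    live = list(a = res$live, lnL = res$live_lnL, labels = res$live_labels,
                ln_w = ln_w_live),
    steps = M, K = K,
    counters = res$counters,
    cluster_history = res$cluster_history,
    cluster_snapshots = res$cluster_snapshots,
    n_likelihood_evals = res$n_likelihood_evals,
    events = res$events,
    status = res$status,
    model = model, space = space, config = config, data = data)
  class(out) <- "ns_run"
  out
}

#' @export
print.ns_run <- function(x, ...) {
  cat(sprintf("Nested-sampling run: lnE = %.4f  (H = %.3f nats, C_b = %.2f)\n",
              x$lnE, x$H, x$C_b))
  cat(sprintf("  %d steps, K = %d live points, %d cluster analyses\n",
              x$steps, x$K, x$counters$n_cluster_analyses))
  invisible(x)
}

#' Information gain of a completed run
#'
#' Kullback-Leibler divergence from the prior to the posterior, in nats:
#' `H = sum_m (w_m / E) lnL_m - lnE`, including the live-point remainder
#' records. Its square root over `K` sets the theoretical evidence
#' uncertainty `sqrt(H / K)`.
#'
#' @param ln_w Log posterior weights `ln(L_m dX_m)`.
#' @param lnL Log-likelihoods of the same records.
#' @param lnE Log-evidence; recomputed from `ln_w` when missing.
#' @return `H` in nats.
#' @export
information_gain <- function(ln_w, lnL, lnE = logsumexp(ln_w)) {
  if (!length(ln_w)) stop("empty chain")
  p <- exp(ln_w - lnE)
  keep <- p > 0 & is.finite(lnL)
  sum(p[keep] * lnL[keep]) - lnE
}

#' Bayesian complexity of a completed run
#'
#' Effective number of parameters constrained by the data,
#' `C_b = -2 (<lnL>_posterior - lnL_max)`, anchored at the best sampled
#' point. The best-point anchor (rather than the likelihood at the posterior
#' mean) is deliberate: for permutation-degenerate posteriors the posterior
#' mean lies between modes and its likelihood is meaningless.
#'
#' @inheritParams information_gain
#' @return `C_b`.
#' @export
bayesian_complexity <- function(ln_w, lnL, lnE = logsumexp(ln_w)) {
  if (!length(ln_w)) stop("empty chain")
  p <- exp(ln_w - lnE)
  keep <- p > 0 & is.finite(lnL)
  -2 * (sum(p[keep] * lnL[keep]) - max(lnL[is.finite(lnL)]))
}

# weighted empirical quantile: smallest x with cumulative weight >= prob
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-15)[1]], numeric(1))
}

#' Weighted posterior summaries
#'
#' Per-parameter posterior mean, median, standard deviation and central
#' 68/95/99% credible intervals, from the weighted empirical quantile
#' function of the dead-point chain (intervals are
#' `[q(alpha/2), q(1 - alpha/2)]`).
#'
#' @param samples Matrix of parameter samples (rows).
#' @param ln_w Log weights.
#' @return A data frame with one row per parameter.
#' @export
posterior_summaries <- function(samples, ln_w) {
  samples <- as.matrix(samples)
  if (!length(ln_w) || all(ln_w == -Inf)) stop("all-zero weights")
  p <- exp(ln_w - logsumexp(ln_w))
  nm <- colnames(samples)
  if (is.null(nm)) nm <- paste0("a", seq_len(ncol(samples)))
  rows <- lapply(seq_len(ncol(samples)), function(j) {
    x <- samples[, j]
    mu <- sum(p * x)
    sd <- sqrt(max(sum(p * x^2) - mu^2, 0))
    q <- weighted_quantile(x, p, c(0.5, 0.16, 0.84, 0.025, 0.975, 0.005, 0.995))
    data.frame(parameter = nm[j], mean = mu, median = q[1], sd = sd,
               lo68 = q[2], hi68 = q[3], lo95 = q[4], hi95 = q[5],
               lo99 = q[6], hi99 = q[7])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evidence uncertainty from repeated runs
#'
#' The run-to-run scatter of `lnE` over `R` independent nested-sampling runs
#' (different starting live points) is the natural estimate of the evidence
#' uncertainty: `delta(lnE)` is the sample standard deviation (n-1
#' denominator) of the `R` values. With `R = 1` the uncertainty is undefined
#' and reported as `NA` with a warning.
#'
#' @param lnE_values Numeric vector of per-run `lnE`.
#' @return List with `lnE` (mean) and `delta_lnE`.
#' @export
multi_run_uncertainty <- function(lnE_values) {
  lnE_values <- as.numeric(lnE_values)
  if (length(lnE_values) < 1) stop("no runs")
  if (length(lnE_values) == 1) {
    warning("delta(lnE) undefined for a single run; reporting NA")
    return(list(lnE = lnE_values, delta_lnE = NA_real_))
  }
  list(lnE = mean(lnE_values), delta_lnE = stats::sd(lnE_values))
}

#' Log Bayes factor / posterior odds
#'
#' `ln(odds) = lnE_1 - lnE_2 + ln(prior odds)`. As a rule of thumb a
#' difference of 0.9 in `lnE` corresponds to about a two-sigma preference.
#'
#' @param lnE_1,lnE_2 Log-evidences of the two models.
#' @param ln_prior_odds Log prior odds (default 0, equal priors).
#' @return Log posterior odds in favor of model 1.
#' @export
log_bayes_factor <- function(lnE_1, lnE_2, ln_prior_odds = 0) {
  if (!is.finite(lnE_1) || !is.finite(lnE_2) || !is.finite(ln_prior_odds))
    stop("inputs must be finite")
  lnE_1 - lnE_2 + ln_prior_odds
}
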