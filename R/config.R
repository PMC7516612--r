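#' Nested-sampling run configuration
#'
#' Collects every tunable of the sampler. The search-related defaults follow
#' the recommended operating range for difficult multimodal spectra:
#' walk factor `f = 0.2` with `N = 20` accepted steps (the efficiency
#' criterion is `f * N >~ 1`), escalation budgets `Nt = 200` failures before a
#' fallback strategy and `NNt = 2` escalation cycles before a cluster
#' analysis, and a truncated Gaussian mean-shift kernel with neighborhood
#' radius `D = 0.6` and bandwidth `ell = 0.2` in min-max-normalized units.
#'
#' @param K Number of live points (>= 2).
#' @param N Accepted steps per lawn-mower walk (>= 1).
#' @param f Step-size factor multiplying the per-dimension live-point
#'   standard deviation (> 0).
#' @param Nt Consecutive failed proposals before the walk escalates to a
#'   fallback strategy; any accepted proposal (or successful fallback) resets
#'   the counter (>= 1).
#' @param NNt Escalation cycles before a mean-shift cluster analysis is
#'   triggered, i.e. the analysis fires at `Nt * NNt` consecutive failures
#'   (>= 1).
#' @param kernel Mean-shift kernel, `"gaussian"` or `"flat"`. Both are
#'   truncated at the neighborhood radius `D`.
#' @param D Neighborhood radius in normalized units (> 0).
#' @param ell Gaussian-kernel bandwidth in normalized units (> 0).
#' @param ms_tol Mean-shift convergence tolerance (max displacement per
#'   iteration, normalized units).
#' @param ms_max_iter Mean-shift iteration cap.
#' @param merge_dist Single-linkage radius merging converged modes into one
#'   cluster (normalized units).
#' @param ms_blurring Use the blurring mean-shift iteration (see
#'   [mean_shift()]); default `FALSE` (standard query-shifting).
#' @param cluster Enable cluster recognition (set `FALSE` to reproduce the
#'   plain sampler).
#' @param max_cluster_analyses Hard cap of cluster analyses per run before a
#'   non-convergence error (typical runs need 2-10).
#' @param stop_tol Termination tolerance: the run stops once the largest
#'   possible remaining contribution `max(L_live) * X_m` drops below
#'   `stop_tol` times the accumulated evidence.
#' @param max_steps Iteration cap (default `200 * K`).
#' @param runs Number of independent repeats `R`; the evidence uncertainty
#'   `delta(lnE)` is the sample standard deviation of the `R` `lnE` values
#'   (the protocol default is 16).
#' @param walk_unit What the walk budget `N` counts: `"acceptances"`
#'   (accepted jumps, the lawn-mower rule) or `"proposals"` (every proposal,
#'   a rejection holding the chain in place — plain Metropolis, which
#'   removes the small contour-boundary depletion of the jump-counting rule
#'   at the price of a shorter effective walk; see the methods vignette).
#' @param proposal Distribution of the per-component random step factor
#'   `r_j`: `"normal"` (standard normal) or `"uniform"` (on `[-1, 1]`).
#' @param sigma_floor_rel Relative floor applied to every step scale,
#'   `sigma >= sigma_floor_rel * (upper - lower)`, so singleton clusters keep
#'   a nonzero scale.
#' @param record_events Keep the structured per-step event trace (escalations,
#'   fallbacks, cluster triggers) and a live-set snapshot at each cluster
#'   analysis in the result.
#' @return An object of class `ns_config`.
#' @seealso [validate_ns_config()]
#' @export
ns_config <- function(K = 1000, N = 20, f = 0.2, Nt = 200, NNt = 2,
                      kernel = c("gaussian", "flat"), D = 0.6, ell = 0.2,
                      ms_tol = 1e-4, ms_max_iter = 100, merge_dist = 0.05,
                      ms_blurring = FALSE,
                      cluster = TRUE, max_cluster_analyses = 50,
                      stop_tol = 1e-5, max_steps = 200 * K, runs = 16,
                      walk_unit = c("acceptances", "proposals"),
                      proposal = c("normal", "uniform"),
                      sigma_floor_rel = 1e-12, record_events = FALSE) {
  kernel <- match.arg(kernel)
  proposal <- match.arg(proposal)
  walk_unit <- match.arg(walk_unit)
  cfg <- list(K = as.integer(K), N = as.integer(N), f = f,
              Nt = as.integer(Nt), NNt = as.integer(NNt),
              walk_unit = walk_unit,
              walk_unit_id = if (walk_unit == "acceptances") 0L else 1L,
              kernel = kernel,
              kernel_id = if (kernel == "gaussian") 1L else 0L,
              D = D, ell = ell, ms_tol = ms_tol,
              ms_max_iter = as.integer(ms_max_iter), merge_dist = merge_dist,
              ms_blurring = isTRUE(ms_blurring),
              cluster = isTRUE(cluster),
              max_cluster_analyses = as.integer(max_cluster_analyses),
              stop_tol = stop_tol, max_steps = max_steps,
              runs = as.integer(runs), proposal = proposal,
              proposal_id = if (proposal == "normal") 0L else 1L,
              sigma_floor_rel = sigma_floor_rel,
              record_events = isTRUE(record_events))
  class(cfg) <- "ns_config"
  err <- config_errors(cfg)
  if (length(err)) stop("config error: ", paste(err, collapse = "; "))
  cfg
}

config_errors <- function(cfg) {
  err <- character(0)
  if (cfg$K < 2) err <- c(err, "K must be >= 2")
  if (cfg$N < 1) err <- c(err, "N must be >= 1")
  if (!is.finite(cfg$f) || cfg$f <= 0) err <- c(err, "f must be > 0")
  if (cfg$Nt < 1) err <- c(err, "Nt must be >= 1")
  if (cfg$NNt < 1) err <- c(err, "NNt must be >= 1")
  if (cfg$stop_tol <= 0) err <- c(err, "stop_tol must be > 0")
  if (cfg$runs < 1) err <- c(err, "runs must be >= 1")
  if (cfg$D <= 0) err <- c(err, "D must be > 0")
  if (cfg$kernel == "gaussian" && cfg$ell <= 0) err <- c(err, "ell must be > 0")
  if (cfg$ms_tol <= 0) err <- c(err, "ms_tol must be > 0")
  if (cfg$ms_max_iter < 1) err <- c(err, "ms_max_iter must be >= 1")
  err
}

#' Sanity-check a configuration against the sampler's operating criteria
#'
#' Structural violations (e.g. `K < 2`) are errors at construction time; this
#' check returns *warnings* for configurations that are legal but known to
#' behave poorly: `f * N < 1` (the walk cannot cover one standard deviation
#' around its start, so live points stay correlated) and a small live-point
#' number `K < 500` for model families with exchangeable components, whose
#' permutation-degenerate maxima are then not explored reliably.
#'
#' @param config An [ns_config] object.
#' @param model Optional [ns_model]; used to recognize multimodal families
#'   (Gaussian peaks with two or more exchangeable components).
#' @param space Optional [param_space]; when the per-peak position bounds
#'   differ, the peaks are not exchangeable and the small-K warning is
#'   suppressed.
#' @return Character vector of warning messages (also emitted via
#'   [warning()]), invisibly.
#' @export
validate_ns_config <- function(config, model = NULL, space = NULL) {
  if (!inherits(config, "ns_config")) stop("config error: not an ns_config")
  w <- character(0)
  if (config$f * config$N < 1)
    w <- c(w, sprintf(
      "f * N = %.3g < 1: the walk cannot decorrelate from its start (criterion f*N >= 1)",
      config$f * config$N))
  exchangeable <- TRUE
  if (!is.null(space) && !is.null(model) && inherits(model, "ns_model") &&
      model$model_id == 0L && model$npeaks >= 2) {
    idx <- 2 + seq_len(model$npeaks)
    exchangeable <- length(unique(space$lower[idx])) == 1 &&
      length(unique(space$upper[idx])) == 1
  }
  if (!is.null(model) && inherits(model, "ns_model") &&
      model$model_id == 0L && model$npeaks >= 2 && config$K < 500 &&
      exchangeable)
    w <- c(w, sprintf(
      "K = %d < 500 with %d exchangeable peaks: permutation modes may be missed",
      config$K, model$npeaks))
  for (msg in w) warning(msg, call. = FALSE)
  invisible(w)
}

#' @export
print.ns_config <- function(x, ...) {
  cat(sprintf(
    "ns_config: K=%d, N=%d, f=%g, Nt=%d, NNt=%d, kernel=%s (D=%g, ell=%g)\n",
    x$K, x$N, x$f, x$Nt, x$NNt, x$kernel, x$D, x$ell))
  cat(sprintf("  cluster=%s, stop_tol=%g, runs=%d, proposal=%s\n",
              x$cluster, x$stop_tol, x$runs, x$proposal))
  invisible(x)
}
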