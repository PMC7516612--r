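# R surface over the compiled search primitives. These are the building
# blocks of the live-point replacement step; ns_run() drives the same
# compiled code directly.

#' Lawn-mower constrained random walk
#'
#' Performs up to `N` accepted steps `a -> a + f * r * sigma` (componentwise,
#' `r_j` standard normal by default), each accepted iff the proposal is
#' inside the bounds and its log-likelihood is at least `lnL_threshold`
#' (ties are accepted so likelihood plateaus remain reachable). Every
#' rejected proposal increments the consecutive-failure counter `nt` and
#' every acceptance clears it; at each `Nt`-th consecutive failure the walk
#' stops early and signals escalation, returning the last failing proposal
#' for the barycenter fallback.
#'
#' @param start Numeric start point (must satisfy the constraint).
#' @param lnL_start Log-likelihood at `start`.
#' @param sigma Per-dimension step scale.
#' @param lnL_threshold Hard likelihood constraint.
#' @param model,data Likelihood specification ([ns_model] and
#'   [spectrum_data]; `data` may be `NULL` for direct-loglik models).
#' @param f,N Step factor and acceptance budget.
#' @param lower,upper Box bounds.
#' @param nt Current failure count (carried across calls).
#' @param Nt Escalation budget.
#' @param proposal `"normal"` or `"uniform"`.
#' @param walk_unit `"acceptances"` (default) or `"proposals"`; see
#'   [ns_config()].
#' @return List with `a`, `lnL`, `n_steps`, `n_accepted`, `nt`, `escalated`,
#'   `a_fail` (last rejected proposal, meaningful when escalated) and
#'   `n_proposals`.
#' @export
lawn_mower_walk <- function(start, lnL_start, sigma, lnL_threshold, model,
                            data = NULL, f = 0.2, N = 20, lower, upper,
                            nt = 0, Nt = 200,
                            proposal = c("normal", "uniform"),
                            walk_unit = c("acceptances", "proposals")) {
  proposal <- match.arg(proposal)
  walk_unit <- match.arg(walk_unit)
  if (f <= 0 || N < 1) stop("config error: need f > 0 and N >= 1")
  if (!(lnL_start >= lnL_threshold))
    stop("walk start must satisfy the likelihood constraint")
  spec <- ns_likelihood(model, data)
  lawn_mower_walk_cpp(as.numeric(start), lnL_start, as.numeric(sigma),
                      lnL_threshold, f, as.integer(N), as.numeric(lower),
                      as.numeric(upper), spec, as.integer(nt), as.integer(Nt),
                      if (proposal == "normal") 0L else 1L,
                      if (walk_unit == "acceptances") 0L else 1L)
}

#' Barycenter fallback search
#'
#' Draws a candidate uniformly on the segment between the live-point
#' barycenter and the last failing chain point,
#' `cand = g + u (a_fail - g)` with `u ~ U(0, 1)`; the candidate is accepted
#' iff it is in bounds and meets the likelihood constraint. This strategy
#' favors re-centering of the live ensemble.
#'
#' @param a_fail Last failing chain point (may lie outside the bounds).
#' @param barycenter Live-point barycenter.
#' @inheritParams lawn_mower_walk
#' @return List with `a`, `lnL`, `u` and `success`.
#' @export
barycenter_fallback <- function(a_fail, barycenter, lnL_threshold, model,
                                data = NULL, lower, upper) {
  spec <- ns_likelihood(model, data)
  barycenter_fallback_cpp(as.numeric(a_fail), as.numeric(barycenter),
                          lnL_threshold, as.numeric(lower), as.numeric(upper),
                          spec)
}

#' Coordinate-mix fallback search
#'
#' Builds a synthetic candidate whose j-th component is the j-th component
#' of a live point drawn uniformly (and independently per dimension) from
#' the current set, so each marginal of the candidate follows the empirical
#' live-point marginal. Good at jumping between peripheral likelihood
#' maxima. On rejection the caller restarts the walk from a fresh random
#' live point.
#'
#' @param live Matrix of live points (rows).
#' @inheritParams lawn_mower_walk
#' @return List with `a`, `lnL` and `success`.
#' @export
coordinate_mix_fallback <- function(live, lnL_threshold, model, data = NULL) {
  if (nrow(live) < 2) stop("need at least two live points")
  spec <- ns_likelihood(model, data)
  coordinate_mix_fallback_cpp(as.matrix(live), lnL_threshold, spec)
}

#' Search state for the live-point replacement orchestrator
#'
#' @param nt Failed tries since the last reset.
#' @param fails_since_cluster Failed walk proposals since the last cluster
#'   analysis.
#' @param n_cluster_analyses Cluster analyses performed so far.
#' @return A list of class `search_state`.
#' @export
search_state <- function(nt = 0, fails_since_cluster = 0,
                         n_cluster_analyses = 0) {
  structure(list(nt = as.numeric(nt),
                 fails_since_cluster = as.numeric(fails_since_cluster),
                 n_cluster_analyses = as.integer(n_cluster_analyses)),
            class = "search_state")
}

#' Find a replacement live point
#'
#' Orchestrates the full search: a lawn-mower walk from a random live point
#' (using the global step scale, or the scale of the start's cluster when
#' labels exist); at every `Nt`-th consecutive failure one of the two
#' fallback strategies is chosen with a fair coin; a successful fallback
#' candidate clears the failure counter and becomes the new walk start
#' (remaining budget), a failed one restarts the walk from a fresh random
#' live point with the counter preserved; once `Nt * NNt` consecutive
#' failures accumulate, mean-shift clustering of the live set is triggered,
#' points are relabelled, and the walk restarts with the per-cluster scale.
#' New points inherit the cluster label of their walk start.
#'
#' @param live Matrix of live points (rows).
#' @param lnL Log-likelihood of each live point.
#' @param lnL_threshold Hard constraint the new point must satisfy.
#' @param model,data Likelihood specification.
#' @param space [param_space] bounds.
#' @param config [ns_config].
#' @param state [search_state], carried across calls.
#' @param labels Optional integer cluster labels per live point.
#' @param exclude Optional live index ineligible as walk start (the point
#'   being replaced).
#' @return List with the accepted point (`a`, `lnL`, `cluster_label`,
#'   `sigma_used`, `start_index`), the updated `state`, the `events` code
#'   trace (1 escalation, 2/3 barycenter fallback success/failure, 4/5
#'   coordinate-mix success/failure, 6 cluster analysis, 7 restart), and
#'   possibly updated `labels`.
#' @export
find_new_live_point <- function(live, lnL, lnL_threshold, model, data = NULL,
                                space, config = ns_config(K = nrow(live)),
                                state = search_state(), labels = NULL,
                                exclude = NA) {
  stopifnot_space(space)
  live <- as.matrix(live)
  spec <- ns_likelihood(model, data)
  if (is.null(labels)) labels <- integer(0)
  res <- find_new_live_point_cpp(live, as.numeric(lnL),
                                 as.integer(labels), lnL_threshold,
                                 space$lower, space$upper, spec,
                                 unclass(config), unclass(state),
                                 if (is.na(exclude)) -1L
                                 else as.integer(exclude) - 1L)
  if (res$error == 2)
    stop("non-convergence: cluster-analysis cap reached during search")
  if (res$error == 3)
    stop("non-convergence: search failure cap reached")
  st <- search_state(res$state$nt, res$state$fails_since_cluster,
                     res$state$n_cluster_analyses)
  list(a = res$a, lnL = res$lnL, cluster_label = res$cluster_label,
       sigma_used = res$sigma_used, start_index = res$start_index,
       state = st, events = res$events,
       labels = if (res$labels_active) res$labels else NULL)
}
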