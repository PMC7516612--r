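#' Fit a spectral model by nested sampling
#'
#' The main entry point: runs `config$runs` independent nested-sampling runs
#' (each from a fresh set of starting live points), pools their weighted
#' posterior samples, and reports the Bayesian evidence with its run-to-run
#' uncertainty, `lnE +/- delta(lnE)`, together with the information gain,
#' Bayesian complexity, and per-parameter posterior summaries. Evidence
#' values of two fits are compared through [log_bayes_factor()].
#'
#' @param model An [ns_model] (built-in family, custom prediction function,
#'   or direct log-likelihood).
#' @param data A [spectrum_data], or `NULL` for direct-loglik models.
#' @param space A [param_space] with the uniform box prior.
#' @param config An [ns_config]; `config$runs` controls the number of
#'   repeats.
#' @param seed Optional master seed; per-run sub-seeds are derived from it,
#'   so a fit is fully reproducible from `(config, seed)`.
#' @return An object of class `ns_fit`. Methods: `print`, `summary`, `coef`
#'   (posterior means), `vcov` (weighted posterior covariance), `predict`,
#'   `residuals`, `simulate`, `plot`, `logLik`.
#' @examples
#' \donttest{
#' sp <- four_peaks_spec(n_channels = 60, positions = c(20, 40),
#'                       areas = c(150, 200))
#' d <- gen_peak_spectrum(sp)
#' fit <- ns_fit(ns_model("gauss_peaks", npeaks = 2), d,
#'               benchmark_space(sp),
#'               ns_config(K = 200, runs = 2, max_steps = 20000), seed = 1)
#' print(fit)
#' }
#' @export
ns_fit <- function(model, data = NULL, space, config = ns_config(),
                   seed = NULL) {
  stopifnot_space(space)
  validate_ns_config(config, model, space)
  if (!is.null(seed)) set.seed(seed)
  R <- config$runs
  sub_seeds <- sample.int(.Machine$integer.max, R)
  runs <- vector("list", R)
  for (r in seq_len(R)) runs[[r]] <- ns_run(model, data, space, config,
                                            seed = sub_seeds[r])
  lnE_r <- vapply(runs, function(z) z$lnE, numeric(1))
  unc <- if (R >= 2) multi_run_uncertainty(lnE_r)
         else suppressWarnings(multi_run_uncertainty(lnE_r))
  # pooled posterior: per-run normalized weights, equal run weight
  samples <- do.call(rbind, lapply(runs, function(z) z$samples))
  ln_w <- unlist(lapply(runs, function(z) z$ln_w - z$lnE - log(R)))
  lnL <- unlist(lapply(runs, function(z) z$lnL))
  best_r <- which.max(vapply(runs, function(z) z$lnL_max, numeric(1)))
  out <- list(
    lnE = unc$lnE, delta_lnE = unc$delta_lnE, lnE_runs = lnE_r,
    H = mean(vapply(runs, function(z) z$H, numeric(1))),
    C_b = mean(vapply(runs, function(z) z$C_b, numeric(1))),
    best_fit = runs[[best_r]]$best_fit,
    lnL_max = runs[[best_r]]$lnL_max,
    summaries = posterior_summaries(samples, ln_w),
    samples = samples, ln_w = ln_w, lnL = lnL,
    runs = runs, seed = seed, sub_seeds = sub_seeds,
    model = model, space = space, config = config, data = data)
  class(out) <- "ns_fit"
  out
}

#' @export
print.ns_fit <- function(x, ...) {
  cat(sprintf("Nested-sampling fit of model '%s' (J = %d)\n",
              x$model$name, x$space$J))
  if (is.na(x$delta_lnE))
    cat(sprintf("  lnE = %.4f  (single run; no uncertainty)\n", x$lnE))
  else
    cat(sprintf("  lnE = %.4f +/- %.4f  (%d runs)\n", x$lnE, x$delta_lnE,
                length(x$lnE_runs)))
  cat(sprintf("  information gain H = %.3f nats, complexity C_b = %.2f\n",
              x$H, x$C_b))
  steps <- sum(vapply(x$runs, function(z) z$steps, numeric(1)))
  ncl <- sum(vapply(x$runs, function(z) z$counters$n_cluster_analyses,
                    numeric(1)))
  cat(sprintf("  %d total steps, %d cluster analyses\n", steps, ncl))
  invisible(x)
}

#' @export
summary.ns_fit <- function(object, ...) {
  structure(list(fit = object, table = object$summaries),
            class = "summary.ns_fit")
}

#' @export
print.summary.ns_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nPosterior summaries (weighted; central credible intervals):\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ns_fit <- function(object, ...) {
  stats::setNames(object$summaries$mean, object$summaries$parameter)
}

#' @export
vcov.ns_fit <- function(object, ...) {
  p <- exp(object$ln_w - logsumexp(object$ln_w))
  X <- object$samples
  mu <- colSums(X * p)
  Xc <- sweep(X, 2, mu)
  V <- crossprod(Xc * p, Xc)
  dimnames(V) <- list(object$space$names, object$space$names)
  V
}

#' @export
logLik.ns_fit <- function(object, ...) {
  structure(object$lnL_max, df = object$space$J, class = "logLik")
}

#' @param object An `ns_fit`.
#' @param newdata Optional numeric vector of bin centers; defaults to the
#'   fitted dataset's.
#' @param type `"mean"` evaluates the model at the posterior mean, `"best"`
#'   at the best sampled point.
#' @rdname ns_fit
#' @export
predict.ns_fit <- function(object, newdata = NULL, type = c("mean", "best"),
                           ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data$x else as.numeric(newdata)
  if (is.null(x)) stop("no data attached; supply 'newdata'")
  a <- if (type == "mean") coef(object) else object$best_fit
  predict(object$model, x, a)
}

#' @export
residuals.ns_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  d <- object$data
  if (is.null(d)) stop("no data attached to this fit")
  f <- predict(object)
  if (d$mode == "poisson") {
    r <- d$counts - f
    if (type == "pearson") r <- r / sqrt(pmax(f, .Machine$double.eps))
  } else {
    r <- d$y - f
    if (type == "pearson") r <- r / d$sigma
  }
  r
}

#' @export
simulate.ns_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  if (is.null(d)) stop("no data attached to this fit")
  p <- exp(object$ln_w - logsumexp(object$ln_w))
  idx <- sample.int(nrow(object$samples), nsim, replace = TRUE, prob = p)
  out <- lapply(idx, function(i) {
    f <- predict(object$model, d$x, object$samples[i, ])
    if (d$mode == "poisson")
      spectrum_data(d$x, counts = stats::rpois(length(f), f))
    else
      spectrum_data(d$x, y = stats::rnorm(length(f), f, d$sigma),
                    sigma = d$sigma)
  })
  if (nsim == 1) out[[1]] else out
}

#' @param x An `ns_fit`.
#' @param which Plot type: `"fit"` (data with the posterior-mean model
#'   curve), `"trace"` (dead-point likelihood against the log prior volume),
#'   or `"posterior"` (weighted histogram of one parameter).
#' @param parameter Parameter name or index for `which = "posterior"`.
#' @rdname ns_fit
#' @export
plot.ns_fit <- function(x, which = c("fit", "trace", "posterior"),
                        parameter = 1, ...) {
  which <- match.arg(which)
  if (which == "fit") {
    d <- x$data
    if (is.null(d)) stop("no data attached to this fit")
    yy <- if (d$mode == "poisson") d$counts else d$y
    graphics::plot(d$x, yy, type = "h", col = "grey50",
                   xlab = "channel", ylab = "counts",
                   main = sprintf("model '%s'", x$model$name), ...)
    graphics::lines(d$x, predict(x), col = "firebrick", lwd = 2)
  } else if (which == "trace") {
    r <- x$runs[[1]]
    graphics::plot(r$dead$lnX, r$dead$lnL, type = "l",
                   xlab = "ln X (log prior volume)", ylab = "ln L",
                   main = "nested-sampling exploration", ...)
  } else {
    j <- if (is.character(parameter)) match(parameter, x$space$names)
         else as.integer(parameter)
    if (is.na(j)) stop("unknown parameter")
    p <- exp(x$ln_w - logsumexp(x$ln_w))
    h <- weighted_hist(x$samples[, j], p, nbins = 60)
    graphics::plot(h$mids, h$density, type = "s",
                   xlab = x$space$names[j], ylab = "posterior density",
                   main = sprintf("posterior of %s", x$space$names[j]), ...)
  }
  invisible(x)
}

weighted_hist <- function(x, w, nbins = 60, from = min(x), to = max(x)) {
  if (from == to) { from <- from - 0.5; to <- to + 0.5 }
  br <- seq(from, to, length.out = nbins + 1)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- vapply(seq_len(nbins), function(b) sum(w[idx == b]), numeric(1))
  dens <- dens / sum(w) / diff(br)
  list(breaks = br, mids = (br[-1] + br[-(nbins + 1)]) / 2, density = dens)
}
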