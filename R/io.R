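# Run orchestration and result files. Every output is plain text and
# timestamp-free, so a run is byte-reproducible from (config, seed).

#' Write the posterior sample file
#'
#' One row per record (dead points first, then the final live points) with
#' columns `ln_w`, `lnL` and the parameters, at 17 significant digits so a
#' read-back is bit-exact.
#'
#' @param run An `ns_run` or `ns_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(run, path) {
  if (!inherits(run, c("ns_run", "ns_fit"))) stop("not a run or fit object")
  if (!length(run$ln_w)) stop("empty chain: nothing to write")
  m <- cbind(ln_w = run$ln_w, lnL = run$lnL, run$samples)
  df <- as.data.frame(m)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a posterior sample file
#'
#' @param path File written by [write_posterior()].
#' @return A list with `ln_w`, `lnL` and `samples`.
#' @export
read_posterior <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  list(ln_w = df$ln_w, lnL = df$lnL,
       samples = as.matrix(df[, -(1:2), drop = FALSE]))
}

#' Read a run configuration file
#'
#' YAML schema with blocks `data` (file path), `model` (name, optionally
#' `npeaks` or a name-and-arity string such as `gauss_peaks:4`), `bounds`
#' (`names`, `lower`, `upper`) and `sampler` (any [ns_config] field), plus
#' optional top-level `seed` and `outdir`.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with `model`, `data`, `space`,
#'   `config`, `seed`, `outdir`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model) || is.null(raw$bounds))
    stop("config error: 'model' and 'bounds' blocks are required")
  model <- ns_model(raw$model$name,
                    npeaks = raw$model$npeaks)
  data <- NULL
  if (!is.null(raw$data)) {
    if (!file.exists(raw$data))
      stop("config error: data file not found: ", raw$data)
    data <- read_spectrum(raw$data)
  }
  space <- param_space(raw$bounds$names, raw$bounds$lower, raw$bounds$upper)
  if (space$J != model$J)
    stop(sprintf("config error: %d bounds for a model with %d parameters",
                 space$J, model$J))
  config <- do.call(ns_config, if (is.null(raw$sampler)) list()
                               else raw$sampler)
  structure(list(model = model, data = data, space = space, config = config,
                 seed = raw$seed, outdir = raw$outdir),
            class = "run_config")
}

#' Run a configured experiment and write its artifacts
#'
#' Executes the repeated nested-sampling analysis described by a
#' [read_run_config()] object (or an equivalent list) and writes, under
#' `outdir`: `summary.txt` (human-readable), `results.json` (the same
#' numbers as machine-readable key/value records, including the counter
#' block), one posterior sample file per run, an evolution trace per run
#' (step, lnL, lnX, one column per parameter), and optional weighted 2D
#' histogram tables for requested parameter pairs.
#'
#' @param rc A `run_config`, or arguments `model`, `data`, `space`,
#'   `config` given directly.
#' @param outdir Output directory (created if missing); overrides
#'   `rc$outdir`.
#' @param seed Master seed; overrides `rc$seed`.
#' @param pairs Optional list of length-2 character vectors of parameter
#'   names for joint-posterior histogram tables.
#' @param nbins Number of histogram bins per axis.
#' @return The [ns_fit] object, invisibly.
#' @export
run_experiment <- function(rc, outdir = rc$outdir, seed = rc$seed,
                           pairs = NULL, nbins = 40) {
  if (!inherits(rc, "run_config")) stop("'rc' must be a run_config")
  if (is.null(outdir)) stop("config error: no output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fit <- ns_fit(rc$model, rc$data, rc$space, rc$config, seed = seed)
  write_summary(fit, file.path(outdir, "summary.txt"))
  jsonlite::write_json(machine_summary(fit),
                       file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (r in seq_along(fit$runs)) {
    run <- fit$runs[[r]]
    write_posterior(run, file.path(outdir, sprintf("posterior_run%02d.dat", r)))
    tr <- cbind(step = seq_len(run$steps), lnL = run$dead$lnL,
                lnX = run$dead$lnX, run$dead$a)
    colnames(tr) <- c("step", "lnL", "lnX", rc$space$names)
    utils::write.table(format(as.data.frame(tr), digits = 10, trim = TRUE),
                       file.path(outdir, sprintf("trace_run%02d.dat", r)),
                       quote = FALSE, row.names = FALSE)
  }
  for (pr in pairs) {
    h <- joint_hist(fit, pr[1], pr[2], nbins = nbins)
    utils::write.table(h, file.path(outdir,
                                    sprintf("hist2d_%s_%s.dat", pr[1], pr[2])),
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fit)
}

# weighted 2D histogram table (long format: x, y, weight)
joint_hist <- function(fit, px, py, nbins = 40) {
  jx <- match(px, fit$space$names); jy <- match(py, fit$space$names)
  if (is.na(jx) || is.na(jy)) stop("unknown parameter pair")
  p <- exp(fit$ln_w - logsumexp(fit$ln_w))
  x <- fit$samples[, jx]; y <- fit$samples[, jy]
  bx <- seq(min(x), max(x), length.out = nbins + 1)
  by <- seq(min(y), max(y), length.out = nbins + 1)
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  w <- tapply(p, list(factor(ix, 1:nbins), factor(iy, 1:nbins)), sum,
              default = 0)
  data.frame(x = rep((bx[-1] + bx[-(nbins + 1)]) / 2, nbins),
             y = rep((by[-1] + by[-(nbins + 1)]) / 2, each = nbins),
             weight = as.vector(w))
}

machine_summary <- function(fit) {
  ctr <- lapply(fit$runs, function(z) z$counters)
  list(
    model = fit$model$name,
    lnE = fit$lnE,
    delta_lnE = fit$delta_lnE,
    lnE_runs = fit$lnE_runs,
    H = fit$H,
    bayesian_complexity = fit$C_b,
    lnL_max = fit$lnL_max,
    best_fit = as.list(stats::setNames(as.numeric(fit$best_fit),
                                       fit$space$names)),
    posterior = fit$summaries,
    counters = list(
      steps = vapply(fit$runs, function(z) z$steps, numeric(1)),
      likelihood_evals = vapply(fit$runs, function(z) z$n_likelihood_evals,
                                numeric(1)),
      total_tries = vapply(ctr, function(z) z$total_proposals, numeric(1)),
      total_fails = vapply(ctr, function(z) z$total_fails, numeric(1)),
      fallback_barycenter = vapply(ctr, function(z) z$n_fallback_bary,
                                   numeric(1)),
      fallback_coordinate_mix = vapply(ctr, function(z) z$n_fallback_mix,
                                       numeric(1)),
      cluster_analyses = vapply(ctr, function(z) z$n_cluster_analyses,
                                numeric(1))),
    cluster_history = lapply(fit$runs, function(z)
      as.list(z$cluster_history)),
    seed = fit$seed)
}

#' Write the human-readable results summary
#'
#' Evidence with uncertainty, information gain, complexity, best-fit point,
#' per-parameter posterior summaries and the search counter block.
#'
#' @param fit An [ns_fit].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# nested-sampling results summary")
  w("model: %s", fit$model$name)
  w("runs: %d", length(fit$runs))
  w("lnE: %.10g", fit$lnE)
  w("delta_lnE: %.10g", fit$delta_lnE)
  w("H: %.10g", fit$H)
  w("bayesian_complexity: %.10g", fit$C_b)
  w("lnL_max: %.10g", fit$lnL_max)
  w("")
  w("# best-fit parameters")
  for (j in seq_along(fit$best_fit))
    w("%s: %.10g", fit$space$names[j], fit$best_fit[j])
  w("")
  w("# posterior summaries")
  utils::write.table(format(fit$summaries, digits = 6, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE)
  w("")
  w("# counters")
  w("steps: %s", paste(vapply(fit$runs, function(z) z$steps, numeric(1)),
                       collapse = " "))
  w("total_tries: %s",
    paste(vapply(fit$runs, function(z) z$counters$total_proposals,
                 numeric(1)), collapse = " "))
  w("fallback_invocations: %s",
    paste(vapply(fit$runs, function(z)
      z$counters$n_fallback_bary + z$counters$n_fallback_mix, numeric(1)),
      collapse = " "))
  w("cluster_analyses: %s",
    paste(vapply(fit$runs, function(z) z$counters$n_cluster_analyses,
                 numeric(1)), collapse = " "))
  invisible(path)
}
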