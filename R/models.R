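#' Model families for binned spectra
#'
#' A model maps a parameter vector `a` to the expected value in every bin.
#' Two families cover the benchmark problems:
#'
#' * `"gauss_peaks"` — `P` Gaussian peaks of shared width on a flat
#'   background. Parameters, in order: `bg` (background per bin, >= 0),
#'   `w` (shared width, > 0), the `P` peak positions `x0_p`, and the `P`
#'   peak *areas* `A_p` (>= 0), so `J = 2 + 2P`. Parameterizing amplitude by
#'   area makes the integral of the peaks equal `sum(A_p)` exactly and
#'   decouples amplitude from width:
#'   `f(x) = bg + sum_p A_p / (w sqrt(2 pi)) exp(-(x - x0_p)^2 / (2 w^2))`.
#'   Because the peaks share a width, the likelihood is invariant under any
#'   permutation of the peak index — `P!` exchangeable maxima.
#' * `"mod_decay"` — exponential decay with sinusoidal modulation.
#'   Parameters: `C` (normalization, >= 0), `tau` (lifetime, > 0), `amod`
#'   (relative modulation amplitude, in `[0, 1)`), `omega` (pulsation, > 0),
#'   `phi` (phase, in `[0, 2 pi)`), `bg` (flat background, >= 0):
#'   `f(t) = C exp(-t / tau) (1 + amod cos(omega t + phi)) + bg`.
#'
#' Custom models are supported either through a `predict` function
#' `function(x, a)` returning expected values (combined with the dataset's
#' counting statistic), or through a direct log-likelihood `loglik`
#' `function(a)` for problems that are not spectra at all (toy integrands,
#' rigged test likelihoods).
#'
#' @param name One of `"gauss_peaks"`, `"mod_decay"`, `"custom"`. Models can
#'   also be addressed by the name-and-arity string used in run-config files,
#'   e.g. `"gauss_peaks:4"`.
#' @param npeaks Number of peaks for `"gauss_peaks"`.
#' @param predict Custom prediction function `function(x, a)`.
#' @param loglik Custom direct log-likelihood `function(a)`.
#' @param J Number of parameters (required for custom models).
#' @return An object of class `ns_model`.
#' @examples
#' m <- ns_model("gauss_peaks", npeaks = 1)
#' predict(m, x = 1:10, a = c(0, 2, 5, 30))
#' @export
ns_model <- function(name = "custom", npeaks = NULL, predict = NULL,
                     loglik = NULL, J = NULL) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    npeaks <- as.integer(parts[2])
  }
  if (name == "gauss_peaks") {
    if (is.null(npeaks) || npeaks < 1) stop("'npeaks' must be >= 1")
    npeaks <- as.integer(npeaks)
    obj <- list(name = name, model_id = 0L, npeaks = npeaks,
                J = 2L + 2L * npeaks,
                par_names = c("bg", "w", paste0("x0_", seq_len(npeaks)),
                              paste0("A_", seq_len(npeaks))))
  } else if (name == "mod_decay") {
    obj <- list(name = name, model_id = 1L, npeaks = 0L, J = 6L,
                par_names = c("C", "tau", "amod", "omega", "phi", "bg"))
  } else {
    if (is.null(predict) && is.null(loglik))
      stop("custom models need 'predict' or 'loglik'")
    if (is.null(J)) stop("custom models need 'J'")
    obj <- list(name = name, model_id = -1L, npeaks = 0L, J = as.integer(J),
                predict = predict, loglik = loglik,
                par_names = paste0("a", seq_len(J)))
  }
  structure(obj, class = "ns_model")
}

#' @export
print.ns_model <- function(x, ...) {
  cat(sprintf("Model '%s' (J = %d): %s\n", x$name, x$J,
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

#' @param object An `ns_model`.
#' @param x Bin centers at which to evaluate.
#' @param a Parameter vector.
#' @param ... Unused.
#' @rdname ns_model
#' @export
predict.ns_model <- function(object, x, a, ...) {
  a <- as.numeric(a)
  if (length(a) != object$J)
    stop(sprintf("expected %d parameters, got %d", object$J, length(a)))
  if (object$model_id >= 0L)
    return(predict_builtin_cpp(object$model_id, object$npeaks,
                               as.numeric(x), a))
  if (is.null(object$predict))
    stop("model has no prediction function (direct log-likelihood only)")
  object$predict(x, a)
}

#' Gaussian-peaks expected spectrum
#'
#' Direct evaluator for the shared-width multi-peak model; see [ns_model] for
#' the parameter layout `(bg, w, x0_1..P, A_1..P)`.
#'
#' @param x Channels.
#' @param a Parameter vector of length `2 + 2 P`.
#' @return Expected counts per bin.
#' @export
gauss_peaks_model <- function(x, a) {
  a <- as.numeric(a)
  P <- (length(a) - 2L) / 2L
  if (P < 1 || P != round(P)) stop("parameter vector length must be 2 + 2P")
  predict_builtin_cpp(0L, as.integer(P), as.numeric(x), a)
}

#' Modulated exponential-decay expected series
#'
#' Direct evaluator for the decay model; see [ns_model] for the parameter
#' layout `(C, tau, amod, omega, phi, bg)`.
#'
#' @param t Times.
#' @param a Parameter vector of length 6.
#' @return Expected counts per bin.
#' @export
modulated_decay_model <- function(t, a) {
  a <- as.numeric(a)
  if (length(a) != 6) stop("parameter vector must have length 6")
  predict_builtin_cpp(1L, 0L, as.numeric(t), a)
}

# Build the likelihood specification consumed by the compiled engine.
# kind 0: built-in model + statistic; 1: direct lnL callback; 2: predict
# callback + statistic.
ns_likelihood <- function(model, data) {
  if (!inherits(model, "ns_model")) stop("'model' must be an ns_model")
  if (!is.null(model$loglik)) {
    return(list(kind = 1L, fn = model$loglik, J = model$J))
  }
  if (is.null(data)) stop("data error: models without 'loglik' need data")
  if (!inherits(data, "spectrum_data")) stop("'data' must be a spectrum_data")
  stat <- if (data$mode == "poisson") 0L else 1L
  base <- list(stat = stat, x = data$x, J = model$J)
  if (stat == 0L) {
    base$counts <- data$counts
    base$lgamma_sum <- sum(lgamma(data$counts + 1))
  } else {
    base$y <- data$y
    base$sigma <- data$sigma
    base$gauss_norm <- sum(log(data$sigma * sqrt(2 * pi)))
  }
  if (model$model_id >= 0L) {
    c(list(kind = 0L, model_id = model$model_id, npeaks = model$npeaks), base)
  } else {
    xs <- data$x
    pf <- model$predict
    c(list(kind = 2L, fn = function(a) pf(xs, a)), base)
  }
}

#' Poisson log-likelihood of a model on counting data
#'
#' `lnL = sum_i [ n_i ln(lambda_i) - lambda_i - ln(n_i!) ]` with the
#' convention `0 ln 0 = 0`; a bin with zero predicted rate but observed
#' counts gives `-Inf` (the sampler rejects such points rather than raising).
#' The `ln(n_i!)` term is included so that `lnE` values are absolute and
#' comparable across models.
#'
#' @param model An [ns_model] with a prediction rule.
#' @param data Poisson-mode [spectrum_data].
#' @param a Parameter vector.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @examples
#' d <- spectrum_data(1, counts = 3)
#' m <- ns_model("flat", predict = function(x, a) rep(a[1], length(x)), J = 1)
#' poisson_loglike(m, d, 2.5)  # 3 log 2.5 - 2.5 - log 6
#' @export
poisson_loglike <- function(model, data, a) {
  if (data$mode != "poisson") stop("data error: dataset is not poisson-mode")
  eval_loglik_cpp(ns_likelihood(model, data), as.numeric(a))
}

#' Gaussian log-likelihood of a model on measured data
#'
#' `lnL = -1/2 sum_i ((y_i - f_i)/sigma_i)^2 - sum_i ln(sigma_i sqrt(2 pi))`.
#'
#' @inheritParams poisson_loglike
#' @param data Gaussian-mode [spectrum_data].
#' @return Scalar log-likelihood.
#' @export
gaussian_loglike <- function(model, data, a) {
  if (data$mode != "gaussian") stop("data error: dataset is not gaussian-mode")
  eval_loglik_cpp(ns_likelihood(model, data), as.numeric(a))
}
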