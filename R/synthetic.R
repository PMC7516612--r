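# Synthetic benchmark generators. These emulate the *statistical structure*
# of the two hard reference problems — a low-count spectrum of four
# identical-width Gaussian peaks on a flat background (whose likelihood has
# 4! = 24 permutation-degenerate maxima) and a Poisson-binned exponential
# decay with sinusoidal modulation (beat-degenerate in amplitude, pulsation
# and phase). They are synthetic stand-ins: the real spectra they mimic are
# not publicly deposited.

#' Four-peak benchmark specification
#'
#' Defaults describe a modest-statistics spectrum (about 3600 total counts
#' over 200 channels) with four well-separated identical-width peaks. Positions
#' and areas are chosen so that, after min-max normalization of a late-stage
#' live-point ensemble, every pair of permutation modes is farther apart
#' than the default mean-shift neighborhood radius `D = 0.6` — the condition
#' for the cluster recognition to resolve all `4! = 24` modes (see the
#' methods vignette for the separability computation).
#'
#' @param n_channels Number of unit-width channels, centers `1..n_channels`.
#' @param positions True peak positions.
#' @param areas True peak areas (expected counts per peak).
#' @param width Shared peak width.
#' @param bg Flat background per channel.
#' @return A list of class `benchmark_spec` (family `"four_peaks"`) holding
#'   the generating parameters and the true parameter vector in model order.
#' @export
four_peaks_spec <- function(n_channels = 200,
                            positions = c(25, 80, 135, 190),
                            areas = c(850, 300, 1300, 750),
                            width = 8, bg = 2) {
  if (length(positions) != length(areas)) stop("invalid spec: P mismatch")
  if (width <= 0 || bg < 0 || any(areas < 0)) stop("invalid spec")
  if (any(positions < 1) || any(positions > n_channels))
    stop("invalid spec: peaks outside the channel range")
  structure(list(family = "four_peaks", n_channels = as.integer(n_channels),
                 positions = positions, areas = areas, width = width, bg = bg,
                 npeaks = length(positions),
                 truth = c(bg, width, positions, areas)),
            class = "benchmark_spec")
}

#' Modulated-decay benchmark specification
#'
#' A decay curve binned in unit time steps with a sinusoidal modulation on
#' top of the exponential; the posterior in (amod, omega, phi) is multimodal
#' through phase/pulsation beats. Defaults give a low-statistics series of
#' about 600 counts.
#'
#' @param n_bins Number of unit-width time bins, centers `0.5..n_bins-0.5`.
#' @param C Decay amplitude (expected counts per bin at t = 0).
#' @param tau Lifetime.
#' @param amod Relative modulation amplitude in `[0, 1)`.
#' @param omega Modulation pulsation.
#' @param phi Modulation phase.
#' @param bg Flat background per bin.
#' @return A `benchmark_spec` of family `"mod_decay"`.
#' @export
mod_decay_spec <- function(n_bins = 100, C = 40, tau = 15, amod = 0.25,
                           omega = 1.0, phi = 1.0, bg = 0.5) {
  if (tau <= 0 || C < 0 || amod < 0 || amod >= 1 || omega <= 0 || bg < 0)
    stop("invalid spec")
  structure(list(family = "mod_decay", n_bins = as.integer(n_bins),
                 C = C, tau = tau, amod = amod, omega = omega, phi = phi,
                 bg = bg, truth = c(C, tau, amod, omega, phi, bg)),
            class = "benchmark_spec")
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat(sprintf("Benchmark spec '%s'\n", x$family))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

benchmark_x <- function(spec) {
  if (spec$family == "four_peaks") seq_len(spec$n_channels)
  else seq_len(spec$n_bins) - 0.5
}

#' Expected (noise-free) benchmark spectrum
#'
#' @param spec A `benchmark_spec`.
#' @return Numeric vector of expected counts per bin (midpoint rule for the
#'   decay family, whose bins are narrow).
#' @export
benchmark_expectation <- function(spec) {
  x <- benchmark_x(spec)
  if (spec$family == "four_peaks") gauss_peaks_model(x, spec$truth)
  else modulated_decay_model(x, spec$truth)
}

#' Generate a four-peak Poisson spectrum
#'
#' `counts_i ~ Poisson(f(x_i; truth))` with `f` the shared-width Gaussian
#' peaks model.
#'
#' @param spec A `benchmark_spec` from [four_peaks_spec()].
#' @param seed Optional seed for reproducible datasets.
#' @return A Poisson-mode [spectrum_data].
#' @export
gen_peak_spectrum <- function(spec, seed = NULL) {
  if (!inherits(spec, "benchmark_spec") || spec$family != "four_peaks")
    stop("invalid spec: expected a four_peaks benchmark_spec")
  if (!is.null(seed)) set.seed(seed)
  lam <- benchmark_expectation(spec)
  spectrum_data(benchmark_x(spec), counts = stats::rpois(length(lam), lam))
}

#' Generate a modulated-decay Poisson series
#'
#' Binned counts `~ Poisson(f(t_i) * dt)` with unit bins and the midpoint
#' approximation of the bin integral.
#'
#' @param spec A `benchmark_spec` from [mod_decay_spec()].
#' @inheritParams gen_peak_spectrum
#' @return A Poisson-mode [spectrum_data].
#' @export
gen_decay_series <- function(spec, seed = NULL) {
  if (!inherits(spec, "benchmark_spec") || spec$family != "mod_decay")
    stop("invalid spec: expected a mod_decay benchmark_spec")
  if (!is.null(seed)) set.seed(seed)
  lam <- benchmark_expectation(spec)
  spectrum_data(benchmark_x(spec), counts = stats::rpois(length(lam), lam))
}

#' Prior box used with a benchmark
#'
#' Wide uniform bounds enclosing the generating parameters; for the peaks
#' family every position (and every area) shares the same box, which is what
#' makes the permutation modes exactly degenerate.
#'
#' @param spec A `benchmark_spec`.
#' @return A [param_space].
#' @export
benchmark_space <- function(spec) {
  if (spec$family == "four_peaks") {
    P <- spec$npeaks
    param_space(
      c("bg", "w", paste0("x0_", seq_len(P)), paste0("A_", seq_len(P))),
      lower = c(0, spec$width / 4, rep(1, P), rep(0, P)),
      upper = c(max(5, 5 * spec$bg), 2.5 * spec$width,
                rep(spec$n_channels, P), rep(1.3 * max(spec$areas), P)))
  } else {
    param_space(c("C", "tau", "amod", "omega", "phi", "bg"),
                lower = c(0, 1, 0, 0.05, 0, 0),
                upper = c(200, 60, 0.999, 5, 2 * pi, 5))
  }
}

#' Model matching a benchmark family
#'
#' @param spec A `benchmark_spec`.
#' @return An [ns_model].
#' @export
benchmark_model <- function(spec) {
  if (spec$family == "four_peaks") ns_model("gauss_peaks", npeaks = spec$npeaks)
  else ns_model("mod_decay")
}
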