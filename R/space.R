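#' Parameter space with uniform box prior
#'
#' Defines the names and box bounds of the J model parameters. The prior is
#' uniform on the box; nested sampling draws the initial live points from it
#' and the evidence is normalized to its volume, so `lnE` values are absolute
#' and directly comparable between models.
#'
#' @param names Character vector of parameter identifiers.
#' @param lower,upper Numeric vectors of bounds, one per parameter, with
#'   `lower < upper` componentwise.
#' @return An object of class `param_space` with elements `names`, `lower`,
#'   `upper` and `J` (the number of parameters).
#' @examples
#' param_space(c("bg", "w"), lower = c(0, 1), upper = c(5, 10))
#' @export
param_space <- function(names, lower, upper) {
  names <- as.character(names)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  J <- length(names)
  if (J < 1) stop("at least one parameter is required")
  if (length(lower) != J || length(upper) != J)
    stop("'names', 'lower' and 'upper' must have the same length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper))
    stop("degenerate bounds: 'lower' must be strictly below 'upper'")
  structure(list(names = names, lower = lower, upper = upper, J = J),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat("Parameter space (uniform box prior), J =", x$J, "\n")
  print(data.frame(parameter = x$names, lower = x$lower, upper = x$upper),
        row.names = FALSE)
  invisible(x)
}

ln_prior_volume <- function(space) sum(log(space$upper - space$lower))

stopifnot_space <- function(space) {
  if (!inherits(space, "param_space")) stop("'space' must be a param_space")
  invisible(space)
}
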