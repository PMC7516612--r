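# Shared toy models and oracles used across the suite.

# direct-loglik toy models (1-D unless noted)
const_model <- function(value = 0) {
  ns_model("const", loglik = function(a) value, J = 1)
}

gauss_toy_model <- function() {
  ns_model("gauss_toy", loglik = function(a) -0.5 * a[1]^2, J = 1)
}
# analytic evidence of the Gaussian toy on U(-10, 10)
GAUSS_TOY_LNE <- log(sqrt(2 * pi) / 20)

bimodal_model <- function() {
  ns_model("bimodal", loglik = function(a) {
    x <- a[1]
    e1 <- -(x - 5)^2 / 0.02
    e2 <- -(x + 5)^2 / 0.02
    m <- max(e1, e2)
    m + log(exp(e1 - m) + exp(e2 - m))
  }, J = 1)
}
# two Gaussian modes of sd 0.1 on U(-10, 10)
BIMODAL_LNE <- log(2 * 0.1 * sqrt(2 * pi) / 20)

unit_space <- function(lo = -10, hi = 10) param_space("x", lo, hi)

# numeric-quadrature oracle for H = int p ln(p / prior) over a 1-D box prior
quad_H <- function(lnf, lo, hi, n = 200001) {
  x <- seq(lo, hi, length.out = n)
  lf <- vapply(x, function(v) lnf(v), numeric(1))
  w <- rep(1, n); w[c(1, n)] <- 0.5
  dx <- (hi - lo) / (n - 1)
  E <- sum(w * exp(lf)) * dx / (hi - lo)
  p <- exp(lf) / (hi - lo) / E            # posterior density
  keep <- p > 0
  sum((w * p * (lf - log(E)))[keep]) * dx - 0  # int p ln(L/E); prior=1/(hi-lo)
}

# brute-force reference mean shift (matrix algebra, independent of the
# compiled loop); mirrors the documented update rule exactly
reference_mean_shift <- function(X, kernel = "gaussian", D = 0.6, ell = 0.2,
                                 tol = 1e-4, max_iter = 100,
                                 merge_dist = 0.05, blurring = FALSE) {
  X <- as.matrix(X)
  M <- X
  for (it in seq_len(max_iter)) {
    data <- if (blurring) M else X
    d2 <- outer(rowSums(M^2), rep(1, nrow(data))) +
      outer(rep(1, nrow(M)), rowSums(data^2)) - 2 * M %*% t(data)
    d <- sqrt(pmax(d2, 0))
    W <- if (kernel == "flat") (d < D) * 1 else exp(-d / ell) * (d < D)
    rs <- rowSums(W)
    Mnew <- (W %*% data) / ifelse(rs > 0, rs, 1)
    Mnew[rs == 0, ] <- M[rs == 0, ]
    disp <- sqrt(rowSums((Mnew - M)^2))
    M <- Mnew
    if (max(disp) < tol) break
  }
  # single-linkage merge at merge_dist
  K <- nrow(M)
  lab <- seq_len(K)
  dd <- as.matrix(dist(M))
  repeat {
    changed <- FALSE
    for (i in seq_len(K)) {
      nb <- which(dd[i, ] < merge_dist)
      tgt <- min(lab[nb])
      if (any(lab[nb] != tgt)) { lab[lab %in% lab[nb]] <- tgt; changed <- TRUE }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# canonical form of a partition for exact comparison
canon_partition <- function(labels) match(labels, unique(labels))

expect_same_partition <- function(a, b) {
  expect_identical(canon_partition(a), canon_partition(b))
}
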