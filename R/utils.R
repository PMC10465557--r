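## Internal numerical and bookkeeping utilities shared across modules.

#' Derive a deterministic sub-seed from a master seed
#'
#' All stochastic stages derive their own seed from one master seed plus a
#' fixed stage offset, so that pipeline stages can be re-run in isolation and
#' still reproduce the end-to-end run. Results are kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param offset fixed non-negative integer offset identifying the stage.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1103L + as.numeric(offset) * 12289) %% 2147483629)
}

#' Multivariate normal draw via Cholesky factorisation
#' @param n number of draws.
#' @param mu mean vector.
#' @param Sigma covariance matrix (positive definite after jitter).
#' @return n x length(mu) matrix.
#' @keywords internal
rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  L <- chol(Sigma + diag(1e-10 * mean(diag(Sigma)) + 1e-12, p))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2, mu, "+")
}

## Exponential-covariance Gaussian random field evaluated at coords (n x 2).
## range is the e-folding distance, sd the marginal standard deviation.
sim_gp_field <- function(coords, range, sd) {
  D <- as.matrix(stats::dist(coords))
  drop(rmvnorm_chol(1, rep(0, nrow(coords)), sd^2 * exp(-D / range)))
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given probability mass, computed from the
#' sorted draws (Chen-Shao algorithm).
#'
#' @param x numeric vector of draws.
#' @param prob mass of the interval (default 0.95).
#' @return named vector c(lower, upper).
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) return(c(lower = min(x), upper = max(x)))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

## Split-chain potential scale reduction factor (R-hat). draws: iterations x chains.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

## Effective sample size by the initial-positive-sequence autocorrelation
## estimator, pooled over chains.
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(n * m)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    x <- draws[, ch] - mean(draws[, ch])
    if (mean(x^2) <= 0) next
    acf_vals <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                           demean = FALSE)$acf[-1]
    s <- 0
    k <- 1
    while (k < length(acf_vals)) {
      pair <- acf_vals[k] + ifelse(k + 1 <= length(acf_vals), acf_vals[k + 1], 0)
      if (is.na(pair) || pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    rho_sum <- rho_sum + s
  }
  rho <- rho_sum / m
  max(1, n * m / (1 + 2 * rho))
}

## Univariate slice sampler step (Neal 2003, stepping-out), used for scale
## parameters sampled on the log scale.
slice_step <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point")
  y <- f0 + log(stats::runif(1))
  L <- x0 - stats::runif(1) * w
  R <- L + w
  k <- max_steps
  while (k > 0 && logf(L) > y) { L <- L - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## Structured one-line stage log used by the pipeline.
log_stage <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  msg <- paste(sprintf("%s", c(...)), collapse = " ")
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
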