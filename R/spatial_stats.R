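## Spatially corrected correlation tests: Dutilleul's (1993) modified t-test
## with a distance-class estimate of the effective sample size, Moran's I
## with a permutation null, and plain correlation utilities.

## Spatial covariance matrix estimate of one variable from distance classes:
## Sigma[i,j] (i != j) is the mean cross-product of centred values over all
## pairs in the distance class containing d_ij; the diagonal is the sample
## variance (1/n).
class_cov_matrix <- function(z, class_idx, n_classes, n) {
  zc <- z - mean(z)
  v <- sum(zc^2) / n
  prod_upper <- tcrossprod(zc)[upper.tri(diag(n))]
  cov_k <- vapply(seq_len(n_classes), function(k) {
    sel <- class_idx == k
    if (!any(sel)) 0 else mean(prod_upper[sel])
  }, numeric(1))
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- cov_k[class_idx]
  S <- S + t(S)
  diag(S) <- v
  S
}

#' Dutilleul's modified t-test of correlation between spatial variables
#'
#' Tests the Pearson correlation of two georeferenced variables while
#' correcting the degrees of freedom for spatial autocorrelation in both.
#' The spatial covariance of each variable is estimated over a set of
#' distance classes; with `B` the centring matrix, the effective sample size
#' is `M = 1 + tr(B Sx) tr(B Sy) / tr(B Sx B Sy)`, and the statistic
#' `F = (M - 2) r^2 / (1 - r^2)` is referred to `F(1, M - 2)` with
#' fractional degrees of freedom `M - 2`. With no autocorrelation `M`
#' approaches `n` and the classical Pearson test is recovered.
#'
#' @param x,y numeric vectors (>= 10 points, non-constant).
#' @param coords matrix/data.frame of projected coordinates (metres), one
#'   row per point.
#' @param n_classes number of distance classes (default 13, equal-count
#'   breaks; reduced with a warning when there are too few pairs).
#' @return object of class `modified_ttest`: list(r, F, dof, p, ess, n).
#' @references Dutilleul, P. (1993) Biometrics 49, 305-314.
#' @export
modified_ttest <- function(x, y, coords, n_classes = 13) {
  coords <- as.matrix(coords)
  n <- length(x)
  if (length(y) != n || nrow(coords) != n) stop("x, y, coords lengths differ")
  if (n < 10) stop("need at least 10 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant variable")

  d <- as.matrix(stats::dist(coords))[upper.tri(diag(n))]
  n_pairs <- length(d)
  if (n_pairs < 2 * n_classes) {
    n_classes <- max(1L, floor(n_pairs / 2))
    warning("too few pairs; reduced to ", n_classes, " distance classes")
  }
  ## equal-count classes from distance quantiles
  breaks <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_classes + 1)))
  class_idx <- cut(d, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  n_classes <- length(breaks) - 1L

  Sx <- class_cov_matrix(x, class_idx, n_classes, n)
  Sy <- class_cov_matrix(y, class_idx, n_classes, n)
  B <- diag(n) - matrix(1 / n, n, n)
  BSx <- B %*% Sx
  BSy <- B %*% Sy
  num <- sum(diag(BSx)) * sum(diag(BSy))
  den <- sum(BSx * t(BSy))      # tr(B Sx B Sy)
  ess <- if (den <= 0) n else 1 + num / den
  ess <- min(max(ess, 2 + 1e-8), n)

  r <- stats::cor(x, y)
  dof <- ess - 2
  Fstat <- dof * r^2 / (1 - r^2)
  p <- 1 - stats::pf(Fstat, 1, dof)
  structure(list(r = r, F = Fstat, dof = dof, p = p, ess = ess, n = n,
                 n_classes = n_classes),
            class = "modified_ttest")
}

#' @export
print.modified_ttest <- function(x, ...) {
  cat("Modified t-test of spatial association (Dutilleul correction)\n")
  cat(sprintf("  r = %.4f, F = %.4f, dof = %.3f (n = %d), p = %.4g\n",
              x$r, x$F, x$dof, x$n, x$p))
  invisible(x)
}

#' Linear and quadratic latitudinal correlation tests
#'
#' Runs the spatially modified t-test of a cell-level response against
#' absolute latitude (linear) and squared latitude (quadratic). A negative
#' quadratic coefficient sign indicates a response peaking at mid/subtropical
#' latitudes and declining both poleward and toward the equator.
#'
#' @param values per-cell response.
#' @param centroids data.frame with `lat` plus projected `x`, `y` (as from
#'   [cell_centroids()]).
#' @param n_classes distance classes for the correction.
#' @return list with `linear` and `quadratic` [modified_ttest()] results and
#'   a tidy `table` (term, r, F, dof, p).
#' @export
quadratic_latitude_test <- function(values, centroids, n_classes = 13) {
  coords <- cbind(centroids$x, centroids$y)
  lin <- modified_ttest(values, abs(centroids$lat), coords, n_classes)
  quad <- modified_ttest(values, centroids$lat^2, coords, n_classes)
  tab <- data.frame(term = c("linear", "quadratic"),
                    r = c(lin$r, quad$r), F = c(lin$F, quad$F),
                    dof = c(lin$dof, quad$dof), p = c(lin$p, quad$p))
  list(linear = lin, quadratic = quad, table = tab)
}

## Row-standardised spatial weights: k-nearest-neighbour (default) or
## inverse distance.
spatial_weights <- function(coords, scheme = c("knn", "idw"), k = 8) {
  coords <- as.matrix(coords)
  scheme <- match.arg(scheme)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
  } else {
    W <- 1 / D
    diag(W) <- 0
  }
  W / rowSums(W)
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of `values` over `coords`, with a
#' one-sided (greater) p-value from random permutation of the values across
#' locations. The null expectation of I is `-1/(n-1)`.
#'
#' @param values numeric vector (non-constant).
#' @param coords projected coordinates (metres), or `NULL` when `W` is given.
#' @param scheme `"knn"` (k-nearest, row-standardised; default) or `"idw"`.
#' @param k neighbours for the knn scheme (default 8).
#' @param n_perm permutations (default 10000).
#' @param W optional pre-built row-standardised weight matrix.
#' @param seed optional integer seed for the permutations.
#' @return object of class `moran_test`: list(I, expected, p, n_perm).
#' @export
morans_i <- function(values, coords = NULL, scheme = "knn", k = 8,
                     n_perm = 10000, W = NULL, seed = NULL) {
  n <- length(values)
  if (n < 10) stop("need at least 10 locations")
  if (stats::sd(values) == 0) stop("constant values")
  if (is.null(W)) W <- spatial_weights(coords, scheme, k)
  if (!is.null(seed)) set.seed(seed)
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  I_obs <- (n / s0) * sum(z * (W %*% z)) / denom
  ## permutations in one matrix product
  P <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) P[, b] <- z[sample.int(n)]
  I_perm <- (n / s0) * colSums(P * (W %*% P)) / denom
  p <- (1 + sum(I_perm >= I_obs)) / (n_perm + 1)
  structure(list(I = I_obs, expected = -1 / (n - 1), p = p,
                 n_perm = n_perm, I_perm_mean = mean(I_perm)),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), one-sided p = %.4g (%d permutations)\n",
              x$I, x$expected, x$p, x$n_perm))
  invisible(x)
}

#' Sampling-effort correlation checks
#'
#' Pearson correlations used to verify that sampling intensity does not
#' drive the diversity metrics: (a) per-OTU diversity vs copies per OTU;
#' (b) per-cell GDM and GDE vs total individuals, mean copies per OTU and
#' OTU richness.
#'
#' @param summaries cell summary table from [summarize_cells()] (with its
#'   `otu_diversity` attribute, or pass `otu_div`).
#' @param otu_div optional per-OTU diversity table.
#' @return data.frame: level, response, predictor, r, p (NA where a variable
#'   is constant, with a message).
#' @export
pearson_sampling_checks <- function(summaries, otu_div = attr(summaries, "otu_diversity")) {
  rows <- list()
  safe_cor <- function(a, b, level, response, predictor) {
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      message(sprintf("pearson_sampling_checks: %s ~ %s skipped (constant or too short)",
                      response, predictor))
      return(data.frame(level = level, response = response, predictor = predictor,
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(a, b)
    data.frame(level = level, response = response, predictor = predictor,
               r = unname(ct$estimate), p = ct$p.value)
  }
  if (!is.null(otu_div) && nrow(otu_div) > 0)
    rows <- c(rows, list(safe_cor(otu_div$pi, otu_div$n_copies,
                                  "otu", "pi", "n_copies")))
  mean_copies <- summaries$n_individuals / summaries$n_otus
  for (resp in c("gdm", "gde")) {
    rows <- c(rows,
              list(safe_cor(summaries[[resp]], summaries$n_individuals, "cell", resp, "n_individuals"),
                   safe_cor(summaries[[resp]], mean_copies, "cell", resp, "mean_copies"),
                   safe_cor(summaries[[resp]], summaries$n_otus, "cell", resp, "n_otus")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
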