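## Environmental predictor handling and the Bayesian spatial regression of
## the cell-level diversity metrics: collinearity pruning, standardisation,
## continent-stratified splitting, variable selection, the knot-based spatial
## GLMM, fit diagnostics and posterior prediction.

#' Prune collinear predictors
#'
#' Greedy removal: while any retained pair has `|r| > threshold`, the pair
#' with the largest `|r|` is found and its lower-priority member dropped.
#' Priority is the order of `priority` (earlier = kept preferentially),
#' defaulting to column order.
#'
#' @param env data.frame of candidate predictors (numeric columns only).
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.75).
#' @param priority character vector ordering the predictors by importance.
#' @return list: `retained`, `dropped`, and the full correlation matrix.
#' @export
prune_collinear <- function(env, threshold = 0.75, priority = names(env)) {
  stopifnot(ncol(env) >= 2)
  cm <- stats::cor(env)
  keep <- names(env)
  rank_of <- function(v) match(v, priority)
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(keep[idx[1]], keep[idx[2]])
    drop_var <- pair[which.max(rank_of(pair))]
    keep <- setdiff(keep, drop_var)
  }
  list(retained = keep, dropped = setdiff(names(env), keep), cor = cm)
}

#' Standardise predictors using training-set moments
#'
#' Z-scores each column with the training rows' mean and sample standard
#' deviation (`stats::sd`, denominator n-1); the same transform is applied
#' to every row, so test and prediction cells are expressed on the training
#' scale.
#'
#' @param env data.frame of predictors.
#' @param train_idx rows defining the moments (default all rows).
#' @return list of class `env_transform`: `table` (standardised env),
#'   `center`, `scale`.
#' @export
standardize_env <- function(env, train_idx = seq_len(nrow(env))) {
  center <- vapply(env[train_idx, , drop = FALSE], mean, numeric(1))
  scale <- vapply(env[train_idx, , drop = FALSE], stats::sd, numeric(1))
  zero <- names(scale)[scale == 0 | !is.finite(scale)]
  if (length(zero))
    stop("zero-variance column(s) over training cells: ", paste(zero, collapse = ", "))
  tab <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              env, center, scale, SIMPLIFY = FALSE))
  structure(list(table = tab, center = center, scale = scale),
            class = "env_transform")
}

#' Apply or invert a stored standardisation
#' @param transform an `env_transform`.
#' @param newdata data.frame with the transform's columns.
#' @param invert map standardised values back to the original scale.
#' @return data.frame.
#' @export
apply_transform <- function(transform, newdata, invert = FALSE) {
  vars <- names(transform$center)
  missing_vars <- setdiff(vars, names(newdata))
  if (length(missing_vars))
    stop("newdata lacks predictor(s): ", paste(missing_vars, collapse = ", "))
  out <- newdata[, vars, drop = FALSE]
  for (v in vars) {
    out[[v]] <- if (invert) out[[v]] * transform$scale[v] + transform$center[v]
                else (out[[v]] - transform$center[v]) / transform$scale[v]
  }
  out
}

#' Continent-stratified train/test split
#'
#' Within each continent, `round-half-up(fraction * n)` cells go to
#' training and the remainder to testing; a continent with a single cell is
#' assigned to training with a warning. Deterministic under `seed`.
#'
#' @param continent character vector, one label per cell.
#' @param fraction training fraction (default 0.75).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(continent, fraction = 0.75, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (ct in unique(continent)) {
    idx <- which(continent == ct)
    n <- length(idx)
    if (n == 1) {
      warning("continent '", ct, "' has a single cell; assigned to training")
      train <- c(train, idx)
      next
    }
    n_train <- min(n, floor(fraction * n + 0.5))
    train <- c(train, sample(idx, n_train))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(continent), train))
}

## ---- spatial GLMM -----------------------------------------------------

## Exponential covariance between two coordinate sets.
exp_cov <- function(c1, c2, range) {
  d <- sqrt(outer(c1[, 1], c2[, 1], "-")^2 + outer(c1[, 2], c2[, 2], "-")^2)
  exp(-d / range)
}

#' Fit the Bayesian spatial GLMM
#'
#' Gaussian observation model
#' `y_i = alpha + x_i' beta + w(s_i) + eps_i`, `eps ~ N(0, sigma^2)`,
#' where `w` is a knot-based (predictive-process) random field with
#' exponential covariance and a heavy-tail scale mixture: conditional on a
#' mixing variable `lambda ~ Inv-Gamma(df/2, df/2)` the knot values are
#' Gaussian with covariance `sigma_w^2 * lambda * K`, so marginally the
#' field is multivariate-t with `df` degrees of freedom. Priors: slopes
#' `N(0, 0.1)` (variance 0.1, sd about 0.316 -- regularising on
#' standardised predictors while still admitting moderate effects),
#' residual scale half-`N(0, 1)`, field scale half-`N(0, 1)`, intercept
#' `N(0, 5)`.
#'
#' The model is conditionally conjugate, so posterior draws come from a
#' blocked Gibbs sampler: `(alpha, beta, u)` jointly Gaussian given the
#' scales, slice-sampling updates for `sigma` and `sigma_w`, and a
#' conjugate inverse-gamma update for `lambda`. Convergence is summarised
#' with split R-hat and effective sample sizes; a fit with any
#' `R-hat > 1.05` is flagged and refuses silent downstream use.
#'
#' @param y numeric response (e.g. sqrt-GDM or GDE of training cells).
#' @param X numeric matrix/data.frame of standardised predictors.
#' @param coords projected coordinates (metres), one row per observation.
#' @param n_knots knots for the low-rank field (default 25; reduced to at
#'   most n/2). Knots are placed by k-means on the coordinates.
#' @param gp_range e-folding range of the exponential covariance in metres;
#'   default one quarter of the maximum inter-point distance.
#' @param df degrees of freedom of the multivariate-t field (default 10).
#' @param priors list overriding `slope_sd` (0.1), `intercept_sd` (5),
#'   `sigma_sd` (1), `field_sd_sd` (1).
#' @param chains,iter_warmup,iter_sampling MCMC configuration
#'   (defaults 4, 1000, 1000).
#' @param transform `"identity"` (default) or `"logit"`; with `"logit"` the
#'   response (in (0,1), e.g. GDE) is logit-transformed before fitting and
#'   predictions are mapped back.
#' @param seed master seed; chain seeds derive from it.
#' @return object of class `spatial_glmm`.
#' @export
fit_spatial_glmm <- function(y, X, coords, n_knots = 25, gp_range = NULL,
                             df = 10, priors = list(),
                             chains = 4, iter_warmup = 1000,
                             iter_sampling = 1000,
                             transform = c("identity", "logit"),
                             seed = 1) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  coords <- as.matrix(coords)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(coords) == n)
  if (n < 30) warning("fewer than 30 training cells; fit may be unstable")
  y_raw <- y
  if (transform == "logit") {
    if (any(y <= 0 | y >= 1)) stop("logit transform needs response in (0,1)")
    y <- stats::qlogis(y)
  }
  pr <- utils::modifyList(list(slope_sd = sqrt(0.1), intercept_sd = 5,
                               sigma_sd = 1, field_sd_sd = 1), priors)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  set.seed(derive_seed(seed, 17L))
  m <- min(n_knots, floor(n / 2))
  km <- stats::kmeans(coords, centers = m, nstart = 3, iter.max = 50)
  knots <- km$centers
  if (is.null(gp_range)) {
    D <- stats::dist(coords)
    gp_range <- max(D) / 4
  }
  K <- exp_cov(knots, knots, gp_range) + diag(1e-8, m)
  Kinv <- chol2inv(chol(K))
  A <- exp_cov(coords, knots, gp_range) %*% Kinv

  M <- cbind(1, X, A)
  d <- ncol(M)
  MtM <- crossprod(M)
  Mty <- crossprod(M, y)
  prior_prec_fixed <- c(1 / pr$intercept_sd^2, rep(1 / pr$slope_sd^2, p))

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    sigma <- stats::sd(y) * stats::runif(1, 0.5, 1.5)
    sigma_w <- stats::sd(y) * stats::runif(1, 0.2, 1)
    lambda <- 1
    theta <- rep(0, d)
    n_iter <- iter_warmup + iter_sampling
    keep <- matrix(NA_real_, iter_sampling, d + 3)
    for (it in seq_len(n_iter)) {
      ## joint Gaussian update of (alpha, beta, u)
      P0 <- diag(c(prior_prec_fixed, rep(0, m)), d)
      P0[(p + 2):d, (p + 2):d] <- Kinv / (sigma_w^2 * lambda)
      Q <- MtM / sigma^2 + P0
      ch <- chol(Q)
      mu <- backsolve(ch, forwardsolve(t(ch), Mty / sigma^2))
      theta <- mu + backsolve(ch, stats::rnorm(d))
      resid <- y - drop(M %*% theta)
      ss <- sum(resid^2)
      u <- theta[(p + 2):d]
      quad <- drop(crossprod(u, Kinv %*% u))
      ## residual scale: half-Normal(0, sigma_sd) prior, slice on log sigma
      ls <- slice_step(log(sigma), function(l) {
        s <- exp(l)
        -n * l - ss / (2 * s^2) - s^2 / (2 * pr$sigma_sd^2) + l
      })
      sigma <- exp(ls)
      ## field scale: half-Normal(0, field_sd_sd), slice on log sigma_w
      lw <- slice_step(log(sigma_w), function(l) {
        s <- exp(l)
        -m * l - quad / (2 * s^2 * lambda) - s^2 / (2 * pr$field_sd_sd^2) + l
      })
      sigma_w <- exp(lw)
      ## t-mixture scale: conjugate inverse-gamma
      lambda <- 1 / stats::rgamma(1, shape = (df + m) / 2,
                                  rate = (df + quad / sigma_w^2) / 2)
      if (it > iter_warmup)
        keep[it - iter_warmup, ] <- c(theta, sigma, sigma_w, lambda)
    }
    keep
  }

  chain_draws <- lapply(seq_len(chains), function(ch) run_chain(derive_seed(seed, 100L + ch)))
  par_names <- c("(Intercept)", colnames(X), paste0("u", seq_len(m)),
                 "sigma", "sigma_w", "lambda")
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- par_names

  ## convergence on the interpretable parameters
  diag_pars <- c("(Intercept)", colnames(X), "sigma", "sigma_w")
  rhat <- vapply(diag_pars, function(pn) {
    split_rhat(sapply(chain_draws, function(cd) cd[, match(pn, par_names)]))
  }, numeric(1))
  ess <- vapply(diag_pars, function(pn) {
    ess_basic(sapply(chain_draws, function(cd) cd[, match(pn, par_names)]))
  }, numeric(1))
  converged <- all(is.finite(rhat)) && max(rhat) < 1.05
  if (!converged)
    warning("chains not converged (max R-hat = ",
            sprintf("%.3f", max(rhat, na.rm = TRUE)), "); fit is flagged")

  ## per-draw Bayesian R^2: modelled variance (linear predictor + field)
  ## over modelled + residual variance
  eta_draws <- draws[, seq_len(d), drop = FALSE] %*% t(M)
  mod_var <- apply(eta_draws, 1, stats::var)
  r2 <- mod_var / (mod_var + draws[, "sigma"]^2)

  structure(list(draws = draws, chain_draws = chain_draws,
                 par_names = par_names, predictors = colnames(X),
                 n = n, m = m, knots = knots, gp_range = gp_range, df = df,
                 Kinv = Kinv, priors = pr, transform = transform,
                 y = y_raw, X = X, coords = coords,
                 rhat = rhat, ess = ess, converged = converged,
                 r2 = r2,
                 chains = chains, iter_warmup = iter_warmup,
                 iter_sampling = iter_sampling, seed = seed),
            class = "spatial_glmm")
}

#' @export
print.spatial_glmm <- function(x, ...) {
  cat("Bayesian spatial GLMM (knot-based t-field, blocked Gibbs)\n")
  cat(sprintf("  n = %d cells, %d predictors, %d knots, range = %.0f m\n",
              x$n, length(x$predictors), x$m, x$gp_range))
  cat(sprintf("  %d chains x %d draws; converged: %s (max R-hat %.3f)\n",
              x$chains, x$iter_sampling, x$converged, max(x$rhat)))
  cat(sprintf("  Bayesian R2 (median) = %.3f\n", stats::median(x$r2)))
  invisible(x)
}

#' @export
coef.spatial_glmm <- function(object, ...) {
  pars <- c("(Intercept)", object$predictors)
  vapply(pars, function(pn) stats::median(object$draws[, pn]), numeric(1))
}

#' @export
summary.spatial_glmm <- function(object, prob = 0.95, ...) {
  pars <- c("(Intercept)", object$predictors, "sigma", "sigma_w")
  tab <- t(vapply(pars, function(pn) {
    dr <- object$draws[, pn]
    h <- hdi(dr, prob)
    c(median = stats::median(dr), lower = h[["lower"]], upper = h[["upper"]],
      rhat = object$rhat[[pn]], ess = object$ess[[pn]])
  }, numeric(5)))
  r2h <- hdi(object$r2, prob)
  out <- list(coefficients = as.data.frame(tab),
              r2 = c(median = stats::median(object$r2), r2h),
              converged = object$converged, prob = prob)
  class(out) <- "summary.spatial_glmm"
  out
}

#' @export
print.summary.spatial_glmm <- function(x, ...) {
  cat("Posterior summary (median and", sprintf("%d%%", round(100 * x$prob)), "HDI):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Bayesian R2: %.3f [%.3f, %.3f]; converged: %s\n",
              x$r2[["median"]], x$r2[["lower"]], x$r2[["upper"]], x$converged))
  invisible(x)
}

#' @export
residuals.spatial_glmm <- function(object, ...) {
  M <- cbind(1, object$X,
             exp_cov(object$coords, object$knots, object$gp_range) %*% object$Kinv)
  d <- ncol(M)
  theta_med <- apply(object$draws[, seq_len(d), drop = FALSE], 2, stats::median)
  fitted <- drop(M %*% theta_med)
  y <- if (object$transform == "logit") stats::qlogis(object$y) else object$y
  y - fitted
}

#' Plot posterior slope medians and intervals
#'
#' Dot-and-interval display of the standardised slope posteriors, ordered by
#' median, with a dotted zero reference line.
#'
#' @param x a fitted `spatial_glmm`.
#' @param prob interval mass (default 0.95).
#' @param ... passed to [graphics::plot()].
#' @export
plot.spatial_glmm <- function(x, prob = 0.95, ...) {
  pars <- x$predictors
  meds <- vapply(pars, function(pn) stats::median(x$draws[, pn]), numeric(1))
  his <- vapply(pars, function(pn) hdi(x$draws[, pn], prob), numeric(2))
  ord <- order(meds)
  graphics::plot(meds[ord], seq_along(pars), xlim = range(his),
                 yaxt = "n", xlab = "standardised slope", ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = seq_along(pars), labels = pars[ord], las = 1)
  graphics::segments(his[1, ord], seq_along(pars), his[2, ord], seq_along(pars))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Posterior prediction at new cells
#'
#' Posterior predictive of the response per cell: linear predictor plus the
#' kriged field (predictive-process conditional mean at the new locations),
#' optionally plus residual noise, summarised by the median and a
#' highest-density interval over `n_draws` posterior draws.
#'
#' @param object a fitted `spatial_glmm`.
#' @param newdata data.frame/matrix of standardised predictors (the model's
#'   predictors must all be present).
#' @param coords projected coordinates of the new cells.
#' @param n_draws posterior draws used (default 1000).
#' @param include_residual add `N(0, sigma^2)` observation noise per draw
#'   (default FALSE: predict the latent cell mean).
#' @param prob HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame: median, lower, upper (per cell, response scale).
#' @export
predict.spatial_glmm <- function(object, newdata, coords, n_draws = 1000,
                                 include_residual = FALSE, prob = 0.95, ...) {
  if (!object$converged)
    warning("predicting from a non-converged fit")
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss))
    stop("prediction cells lack predictor(s): ", paste(miss, collapse = ", "))
  Xn <- as.matrix(newdata[, object$predictors, drop = FALSE])
  coords <- as.matrix(coords)
  An <- exp_cov(coords, object$knots, object$gp_range) %*% object$Kinv
  Mn <- cbind(1, Xn, An)
  total <- nrow(object$draws)
  take <- if (n_draws >= total) seq_len(total)
          else round(seq(1, total, length.out = n_draws))
  dr <- object$draws[take, , drop = FALSE]
  eta <- dr[, seq_len(ncol(Mn)), drop = FALSE] %*% t(Mn)
  if (include_residual)
    eta <- eta + matrix(stats::rnorm(length(eta), 0, rep(dr[, "sigma"], ncol(eta))),
                        nrow(eta), ncol(eta))
  if (object$transform == "logit") eta <- stats::plogis(eta)
  summ <- apply(eta, 2, function(col) c(stats::median(col), hdi(col, prob)))
  data.frame(median = summ[1, ], lower = summ[2, ], upper = summ[3, ])
}

#' Per-draw Bayesian R-squared of a fit
#'
#' `R2 = var(eta) / (var(eta) + sigma^2)` per posterior draw, where `eta`
#' is the linear predictor plus the spatial field over the training cells.
#'
#' @param fit a `spatial_glmm`.
#' @return list: `draws`, `median`, `hdi` (95%).
#' @export
bayesian_r2 <- function(fit) {
  stopifnot(inherits(fit, "spatial_glmm"))
  list(draws = fit$r2, median = stats::median(fit$r2), hdi = hdi(fit$r2, 0.95))
}

#' Percent prior-posterior overlap per parameter
#'
#' Overlap is the integral of the pointwise minimum of the prior density and
#' a kernel estimate of the posterior density, in percent. Low overlap means
#' the data moved the parameter well away from its prior (the identifiability
#' reading: parameters with small overlap are informed by the data).
#'
#' @param fit a `spatial_glmm` with at least 400 posterior draws.
#' @return named numeric vector of percent overlaps (slopes, intercept,
#'   sigma, sigma_w).
#' @export
prior_posterior_overlap <- function(fit) {
  stopifnot(inherits(fit, "spatial_glmm"))
  if (nrow(fit$draws) < 400) stop("need at least 400 posterior draws")
  pr <- fit$priors
  spec <- c(list("(Intercept)" = function(z) stats::dnorm(z, 0, pr$intercept_sd)),
            stats::setNames(lapply(fit$predictors, function(pn) {
              function(z) stats::dnorm(z, 0, pr$slope_sd)
            }), fit$predictors),
            list(sigma = function(z) 2 * stats::dnorm(z, 0, pr$sigma_sd) * (z >= 0),
                 sigma_w = function(z) 2 * stats::dnorm(z, 0, pr$field_sd_sd) * (z >= 0)))
  vapply(names(spec), function(pn) {
    draws <- fit$draws[, pn]
    dens <- stats::density(draws, n = 1024)
    overlap_grid(dens$x, dens$y, spec[[pn]])
  }, numeric(1))
}

## integral of min(posterior density estimate, prior density) on the grid,
## as a percentage
overlap_grid <- function(x, post_y, prior_fun) {
  dx <- diff(x[1:2])
  100 * sum(pmin(post_y, prior_fun(x))) * dx
}

#' Forward cross-validated variable selection
#'
#' Ranks candidate predictors by their gain in K-fold cross-validated
#' expected log predictive density (ELPD) under a ridge-regularised Gaussian
#' linear model whose penalty matches the `N(0, slope_sd)` slope prior, and
#' adds them greedily until the best gain drops below `gain_tol`. This is a
#' deliberately non-spatial, fast search (the spatial field enters at the
#' final fitting stage, not during screening).
#'
#' @param y response over training cells.
#' @param X data.frame/matrix of standardised candidate predictors.
#' @param k_folds folds (default 5).
#' @param gain_tol minimum ELPD gain to keep adding (default 1).
#' @param slope_sd prior scale defining the ridge penalty (default 0.1).
#' @param max_vars cap on selected predictors (default all).
#' @param seed fold-assignment seed.
#' @return list: `selected` (ordered names, possibly empty), `path`
#'   (data.frame of candidate ELPD at each step), `elpd_null`.
#' @export
select_variables <- function(y, X, k_folds = 5, gain_tol = 1, slope_sd = sqrt(0.1),
                             max_vars = ncol(X), seed = 1) {
  X <- as.matrix(X)
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  elpd_of <- function(vars) {
    tot <- 0
    for (f in seq_len(k_folds)) {
      tr <- fold != f; te <- !tr
      ytr <- y[tr]
      if (length(vars) == 0) {
        mu_hat <- mean(ytr)
        s <- stats::sd(ytr)
        tot <- tot + sum(stats::dnorm(y[te], mu_hat, s, log = TRUE))
      } else {
        Xtr <- X[tr, vars, drop = FALSE]
        Xte <- X[te, vars, drop = FALSE]
        Mtr <- cbind(1, Xtr)
        s2 <- stats::var(ytr)
        pen <- diag(c(0, rep(s2 / slope_sd^2, length(vars))), ncol(Mtr))
        b <- solve(crossprod(Mtr) + pen, crossprod(Mtr, ytr))
        res <- ytr - drop(Mtr %*% b)
        s <- sqrt(sum(res^2) / max(1, sum(tr) - length(vars) - 1))
        pred <- drop(cbind(1, Xte) %*% b)
        tot <- tot + sum(stats::dnorm(y[te], pred, s, log = TRUE))
      }
    }
    tot
  }
  selected <- character(0)
  current <- elpd_of(selected)
  elpd_null <- current
  path <- list()
  remaining <- colnames(X)
  while (length(selected) < max_vars && length(remaining)) {
    gains <- vapply(remaining, function(v) elpd_of(c(selected, v)) - current,
                    numeric(1))
    best <- names(which.max(gains))
    path[[length(path) + 1]] <- data.frame(step = length(selected) + 1,
                                           candidate = best,
                                           gain = unname(gains[best]))
    if (gains[best] < gain_tol) break
    selected <- c(selected, best)
    current <- current + gains[best]
    remaining <- setdiff(remaining, best)
  }
  list(selected = selected,
       path = if (length(path)) do.call(rbind, path) else
         data.frame(step = integer(), candidate = character(), gain = numeric()),
       elpd_null = elpd_null)
}

#' Spatially corrected test of the freeze effect
#'
#' Modified t-test of a diversity metric against the binary freeze
#' indicator (minimum temperature of the coldest month at or below 0 C).
#'
#' @param values per-cell metric (e.g. GDE).
#' @param freeze logical/0-1 vector; both classes must be present.
#' @param coords projected cell coordinates.
#' @param n_classes distance classes for the correction.
#' @return a [modified_ttest()] result.
#' @export
freeze_test <- function(values, freeze, coords, n_classes = 13) {
  freeze <- as.numeric(freeze)
  if (length(unique(freeze)) < 2) stop("both freeze classes must be present")
  modified_ttest(values, freeze, coords, n_classes)
}
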