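test_that("collinearity pruning keeps one of each correlated block by priority", {
  set.seed(1)
  n <- 80
  a <- rnorm(n)
  env <- data.frame(a = a, b = a + rnorm(n, 0, 0.1), c = a + rnorm(n, 0, 0.1),
                    d = rnorm(n))
  pr <- prune_collinear(env, threshold = 0.75, priority = c("b", "a", "c", "d"))
  expect_setequal(pr$retained, c("b", "d"))
  ## identical columns: exactly one kept
  env2 <- data.frame(x = a, y = a)
  expect_equal(prune_collinear(env2)$retained, "x")
  ## independent columns: all kept
  env3 <- as.data.frame(matrix(rnorm(n * 3), n))
  expect_setequal(prune_collinear(env3)$retained, names(env3))
})

test_that("standardisation uses training moments, applies to new data and inverts", {
  env <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60))
  st <- standardize_env(env)
  expect_equal(st$table$a, c(-1, 0, 1))            # sample sd convention
  expect_equal(mean(st$table$b), 0)
  expect_equal(stats::sd(st$table$b), 1)
  new <- data.frame(a = 2, b = 30)                  # training means -> 0
  z <- apply_transform(st, new)
  expect_equal(unname(unlist(z)), c(0, 0))
  back <- apply_transform(st, st$table, invert = TRUE)
  expect_equal(as.matrix(back), as.matrix(env), tolerance = 1e-12)
  expect_error(standardize_env(data.frame(a = c(1, 1, 1))), "zero-variance")
})

test_that("stratified split rounds half-up per continent and is deterministic", {
  cont <- rep("A", 100)
  sp <- split_train_test(cont, seed = 2)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  cont2 <- c(rep("A", 40), rep("B", 60))
  sp2 <- split_train_test(cont2, seed = 2)
  expect_equal(sum(cont2[sp2$train] == "A"), 30)
  expect_equal(sum(cont2[sp2$train] == "B"), 45)
  expect_identical(sp2, split_train_test(cont2, seed = 2))
  expect_warning(split_train_test(c("A", "A", "B"), seed = 1), "single cell")
})

test_that("spatial GLMM recovers planted slopes and flags convergence", {
  d <- simulate_cell_data(n_cells = 120, slopes = c(x1 = 0.5, x2 = -0.3),
                          field_sd = 0.15, noise_sd = 0.1, seed = 5)
  fit <- fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                          iter_warmup = 300, iter_sampling = 500, seed = 5)
  expect_s3_class(fit, "spatial_glmm")
  expect_true(fit$converged)
  co <- coef(fit)
  expect_equal(unname(co["x1"]), 0.5, tolerance = 0.1)
  expect_equal(unname(co["x2"]), -0.3, tolerance = 0.1)
  s <- summary(fit)
  expect_true(all(c("median", "lower", "upper", "rhat", "ess") %in%
                    colnames(s$coefficients)))
  expect_equal(length(residuals(fit)), 120)
})

test_that("pure-noise response yields slope intervals covering zero and low R2", {
  set.seed(6)
  d <- simulate_cell_data(n_cells = 100, slopes = c(x1 = 0, x2 = 0),
                          field_sd = 0, noise_sd = 0.3, seed = 6)
  fit <- suppressWarnings(fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                                           iter_warmup = 300, iter_sampling = 400,
                                           seed = 6))
  for (v in c("x1", "x2")) {
    ci <- hdi(fit$draws[, v], 0.90)
    expect_true(ci["lower"] < 0 && ci["upper"] > 0)
  }
  expect_lt(stats::median(fit$r2), 0.25)
})

test_that("a field-only response is absorbed by the spatial term, not the slopes", {
  d <- simulate_cell_data(n_cells = 120, slopes = c(x1 = 0, x2 = 0),
                          field_sd = 0.5, noise_sd = 0.05, seed = 7)
  fit <- suppressWarnings(fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                                           iter_warmup = 300, iter_sampling = 400,
                                           seed = 7))
  expect_gt(stats::quantile(fit$draws[, "sigma_w"], 0.05), 0.05)
  expect_lt(max(abs(coef(fit)[c("x1", "x2")])), 0.2)
})

test_that("posterior prediction is consistent at training cells and respects input checks", {
  d <- simulate_cell_data(n_cells = 80, slopes = c(x1 = 0.5), field_sd = 0.1,
                          noise_sd = 0.1, seed = 8)
  fit <- suppressWarnings(fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                                           iter_warmup = 300, iter_sampling = 400,
                                           seed = 8))
  pr <- predict(fit, as.data.frame(d$X), d$coords)
  expect_equal(nrow(pr), 80)
  expect_true(all(pr$lower <= pr$median & pr$median <= pr$upper))
  ## predictions track the observations (latent mean vs observed y)
  expect_gt(stats::cor(pr$median, d$y), 0.8)
  ## all-zero predictors -> median near the intercept posterior median
  pr0 <- predict(fit, data.frame(x1 = 0), matrix(c(2.5e6, 2.5e6), 1))
  expect_lt(abs(pr0$median - stats::median(fit$draws[, "(Intercept)"])), 0.15)
  expect_error(predict(fit, data.frame(bad = 1), matrix(0, 1, 2)), "lack predictor")
})

test_that("Bayesian R2 tracks the planted variance decomposition", {
  d <- simulate_cell_data(n_cells = 150, slopes = c(x1 = 0.5, x2 = -0.3),
                          field_sd = 0.1, noise_sd = 0.2, seed = 9)
  fit <- suppressWarnings(fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                                           iter_warmup = 300, iter_sampling = 400,
                                           seed = 9))
  eta_true <- d$y - (d$y - (d$X %*% d$slopes + d$field))  # = X beta + field
  share <- stats::var(drop(eta_true)) / (stats::var(drop(eta_true)) + d$noise_sd^2)
  r2 <- bayesian_r2(fit)
  expect_equal(r2$median, share, tolerance = 0.1)
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))
})

test_that("prior-posterior overlap is near 100% with no data signal and small when identified", {
  d <- simulate_cell_data(n_cells = 150, slopes = c(x1 = 0.5, x2 = 0),
                          field_sd = 0, noise_sd = 0.05, seed = 10)
  fit <- suppressWarnings(fit_spatial_glmm(d$y, d$X, d$coords, chains = 2,
                                           iter_warmup = 300, iter_sampling = 500,
                                           seed = 10))
  ov <- prior_posterior_overlap(fit)
  ## sharply identified slope far from zero: analytic Normal-Normal overlap
  ## is essentially the prior mass near the posterior spike
  expect_lt(ov[["x1"]], 13)
  expect_gt(ov[["x2"]], ov[["x1"]])
  fit$draws <- fit$draws[1:100, , drop = FALSE]
  expect_error(prior_posterior_overlap(fit), "400")
})

test_that("overlap computation matches an analytic Normal-Normal oracle", {
  ## posterior N(0.5, 0.05) vs prior N(0, sqrt(0.1)): overlap = integral of
  ## the pointwise minimum, computed here by direct high-resolution quadrature
  set.seed(11)
  draws <- rnorm(4000, 0.5, 0.05)
  grid <- seq(-2, 2, length.out = 40001)
  f_prior <- dnorm(grid, 0, sqrt(0.1))
  f_post <- dnorm(grid, 0.5, 0.05)
  oracle <- sum(pmin(f_prior, f_post)) * diff(grid[1:2])
  dens <- stats::density(draws, n = 1024)
  got <- macrogd:::overlap_grid(dens$x, dens$y, function(z) dnorm(z, 0, sqrt(0.1)))
  expect_equal(got / 100, oracle, tolerance = 0.03)
})

test_that("forward CV selection finds the planted predictor and drops redundant copies", {
  set.seed(12)
  n <- 120
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("v", 1:6)))
  y <- 0.8 * X[, "v3"] + rnorm(n, 0, 0.4)
  sel <- select_variables(y, X, seed = 1)
  expect_equal(sel$selected[1], "v3")
  ## duplicated informative predictor: exactly one of the pair selected
  X2 <- cbind(X, v3b = X[, "v3"] + rnorm(n, 0, 0.01))
  sel2 <- select_variables(y, X2, seed = 1)
  expect_equal(sum(sel2$selected %in% c("v3", "v3b")), 1)
  ## all-noise candidates: empty or a single marginal pick
  y0 <- rnorm(n)
  sel0 <- select_variables(y0, X, seed = 1)
  expect_lte(length(sel0$selected), 1)
})

test_that("freeze test requires both classes and detects a planted effect", {
  set.seed(13)
  n <- 60
  coords <- cbind(runif(n, 0, 1e6), runif(n, 0, 1e6))
  freeze <- rep(c(TRUE, FALSE), each = n / 2)
  gde_vals <- 0.5 + 0.2 * (!freeze) + rnorm(n, 0, 0.05)
  ft <- freeze_test(gde_vals, freeze, coords)
  expect_lt(ft$p, 0.05)
  expect_lt(ft$r, 0)  # higher GDE where freeze is FALSE
  expect_error(freeze_test(gde_vals, rep(TRUE, n), coords), "both")
})
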