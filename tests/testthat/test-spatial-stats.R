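test_that("modified t-test recovers a perfect correlation and validates input", {
  set.seed(1)
  coords <- cbind(runif(30), runif(30))
  x <- rnorm(30)
  r <- modified_ttest(x, x + 1, coords)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  expect_error(modified_ttest(x, rep(1, 30), coords), "constant")
  expect_error(modified_ttest(x[1:5], x[1:5], coords[1:5, ]), "at least 10")
})

test_that("with no autocorrelation the effective dof approaches n - 2", {
  set.seed(2)
  n <- 100
  dofs <- replicate(60, {
    modified_ttest(rnorm(n), rnorm(n), cbind(runif(n), runif(n)))$dof
  })
  expect_gt(mean(dofs), 90)
  expect_lt(mean(dofs), 98)
})

test_that("autocorrelated independent fields shrink the dof and control the error rate", {
  set.seed(3)
  n <- 80
  res <- t(replicate(80, {
    coords <- cbind(runif(n), runif(n))
    x <- sim_gp_field(coords, 0.3, 1)
    y <- sim_gp_field(coords, 0.3, 1)
    m <- modified_ttest(x, y, coords)
    c(m$dof, m$p < 0.05, stats::cor.test(x, y)$p.value < 0.05)
  }))
  expect_lt(mean(res[, 1]), 40)       # strong dof correction
  expect_lt(mean(res[, 2]), 0.12)     # modified test near nominal
  expect_gt(mean(res[, 3]), 0.2)      # naive test badly anticonservative
})

test_that("the test is invariant to affine rescaling of both variables", {
  set.seed(4)
  n <- 40
  coords <- cbind(runif(n), runif(n))
  x <- rnorm(n); y <- x + rnorm(n)
  a <- modified_ttest(x, y, coords)
  b <- modified_ttest(10 + 3 * x, -2 * y + 1, coords)
  expect_equal(abs(a$r), abs(b$r), tolerance = 1e-12)
  expect_equal(a$dof, b$dof, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("latitude tests detect a planted subtropical hump with a negative quadratic sign", {
  set.seed(5)
  g <- grid_spec(385900)
  cells <- expand.grid(row = -16:16, col = 0:3)
  cents <- cell_centroids(cells, g)
  ## response peaks at mid-latitude, symmetric about the equator
  resp <- -(abs(cents$lat) - 30)^2 / 900 + rnorm(nrow(cents), 0, 0.05)
  qt <- quadratic_latitude_test(resp, cents)
  expect_lt(qt$quadratic$r, 0)
  expect_equal(qt$table$term, c("linear", "quadratic"))
  ## a pure quadratic trend is detected much more strongly than linear
  resp2 <- cents$lat^2 / 3600 + rnorm(nrow(cents), 0, 0.03)
  qt2 <- quadratic_latitude_test(resp2, cents)
  expect_gt(abs(qt2$quadratic$r), abs(qt2$linear$r))
})

test_that("Moran's I: checkerboard is negative, gradient is positive with floor p", {
  g <- expand.grid(x = 1:7, y = 1:7)
  coords <- as.matrix(g)
  ## rook weights via 4-nearest neighbours on a unit lattice
  checker <- (-1)^(g$x + g$y)
  m1 <- morans_i(checker, coords, scheme = "knn", k = 4, n_perm = 499, seed = 1)
  expect_lt(m1$I, 0)
  grad <- g$x + g$y + rnorm(49, 0, 0.1)
  m2 <- morans_i(grad, coords, k = 8, n_perm = 999, seed = 2)
  expect_gt(m2$I, 0.5)
  expect_equal(m2$p, 1 / 1000)
  expect_error(morans_i(rep(1, 49), coords), "constant")
})

test_that("permutation distribution of Moran's I is centred on -1/(n-1)", {
  set.seed(6)
  n <- 100
  coords <- cbind(runif(n), runif(n))
  m <- morans_i(rnorm(n), coords, n_perm = 20000, seed = 3)
  expect_equal(m$I_perm_mean, -1 / (n - 1), tolerance = 5e-4)
})

test_that("Moran's I statistic matches the independent ape implementation", {
  set.seed(7)
  n <- 40
  coords <- cbind(runif(n), runif(n))
  v <- rnorm(n)
  W <- macrogd:::spatial_weights(coords, "knn", k = 6)
  ours <- morans_i(v, W = W, n_perm = 99, seed = 1)$I
  theirs <- ape::Moran.I(v, W)$observed
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("iid values reject near the nominal rate", {
  set.seed(8)
  n <- 40
  rej <- replicate(200, {
    coords <- cbind(runif(n), runif(n))
    morans_i(rnorm(n), coords, n_perm = 199)$p <= 0.05
  })
  ## binomial 95% band around 0.05 at 200 sims
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200))
})

test_that("sampling-effort checks compute the advertised correlations", {
  w <- generate_world(world_spec(n_rows = 2, n_cols = 3, otus_per_cell = 20,
                                 samples_per_otu = c(3, 8)), seed = 44)
  recs <- cbind(w$records, assign_cell(w$records$lat, w$records$lon, w$grid))
  s <- summarize_cells(recs, min_otus = 10)
  tab <- pearson_sampling_checks(s)
  expect_true(all(c("pi", "gdm", "gde") %in% tab$response))
  od <- attr(s, "otu_diversity")
  expect_equal(tab$r[tab$response == "pi"],
               unname(stats::cor(od$pi, od$n_copies)), tolerance = 1e-12)
  ## a constant response is surfaced as missing, not an error
  s2 <- s
  s2$gde <- 0.5
  expect_message(tab2 <- pearson_sampling_checks(s2), "skipped")
  expect_true(all(is.na(tab2$r[tab2$response == "gde"])))
})
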