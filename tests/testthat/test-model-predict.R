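test_that("predictor extraction uses nearest-cell semantics", {
  g <- toy_grid()
  pts <- data.frame(longitude = c(0.5, 0.9, 2.2, 5.0),
                    latitude = c(0.5, 1.2, 2.8, 1.0))
  out <- extract_predictors(pts, list(v = g))
  # independent index arithmetic: cell (row, col) = (ceil(lat), ceil(lon))
  expect_equal(out$table$v, c(10 * 1 + 1, 10 * 2 + 1, 10 * 3 + 3))
  expect_equal(out$n_flagged, 1L)
  expect_equal(out$flagged$longitude, 5.0)
  # exact cell-center hit
  hit <- extract_predictors(data.frame(longitude = 1.5, latitude = 2.5),
                            list(v = g))
  expect_equal(hit$table$v, 10 * 3 + 2)
})

test_that("PCA reduction keeps the minimal prefix reaching the target", {
  set.seed(17)
  # two perfectly correlated columns: one component carries everything
  x <- rnorm(100)
  X <- cbind(a = x, b = 2 * x + 3)
  p <- pca_reduce(X, 0.95)
  expect_equal(p$k, 1L)
  expect_equal(p$var_share[1], 1.0, tolerance = 1e-12)
  # shares always sum to one; target 1 returns all components
  Y <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  pa <- pca_reduce(Y, 1.0)
  expect_equal(sum(pa$var_share), 1.0, tolerance = 1e-12)
  expect_equal(pa$k, 4L)
  # retained set is the minimal prefix
  pb <- pca_reduce(Y, 0.5)
  expect_true(pb$cum_share[pb$k] >= 0.5)
  expect_true(pb$k == 1 || pb$cum_share[pb$k - 1] < 0.5)
  # independent columns share variance roughly equally
  Z <- matrix(rnorm(1000 * 5), 1000, 5,
              dimnames = list(NULL, paste0("z", 1:5)))
  pz <- pca_reduce(Z, 1.0)
  expect_true(all(abs(pz$var_share - 1 / 5) < 0.05))
  expect_error(pca_reduce(cbind(a = rnorm(10), b = rep(1, 10))),
               "zero variance")
})

test_that("PCA projection reproduces training scores", {
  set.seed(19)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- pca_reduce(X, 1.0)
  expect_equal(unname(pca_project(p, X)), unname(p$scores),
               tolerance = 1e-10)
})

test_that("the other-country device relabels a seeded 5% per country", {
  tab <- data.frame(country = rep(c("x", "y"), c(100, 40)),
                    v = seq_len(140))
  out <- other_country_augment(tab, fraction = 0.05, seed = 9)
  expect_equal(sum(out$country == "other"), 5L + 2L)
  expect_equal(attr(out, "n_other"), 7L)
  expect_equal(nrow(out), 140L)          # rename in place, no new rows
  expect_equal(out$v, tab$v)             # numeric covariates untouched
  # determinism under the same seed
  out2 <- other_country_augment(tab, fraction = 0.05, seed = 9)
  expect_identical(out, out2)
  # append mode adds relabeled copies instead
  app <- other_country_augment(tab, fraction = 0.05, seed = 9, append = TRUE)
  expect_equal(nrow(app), 147L)
  expect_equal(sum(app$country == "other"), 7L)
  # degenerate and invalid inputs
  empty <- other_country_augment(tab[0, ], fraction = 0.05, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(other_country_augment(tab, fraction = 1.5), "fraction")
})

test_that("smearing factor matches its closed form and Jensen bound", {
  expect_equal(smearing_factor(c(0, 0, 0)), 1.0)
  expect_equal(smearing_factor(c(log(2), -log(2))), 1.25)
  expect_equal(smearing_factor(c(0.1, -0.1)), (exp(0.1) + exp(-0.1)) / 2)
  expect_equal(smearing_factor(c(0.1, -0.1)), 1.0050, tolerance = 1e-4)
  set.seed(23)
  for (i in 1:25) {
    r <- rnorm(50, 0, runif(1, 0.1, 1.5))
    r <- r - mean(r)
    expect_gte(smearing_factor(r), 1.0)
  }
  expect_error(smearing_factor(numeric(0)))
})

test_that("concentration metrics match their definitions", {
  o <- c(1, 2, 3, 4)
  perfect <- model_metrics(o, o)
  expect_equal(perfect$r_squared, 100)
  expect_equal(perfect$nse, 1)
  baseline <- model_metrics(o, rep(mean(o), 4))
  expect_equal(baseline$nse, 0)
  hand <- model_metrics(o, c(1, 2, 3, 5))
  expect_equal(hand$nse, 1 - 1 / 5)
  expect_error(model_metrics(rep(2, 5), 1:5), "zero variance")
})

test_that("noiseless smooth data is recovered almost perfectly", {
  set.seed(29)
  n <- 400
  d <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                  country = sample(c("a", "b"), n, replace = TRUE))
  mu <- log(20) + tanh(d$x1) + 0.5 * sin(d$x2) +
    ifelse(d$country == "a", 0, 0.3)
  d$olsen <- exp(mu)
  fit <- suppressWarnings(fit_olsen_model(
    d, smooth_vars = c("x1", "x2"), factor_vars = "country",
    response = "olsen", split_fraction = 0.7, seed = 1))
  expect_gt(fit$metrics$r_squared, 99.5)
  expect_gt(fit$metrics$nse, 0.99)
  expect_equal(fit$smearing, 1.0, tolerance = 1e-3)
  expect_equal(fit$smearing, smearing_factor(fit$residuals))
  expect_gte(fit$smearing, exp(mean(fit$residuals)))
})

test_that("unseen countries are routed to the other level", {
  set.seed(37)
  n <- 300
  d <- data.frame(x1 = runif(n, -2, 2),
                  country = sample(c("a", "b", "c"), n, replace = TRUE))
  d$olsen <- exp(log(15) + tanh(d$x1) + ifelse(d$country == "a", 0.2, 0))
  d2 <- other_country_augment(d, fraction = 0.05, seed = 2)
  fit <- suppressWarnings(fit_olsen_model(
    d2, smooth_vars = "x1", factor_vars = "country",
    response = "olsen", seed = 1))
  nd <- data.frame(x1 = c(0, 1), country = c("zz", "a"))
  expect_message(p <- predict_concentration(fit, nd), "other")
  expect_true(all(p > 0))
  # an unseen level of a non-country factor is an error
  d$grp <- sample(c("u", "v"), n, replace = TRUE)
  fit2 <- suppressWarnings(fit_olsen_model(
    d, smooth_vars = "x1", factor_vars = "grp",
    response = "olsen", seed = 1))
  expect_error(predict_concentration(
    fit2, data.frame(x1 = 0, grp = "w")), "unseen")
})

test_that("smearing correction removes retransformation bias on average", {
  set.seed(41)
  n <- 5000
  sigma <- 0.6
  d <- data.frame(x1 = runif(n, -2, 2))
  mu <- log(20) + tanh(d$x1)
  d$olsen <- exp(mu + rnorm(n, 0, sigma))
  fit <- suppressWarnings(fit_olsen_model(
    d, smooth_vars = "x1", response = "olsen",
    split_fraction = 0.7, seed = 3))
  test_idx <- setdiff(seq_len(n), fit$train_idx)
  nd <- d[test_idx, , drop = FALSE]
  corrected <- predict_concentration(fit, nd)
  uncorrected <- corrected / fit$smearing
  target <- mean(exp(mu[test_idx] + sigma^2 / 2))  # analytic mean
  expect_lt(abs(mean(corrected) - target) / target, 0.05)
  # the naive back-transform underestimates the mean
  expect_lt(mean(uncorrected), mean(corrected))
  expect_gt(abs(mean(uncorrected) - target), abs(mean(corrected) - target))
})
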