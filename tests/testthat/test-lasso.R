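test_that("standardize_design centers, scales, and drops constants", {
  set.seed(3)
  x <- cbind(a = rnorm(30), b = runif(30), c = rep(2, 30))
  y <- rnorm(30)
  expect_warning(d <- standardize_design(x, y), "constant")
  expect_equal(d$p, 2)
  expect_equal(colMeans(d$X), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(unname(colSums(d$X^2)), c(1, 1), tolerance = 1e-12)
  expect_equal(mean(d$y), 0, tolerance = 1e-12)
  expect_error(suppressWarnings(
    standardize_design(cbind(rep(1, 10)), rnorm(10))), "covariates")
})

test_that("build_design computes per-window densities and fractions", {
  g <- Genome(c(c1 = 10000))
  win <- make_windows(g, 2500)
  peaks <- gr0("c1", c(0, 100, 3000), c(50, 150, 3100))
  feats <- list(f1 = gr0("c1", 0, 1250),          # half of window 1
                f2 = gr0("c1", c(0, 2500, 5000, 7500),
                         c(100, 2700, 5300, 7600)))
  d <- build_design(peaks, win, feats)
  ## response before centering: counts (2,1,0,0) per full-width window
  expect_equal(d$y - min(d$y) * 0, d$y)  # centered
  expect_equal(d$y + mean(c(2, 1, 0, 0)), c(2, 1, 0, 0))
  raw_f1 <- c(0.5, 0, 0, 0)
  expect_equal(d$X[, "f1"] * sqrt(sum((raw_f1 - mean(raw_f1))^2)) +
                 mean(raw_f1), raw_f1)
})

test_that("a single covariate follows the soft-threshold closed form", {
  set.seed(5)
  x <- matrix(rnorm(40), 40, 1)
  x <- x / sqrt(sum(x^2))
  y <- drop(x) * 2 + rnorm(40, 0, 0.2)
  pth <- lars_lasso_path(x, y = y)
  cc <- drop(crossprod(x, y))
  expect_equal(pth$lambda[1], abs(cc))
  expect_equal(pth$beta[, ncol(pth$beta)], cc, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(lasso_at_lambda(pth, abs(cc) / 2), cc - sign(cc) * abs(cc) / 2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("orthonormal designs soft-threshold coordinatewise", {
  set.seed(8)
  n <- 40; p <- 6
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(X) <- paste0("v", 1:p)
  y <- rnorm(n)
  cc <- drop(crossprod(X, y))
  pth <- lars_lasso_path(X, y = y)
  ## entry order = decreasing |c_j|
  expect_equal(pth$entries$variable, order(abs(cc), decreasing = TRUE))
  for (lam in c(0.1, 0.4, 0.8) * max(abs(cc))) {
    expect_equal(lasso_at_lambda(pth, lam),
                 sign(cc) * pmax(abs(cc) - lam, 0),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("the path keeps active correlations tied and dominant", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 30; p <- 7
    X <- scale(matrix(rnorm(n * p), n, p))
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    y <- drop(X %*% c(2, -1, rep(0, p - 2))) + rnorm(n, 0, 0.5)
    y <- y - mean(y)
    pth <- lars_lasso_path(X, y = y)
    for (k in seq_len(length(pth$lambda) - 1)) {
      lam <- (pth$lambda[k] + pth$lambda[k + 1]) / 2
      b <- lasso_at_lambda(pth, lam)
      cr <- drop(crossprod(X, y - X %*% b))
      act <- b != 0
      if (any(act)) expect_lt(max(abs(abs(cr[act]) - lam)), 1e-8)
      if (any(!act)) expect_lt(max(abs(cr[!act])), lam + 1e-8)
    }
  }
})

test_that("variables can leave the active set (lasso modification)", {
  ## classic construction with a drop event: correlated design
  set.seed(123)
  found_drop <- FALSE
  for (rep in 1:50) {
    n <- 20; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    X[, 2] <- X[, 1] * 0.9 + X[, 2] * 0.3
    X <- sweep(scale(X, scale = FALSE), 2,
               sqrt(colSums(scale(X, scale = FALSE)^2)), "/")
    y <- rnorm(n); y <- y - mean(y)
    pth <- lars_lasso_path(X, y = y)
    if (any(pth$action < 0)) { found_drop <- TRUE; break }
  }
  expect_true(found_drop)
  ## after a drop the path still satisfies the KKT tie at midpoints
  k <- which(pth$action < 0)[1]
  lam <- (pth$lambda[k] + pth$lambda[k + 1]) / 2
  b <- lasso_at_lambda(pth, lam)
  cr <- drop(crossprod(X, y - X %*% b))
  expect_lt(max(abs(cr)) - lam, 1e-8)
})

test_that("path coefficients match the coordinate-descent oracle", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(15:30, 1); p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    X <- sweep(scale(X, scale = FALSE), 2,
               sqrt(colSums(scale(X, scale = FALSE)^2)), "/")
    y <- drop(X %*% rnorm(p)) + rnorm(n); y <- y - mean(y)
    pth <- lars_lasso_path(X, y = y)
    for (lam in quantile(pth$lambda, c(0.15, 0.5, 0.85))) {
      expect_equal(lasso_at_lambda(pth, lam), cd_lasso(X, y, lam),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("covariance test reduces to lambda1^2/sigma2 for p = 1 paths", {
  set.seed(23)
  x <- matrix(rnorm(50), 50, 1); x <- x / sqrt(sum(x^2))
  y <- drop(x) * 3 + rnorm(50); y <- y - mean(y)
  pth <- lars_lasso_path(x, y = y)
  d <- list(X = x, y = y)
  s2 <- sum(stats::lm.fit(x, y)$residuals^2) / (50 - 2)
  ct <- covariance_test(pth, d, sigma2 = s2)
  lam1 <- pth$lambda[1]
  expect_equal(ct$T[1], lam1 * (lam1 - 0) / s2, tolerance = 1e-8)
  expect_equal(ct$p_value[1], exp(-ct$T[1]))
})

test_that("a pure signal covariate dominates the covariance test", {
  set.seed(29)
  X <- matrix(rnorm(300), 50, 6)
  y <- X[, 3] * 5 + rnorm(50, 0, 0.01)
  d <- standardize_design(X, y)
  pth <- lars_lasso_path(d)
  ct <- covariance_test(pth, d)
  expect_equal(ct$variable[1], 3)
  expect_gt(ct$T[1], 10 * max(ct$T[-1]))
  rep <- entry_report(pth, d)
  expect_equal(rep$table$name[1], "x3")
  expect_gte(rep$n_significant, 1)
})

test_that("first-entry T has mean about 1 under the global null", {
  set.seed(31)
  T1 <- replicate(300, {
    X <- matrix(rnorm(1000), 100, 10)
    y <- rnorm(100)
    d <- standardize_design(X, y)
    pth <- lars_lasso_path(d, max_steps = 3)
    covariance_test(pth, d)$T[1]
  })
  expect_lt(abs(mean(T1) - 1), 3 * sd(T1) / sqrt(length(T1)))
})

test_that("sigma2 estimation guards against degenerate responses", {
  set.seed(37)
  X <- matrix(rnorm(60), 20, 3)
  expect_error(estimate_sigma2(list(X = X, y = rep(0, 20))),
               "degenerate")
  y <- rnorm(20)
  d <- standardize_design(X, y)      # centering absorbs the intercept
  s2 <- estimate_sigma2(d)
  fit <- lm(y ~ X)
  expect_equal(s2, sum(resid(fit)^2) / (20 - 4), tolerance = 1e-8)
})
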