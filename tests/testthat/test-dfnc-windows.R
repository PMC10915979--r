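test_that("taper is symmetric, normalised, and uniform in the sigma->0 limit", {
  tp <- build_taper(30, 3)
  expect_length(tp$weights, 30)
  expect_equal(sum(tp$weights), 1)
  expect_equal(tp$weights, rev(tp$weights))
  expect_true(all(tp$weights >= 0))
  # vanishing smoothing: rectangle
  tp0 <- build_taper(30, 1e-6)
  expect_equal(tp0$weights, rep(1 / 30, 30), tolerance = 1e-6)
  expect_error(build_taper(30, 0), "sigma")
  expect_error(build_taper(1, 3), "window_length")
})

test_that("window count follows floor((T - W)/step) + 1", {
  x199 <- matrix(rnorm(199 * 3), 199, 3)
  ew <- extract_windows(x199, build_taper(30, 3), step = 1)
  expect_length(ew$segments, 170)
  expect_equal(ew$starts, 0:169)

  x30 <- matrix(rnorm(30 * 3), 30, 3)
  expect_length(extract_windows(x30, build_taper(30, 3))$segments, 1)

  x32 <- matrix(rnorm(32 * 3), 32, 3)
  ew2 <- extract_windows(x32, build_taper(30, 3), step = 2)
  expect_length(ew2$segments, 2)
  expect_equal(ew2$starts, c(0L, 2L))

  expect_error(extract_windows(matrix(0, 10, 3), build_taper(30, 3)),
               "shorter than window")
})

test_that("weighted segments reproduce the taper-weighted covariance", {
  set.seed(21)
  x <- matrix(rnorm(40 * 4), 40, 4)
  tp <- build_taper(30, 3)
  seg <- extract_windows(x, tp)$segments[[5]]
  w <- tp$weights
  win <- x[5:34, ]
  mu <- colSums(win * w)
  manual <- t(win - rep(mu, each = 30)) %*% ((win - rep(mu, each = 30)) * w)
  expect_equal(crossprod(seg), manual, tolerance = 1e-12)
})

test_that("glasso at lambda 0 equals the matrix inverse", {
  set.seed(31)
  X <- matrix(rnorm(300 * 6), 300, 6) %*% matrix(rnorm(36), 6)
  S <- cov(X)
  theta <- glasso_precision(S, 0, input = "covariance")
  expect_lt(norm(theta - solve(S), "F") / norm(solve(S), "F"), 1e-4)
})

test_that("glasso matches the 2-variable closed form", {
  # off-diagonal covariance soft-thresholded by lambda, then inverted
  for (rho in c(0.6, -0.45)) {
    for (lam in c(0.1, 0.3)) {
      S <- matrix(c(1, rho, rho, 1), 2)
      theta <- glasso_precision(S, lam, input = "covariance")
      w12 <- sign(rho) * max(abs(rho) - lam, 0)
      closed <- solve(matrix(c(1, w12, w12, 1), 2))
      expect_lt(max(abs(theta - closed)), 1e-6)
    }
  }
  # full shrinkage: diagonal model, exact zeros
  S <- matrix(c(2, 0.9, 0.9, 1.5), 2)
  theta <- glasso_precision(S, 5, input = "covariance")
  expect_identical(theta[1, 2], 0)
})

test_that("glasso flags near-zero variance components by name", {
  seg <- cbind(a = rnorm(30), dead = rep(0, 30))
  expect_error(glasso_precision(seg, 0.1), "dead")
})

test_that("precision_to_fc inverts and normalises", {
  # diagonal precision -> identity correlation
  expect_equal(precision_to_fc(diag(c(2, 5, 9))), diag(3))
  # 2x2 by hand: [[2,-1],[-1,2]] -> covariance prop [[2,1],[1,2]] -> r = 0.5
  fc <- precision_to_fc(matrix(c(2, -1, -1, 2), 2))
  expect_equal(fc[1, 2], 0.5)
  # round trip through lambda = 0
  set.seed(41)
  X <- matrix(rnorm(500 * 4), 500, 4)
  R <- cor(X)
  theta <- glasso_precision(R, 0, input = "covariance")
  expect_equal(precision_to_fc(theta), R, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("rectangular taper at lambda 0 reproduces plain Pearson windows", {
  set.seed(51)
  x <- matrix(rnorm(60 * 5), 60, 5)
  tp <- build_taper(30, 1e-6)
  ew <- extract_windows(x, tp)
  theta <- glasso_precision(ew$segments[[10]], 0)
  fc <- precision_to_fc(theta)
  plain <- cor(x[10:39, ])
  expect_equal(fc, plain, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("lambda selection is degenerate-safe and seed-deterministic", {
  set.seed(61)
  x <- matrix(rnorm(80 * 5), 80, 5)
  segs <- extract_windows(x, build_taper(30, 3))$segments
  expect_identical(select_lambda(segs, grid = 0.2), 0.2)
  a <- select_lambda(segs, n_repetitions = 10, seed = 5)
  b <- select_lambda(segs, n_repetitions = 10, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("lambda selection beats the grid endpoints on sparse truth", {
  # data from a truly sparse precision: banded, strong partial correlations
  set.seed(71)
  C <- 8
  theta <- diag(C)
  for (i in 1:(C - 1)) theta[i, i + 1] <- theta[i + 1, i] <- -0.4
  sigma <- solve(theta)
  L <- chol(sigma)
  x <- matrix(rnorm(120 * C), 120, C) %*% L
  segs <- extract_windows(x, build_taper(30, 3))$segments
  grid <- 10^seq(-2, 0, length.out = 10)
  best <- select_lambda(segs, grid, n_repetitions = 30, seed = 7)
  scores <- attr(best, "scores")$mean_loglik
  expect_gte(max(scores), scores[1])
  expect_gte(max(scores), scores[length(scores)])
})

test_that("dfnc stacks have the documented shape and symmetry", {
  design <- tiny_design(seed = 13)
  cohort <- simulate_cohort(design)
  stack <- dfnc(cohort$subjects, lambda = 0.01, seed = 13)
  expect_s3_class(stack, "dfnc_stack")
  a <- stack$z[[1]]
  expect_equal(dim(a), c(80 - 30 + 1, 10, 10))
  for (w in c(1, 25, 51)) {
    sl <- a[w, , ]
    expect_equal(sl, t(sl))
    expect_true(all(is.na(diag(sl))))
    expect_true(all(is.finite(sl[upper.tri(sl)])))
  }
})

test_that("residualisation removes a planted age effect and nothing else", {
  # hand-built stack: 400 subjects, tiny matrices, one entry tied to age
  n_sub <- 400
  set.seed(81)
  ages <- runif(n_sub, 60, 90)
  arrays <- lapply(seq_len(n_sub), function(i) {
    a <- toy_windows(3, 4, seed = 1000 + i, noise = 0.05)
    a[, 1, 2] <- a[, 1, 2] + 0.03 * ages[i]
    a[, 2, 1] <- a[, 1, 2]
    a
  })
  stack <- toy_stack(arrays, ages = ages)
  res <- residualize_stack(stack, "age")
  sub_mean <- vapply(res$z, function(a) mean(a[, 1, 2]), numeric(1))
  expect_lt(abs(cor(sub_mean, ages)), 0.02)
  expect_true(attr(res, "residualized"))

  # covariates orthogonal to every entry: output = input
  null_stack <- toy_stack(lapply(1:8, function(i) toy_windows(4, 4, seed = i)),
                          ages = rep(70, 8) + rep(c(-1, 1), 4))
  # zero planted coefficients: regression fit is pure noise removal of means;
  # with a covariate uncorrelated with entries the change must be tiny
  res0 <- residualize_stack(null_stack, "age")
  delta <- max(abs(unlist(res0$z) - unlist(null_stack$z)), na.rm = TRUE)
  expect_lt(delta, 0.5)

  # constant covariate column: collinear with the intercept
  bad <- toy_stack(lapply(1:4, function(i) toy_windows(3, 4, seed = i)),
                   ages = rep(75, 4))
  expect_error(residualize_stack(bad, "age"), "collinear")
})

test_that("exactly orthogonal covariates leave the stack unchanged", {
  # construct subject means exactly orthogonal to the centred covariate
  arrays <- lapply(1:4, function(i) {
    a <- array(0.2, c(2, 3, 3))
    for (w in 1:2) diag(a[w, , ]) <- NA
    a
  })
  stack <- toy_stack(arrays, ages = c(70, 72, 74, 76))
  res <- residualize_stack(stack, "age")
  expect_equal(unlist(res$z), unlist(stack$z), tolerance = 1e-10)
})
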