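test_that("residualization removes covariate variance and matches the hat-matrix oracle", {
  set.seed(61)
  n <- 80
  cov <- data.frame(sex = sample(c("female", "male"), n, TRUE),
                    education = sample(8:18, n, TRUE))
  X <- matrix(rnorm(n * 12), n)
  R <- residualize(X, cov)
  D <- model.matrix(~ sex + education, cov)
  H <- D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(R, (diag(n) - H) %*% X, tolerance = 1e-10,
               ignore_attr = TRUE)
  # a predictor that is an exact linear function of education vanishes
  X2 <- cbind(3 * cov$education - 7, X)
  expect_lt(max(abs(residualize(X2, cov)[, 1])), 1e-10)
  # a predictor orthogonal to the covariate design is untouched
  o <- unname(resid(lm(X[, 1] ~ D - 1)))
  expect_equal(residualize(matrix(o), cov)[, 1], o, tolerance = 1e-10)
  # rank-deficient design is refused
  bad <- data.frame(education = cov$education, twice = 2 * cov$education)
  expect_error(residualize(X, bad), "rank")
})

test_that("NIPALS matches the SIMPLS oracle and, at full rank, least squares", {
  set.seed(62)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 30), 50)
    y <- rnorm(50)
    newX <- matrix(rnorm(20 * 30), 20)
    fit <- nipalsFit(X, y, ncomp = 8)
    expect_equal(predict(fit, newX, ncomp = 1:8),
                 simplsPredict(X, y, newX, 8),
                 tolerance = 1e-8, ignore_attr = TRUE)
    full <- nipalsFit(X, y, ncomp = 30)
    expect_equal(predict(full, newX),
                 olsPredict(X, y, newX), tolerance = 1e-8)
  }
  # y equal to one of mutually orthogonal predictors: one component is exact
  X <- unclass(poly(1:40, 5))
  y <- X[, 3]
  f1 <- nipalsFit(X, y, ncomp = 1)
  expect_gt(cor(predict(f1, X), y)^2, 1 - 1e-10)
  expect_equal(predict(f1, X), y, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("NIPALS agrees with an external PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(68)
  X <- matrix(rnorm(60 * 20), 60, dimnames = list(NULL, paste0("v", 1:20)))
  y <- drop(X %*% rnorm(20)) + rnorm(60)
  newX <- matrix(rnorm(12 * 20), 12, dimnames = list(NULL, colnames(X)))
  fit <- nipalsFit(X, y, ncomp = 4)
  ext <- mixOmics::pls(X, matrix(y, dimnames = list(NULL, "y")),
                       ncomp = 4, mode = "regression", scale = FALSE)
  pr <- predict(ext, newX)$predict[, 1, ]
  expect_equal(predict(fit, newX, ncomp = 1:4), pr, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("score vectors are orthogonal and explained variance is monotone", {
  set.seed(63)
  X <- matrix(rnorm(60 * 25), 60)
  y <- X %*% rnorm(25) + rnorm(60)
  fit <- nipalsFit(X, y, ncomp = 6)
  G <- crossprod(plsScores(fit))
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  va <- varianceAccounting(fit, X, y)
  expect_true(all(diff(va$yVarianceExplained) >= -1e-10))
  expect_true(all(diff(va$xVarianceUsed) >= -1e-10))
  # at full rank the reconstruction uses all predictor variance
  Xs <- matrix(rnorm(30 * 5), 30)
  fullFit <- nipalsFit(Xs, rnorm(30), ncomp = 5)
  vaFull <- varianceAccounting(fullFit, Xs, rnorm(30))
  expect_equal(unname(vaFull$xVarianceUsed[5]), 100, tolerance = 1e-8)
  # toy reconstruction oracle: captured X sum-of-squares via T P'
  E <- sweep(X, 2, colMeans(X))
  recon <- plsScores(fit) %*% t(plsLoadings(fit))
  expect_equal(unname(va$xVarianceUsed[6]),
               100 * sum(recon^2) / sum(E^2), tolerance = 1e-8)
})

test_that("predictions are invariant to column order and joint sign flips", {
  set.seed(64)
  X <- matrix(rnorm(50 * 12), 50)
  y <- X %*% rnorm(12) + rnorm(50)
  newX <- matrix(rnorm(10 * 12), 10)
  fit <- nipalsFit(X, y, ncomp = 3)
  perm <- sample(12)
  fitP <- nipalsFit(X[, perm], y, ncomp = 3)
  expect_equal(predict(fitP, newX[, perm]), predict(fit, newX),
               tolerance = 1e-8)
  # flipping a component's weight/loading/score triple jointly
  flip <- fit
  for (j in c(1, 3)) {
    flip@weights[, j] <- -flip@weights[, j]
    flip@xLoadings[, j] <- -flip@xLoadings[, j]
    flip@scores[, j] <- -flip@scores[, j]
    flip@yLoadings[j] <- -flip@yLoadings[j]
  }
  expect_equal(predict(flip, newX), predict(fit, newX), tolerance = 1e-12)
})

test_that("leave-one-out RMSEP equals a brute-force refit oracle", {
  set.seed(65)
  X <- matrix(rnorm(30 * 8), 30)
  y <- X %*% rnorm(8) + rnorm(30)
  cv <- looRmsep(X, y, maxComponents = 3)
  err <- matrix(NA_real_, 30, 4)
  for (i in 1:30) {
    err[i, 1] <- (y[i] - mean(y[-i]))^2
    f <- nipalsFit(X[-i, ], y[-i], ncomp = 3)
    err[i, 2:4] <- (y[i] - predict(f, X[i, , drop = FALSE], ncomp = 1:3))^2
  }
  expect_equal(unname(rmsep(cv)), sqrt(colMeans(err)))
  expect_equal(unname(cv@looErrors), err)
  # constant response: the mean-only model is error-free
  cv0 <- looRmsep(X, rep(5, 30), maxComponents = 0)
  expect_equal(unname(rmsep(cv0)["0"]), 0)
})

test_that("component selection recovers planted dimensionality", {
  # two planted latent blocks on very different variance scales, both
  # informative: the high-variance block is extracted first, the
  # low-variance clean block supplies the genuine second component
  pick <- vapply(1:12, function(s) {
    set.seed(600 + s)
    n <- 200
    u1 <- rnorm(n); u2 <- rnorm(n)
    y <- 60 + 4 * u2 + 3 * u1 + rnorm(n, sd = 3)
    A <- outer(u2, rep(4, 40)) + matrix(rnorm(n * 40, sd = 1), n)
    B <- outer(u1, rep(0.2, 40)) + matrix(rnorm(n * 40, sd = 0.05), n)
    cv <- looRmsep(cbind(A, B), y, maxComponents = 4)
    selectNcomp(cv)
  }, integer(1))
  expect_gte(sum(pick == 2), 10)
  # a response independent of X selects the mean-only model most often
  pick0 <- vapply(1:9, function(s) {
    set.seed(700 + s)
    X <- matrix(rnorm(80 * 30), 80)
    cv <- looRmsep(X, rnorm(80), maxComponents = 3)
    selectNcomp(cv)
  }, integer(1))
  expect_gte(sum(pick0 == 0), 5)
})

test_that("scrambled nulls preserve marginals and destroy dependence", {
  set.seed(66)
  u <- rnorm(300)
  X <- cbind(u + rnorm(300, sd = 0.2), u + rnorm(300, sd = 0.2),
             matrix(rnorm(300 * 3), 300))
  y <- u + rnorm(300, sd = 0.5)
  nd <- scrambledNull(X, y)
  expect_equal(apply(nd$X, 2, sort), apply(X, 2, sort))
  expect_equal(sort(nd$y), sort(y))
  expect_gt(cor(X[, 1], X[, 2]), 0.8)
  expect_lt(abs(cor(nd$X[, 1], nd$X[, 2])), 0.2)
  expect_lt(abs(cor(nd$X[, 1], nd$y)), 0.2)
})

test_that("repeated splits have the documented sizes and behavior", {
  set.seed(67)
  X <- matrix(rnorm(573 * 5), 573)
  y <- X %*% rnorm(5) + rnorm(573)
  ens <- repeatedSplits(X, y, trainFraction = 0.8, nReps = 3, ncomp = 2,
                        seed = 1)
  expect_true(all(lengths(ens@trainIndices) == 458))
  expect_equal(nrow(X) - length(ens@trainIndices[[1]]), 115)
  # train/test disjoint
  expect_length(intersect(ens@trainIndices[[1]],
                          setdiff(seq_len(573), ens@trainIndices[[1]])), 0)
  ens2 <- repeatedSplits(X[1:100, ], y[1:100], trainFraction = 0.7,
                         nReps = 2, ncomp = 1, seed = 1)
  expect_true(all(lengths(ens2@trainIndices) == 70))
  # a perfect noiseless linear signal is predicted exactly
  yy <- drop(X[1:100, ] %*% c(1, -2, 0.5, 3, -1))
  ens3 <- repeatedSplits(X[1:100, ], yy, trainFraction = 0.8, nReps = 4,
                         ncomp = 5, seed = 2)
  expect_true(all(ens3@testR[, 5] > 1 - 1e-8))
  expect_true(all(ens3@testRmsep[, 5] < 1e-6))
  # reproducible from the master seed
  ensA <- repeatedSplits(X, y, nReps = 2, ncomp = 1, seed = 42)
  ensB <- repeatedSplits(X, y, nReps = 2, ncomp = 1, seed = 42)
  expect_identical(ensA@trainIndices, ensB@trainIndices)
  expect_equal(ensA@testR, ensB@testR)
  expect_error(repeatedSplits(X, y, trainFraction = 0.97, nReps = 2,
                              ncomp = 1), "trainFraction")
})
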