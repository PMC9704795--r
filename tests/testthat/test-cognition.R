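mkBattery <- function(n, seed = 1, latent = NULL) {
  set.seed(seed)
  if (is.null(latent)) latent <- rnorm(n)
  tests <- sapply(1:16, function(t) 0.8 * latent + rnorm(n, sd = 0.5))
  colnames(tests) <- sprintf("test_%02d", 1:16)
  data.frame(subject_id = sprintf("s%03d", 1:n),
             age = runif(n, 55, 85),
             sex = sample(rep(c("female", "male"), length.out = n)),
             education = sample(8:18, n, TRUE), tests)
}

test_that("screening excludes heavy missingness and imputes by stratum median", {
  bat <- mkBattery(60, seed = 51)
  bat$age[1:10] <- 57; bat$age[11:20] <- 70   # known strata
  bat$sex[1:20] <- "female"
  b2 <- bat
  b2[1, sprintf("test_%02d", 1:3)] <- NA       # 3 missing -> excluded
  b2[2, "test_05"] <- NA                       # 1 missing -> imputed
  out <- screenAndImpute(b2)
  expect_false("s001" %in% out$subject_id)
  expect_equal(nrow(out), 59)
  # oracle: median of test_05 in the (female, 55-64) stratum, computed by
  # hand over the retained subjects with an observed value
  donors <- b2$sex == "female" & b2$age < 65 &
    !b2$subject_id %in% c("s001", "s002")
  expect_equal(out$test_05[out$subject_id == "s002"],
               median(b2$test_05[donors]))
  # a battery without missing values passes through unchanged
  expect_identical(screenAndImpute(bat), bat)
})

test_that("outlier exclusion follows the 3-SD rule with safe edge cases", {
  # all scores equal: the zero-SD edge case excludes nobody
  bat <- mkBattery(50, seed = 52)
  bat[sprintf("test_%02d", 1:16)] <- 5
  expect_equal(nrow(excludeOutliers(bat)), 50)
  # bounded scores (uniform: max deviation < 3 SD) with a planted spike:
  # exactly the spiked subject is removed
  b2 <- bat
  set.seed(520)
  b2[sprintf("test_%02d", 1:16)] <- matrix(runif(50 * 16), 50)
  b2$test_02[7] <- mean(b2$test_02) + 5.5 * sd(b2$test_02)
  out <- excludeOutliers(b2)
  expect_false("s007" %in% out$subject_id)
  expect_equal(nrow(out), 49)
  # Gaussian exclusion fraction near 1 - (1 - 2 phi(-3))^k for k tests
  set.seed(53)
  G <- data.frame(subject_id = as.character(1:10000),
                  test_01 = rnorm(10000), test_02 = rnorm(10000),
                  test_03 = rnorm(10000), test_04 = rnorm(10000))
  frac <- 1 - nrow(excludeOutliers(G)) / 10000
  expect_lt(abs(frac - (1 - (1 - 2 * pnorm(-3))^4)), 0.004)
})

test_that("KMO distinguishes factor-structured from independent batteries", {
  set.seed(54)
  lat <- rnorm(400)
  common <- sapply(1:8, function(i) lat + rnorm(400, sd = 0.4))
  expect_gt(kmo(common), 0.8)
  indep <- matrix(rnorm(400 * 8), 400)
  expect_lt(kmo(indep), 0.6)
  # scale-free: per-column linear rescaling changes nothing
  resc <- sweep(sweep(common, 2, 1:8, "*"), 2, seq(10, 80, 10), "+")
  expect_equal(kmo(resc), kmo(common), tolerance = 1e-12)
  # singular correlation matrix is refused
  sing <- cbind(common, common[, 1])
  expect_error(kmo(sing), "singular")
})

test_that("PCA composite is unit-norm, majority-positive and standardized", {
  bat <- mkBattery(200, seed = 55)
  comp <- pcaCog(bat)
  expect_equal(sum(cogLoadings(comp)^2), 1)
  expect_gt(mean(cogLoadings(comp) > 0), 0.5)
  expect_equal(mean(cogScores(comp)), 0, tolerance = 1e-12)
  expect_equal(sd(cogScores(comp)), 1, tolerance = 1e-12)
  # explained share equals the leading eigenvalue share of the
  # correlation matrix (closed-form eigenstructure oracle)
  X <- as.matrix(bat[, sprintf("test_%02d", 1:16)])
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(comp@explainedVariance, ev[1] / sum(ev), tolerance = 1e-10)
  # two orthogonal halves of equal variance: first PC explains ~50%
  set.seed(56)
  a <- rnorm(2000); b <- rnorm(2000)
  half <- cbind(sapply(1:8, function(i) a + rnorm(2000, sd = 0.05)),
                sapply(1:8, function(i) b + rnorm(2000, sd = 0.05)))
  colnames(half) <- sprintf("test_%02d", 1:16)
  hb <- data.frame(subject_id = as.character(1:2000), age = 70,
                   sex = "female", education = 12, half)
  expect_lt(abs(pcaCog(hb)@explainedVariance - 0.5), 0.03)
  expect_error(pcaCog(bat[1:10, ]), "fewer")
})

test_that("cognition pipeline recovers the planted negative age effect", {
  coh <- simulateCohort(250, nNodes = 20, seed = 57)
  res <- cognitionComposite(subjectTable(coh))
  comp <- res$composite
  age <- subjectTable(coh)$age[match(comp@subjectIds,
                                     subjectTable(coh)$subject_id)]
  expect_lt(cor(age, cogScores(comp)), -0.2)
  expect_gt(comp@kmo, 0.8)
  # screening/imputation of an already-clean battery is a no-op
  expect_identical(screenAndImpute(res$battery), res$battery)
})

test_that("the cleaning pipeline is a no-op on a battery without extremes", {
  set.seed(58)
  n <- 120
  lat <- runif(n, -1, 1)
  tests <- sapply(1:16, function(t) 0.7 * lat + runif(n, -0.5, 0.5))
  colnames(tests) <- sprintf("test_%02d", 1:16)
  bat <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    age = runif(n, 55, 85),
                    sex = sample(rep(c("female", "male"), length.out = n)),
                    education = 12, tests)
  res <- cognitionComposite(bat)
  expect_equal(nrow(res$battery), n)
  again <- cognitionComposite(res$battery)
  expect_identical(again$battery, res$battery)
  expect_equal(cogScores(again$composite), cogScores(res$composite))
})
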