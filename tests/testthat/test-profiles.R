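mkEnsemble <- function(seed = 71, n = 120, p = 15, ncomp = 2, nReps = 6) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n,
              dimnames = list(NULL, c(sprintf("v%02d", 1:(p - 1)), "COG")))
  y <- X %*% rnorm(p) + rnorm(n)
  list(X = X, y = drop(y),
       ens = repeatedSplits(X, y, nReps = nReps, ncomp = ncomp, seed = seed))
}

test_that("sign/order alignment undoes arbitrary flips and preserves predictions", {
  d <- mkEnsemble()
  ali <- alignSigns(d$ens)
  expect_true(ali@aligned)
  # flipping replicates at random must align back to the same loadings
  flipped <- d$ens
  set.seed(72)
  for (r in seq_along(flipped@trainIndices)) {
    s <- sample(c(-1, 1), 2, TRUE)
    flipped@xLoadings[, , r] <- sweep(flipped@xLoadings[, , r], 2, s, "*")
    flipped@weights[, , r] <- sweep(flipped@weights[, , r], 2, s, "*")
    flipped@yLoadings[, r] <- flipped@yLoadings[, r] * s
  }
  ali2 <- alignSigns(flipped)
  expect_equal(ali2@xLoadings, ali@xLoadings, tolerance = 1e-12)
  expect_equal(ali2@yLoadings, ali@yLoadings, tolerance = 1e-12)
  # joint flips leave the regression coefficients (hence predictions) alone
  r1 <- d$ens
  W <- r1@weights[, , 1]; P <- r1@xLoadings[, , 1]; q <- r1@yLoadings[, 1]
  bBefore <- W %*% solve(crossprod(P, W)) %*% q
  s <- c(-1, 1)
  W2 <- sweep(W, 2, s, "*"); P2 <- sweep(P, 2, s, "*"); q2 <- q * s
  bAfter <- W2 %*% solve(crossprod(P2, W2)) %*% q2
  expect_equal(bAfter, bBefore, tolerance = 1e-12)
  # mismatched reference depth is refused
  set.seed(73)
  ref1 <- nipalsFit(d$X, d$y, ncomp = 3)
  expect_error(alignSigns(d$ens, ref1), "depth")
})

test_that("mean loadings average replicates and follow the age-decrease orientation", {
  d <- mkEnsemble(seed = 74)
  ali <- alignSigns(d$ens)
  profs <- meanLoadings(ali, d$y)
  expect_length(profs, 2)
  # streaming-free recompute oracle for mean and SD, up to the final
  # orientation sign
  for (k in 1:2) {
    mu <- rowMeans(ali@xLoadings[, k, ])
    s <- apply(ali@xLoadings[, k, ], 1, sd)
    rec <- c(profs[[k]]@predictorMeans, COG = profs[[k]]@cogMean)
    flip <- if (cor(ali@reference@scores[, k], d$y) > 0) -1 else 1
    expect_equal(unname(rec[names(mu)]), unname(flip * mu))
    expect_equal(unname(c(profs[[k]]@predictorSds,
                          profs[[k]]@cogSd)[seq_along(s)]), unname(s))
    # orientation: scores anti-correlate with age
    expect_lte(profs[[k]]@ageCorrelation, 0)
  }
  # single-replicate ensemble: mean is that replicate, SD is zero
  one <- alignSigns(repeatedSplits(d$X, d$y, nReps = 1, ncomp = 2, seed = 9))
  p1 <- meanLoadings(one, d$y)
  expect_true(all(p1[[1]]@predictorSds == 0))
  expect_error(meanLoadings(d$ens, d$y), "align")
})

test_that("network averages equal a group-by oracle and respect families", {
  parc <- makeParcellation(20)
  set.seed(75)
  vals <- rnorm(120)
  names(vals) <- featureNames(parc, includeCog = FALSE)
  prof <- new("AgingProfile", component = 1L, predictorMeans = vals,
              predictorSds = abs(rnorm(120)), cogMean = 0.1, cogSd = 0.01,
              networkSummary = data.frame(), ageCorrelation = -0.4,
              ageCorrelationP = 1e-5)
  ns <- networkMeanLoadings(prof, parc)
  tags <- agingProfiles:::featureTags(parc, includeCog = FALSE)
  for (i in sample(nrow(ns), 10)) {
    sel <- tags$network == ns$network[i] & tags$kind == ns$kind[i] &
      tags$scope == ns$scope[i]
    expect_equal(ns$meanLoading[i], mean(vals[tags$predictor[sel]]))
  }
  # constant profile: every network average equals the constant
  prof2 <- prof; prof2@predictorMeans[] <- 0.25
  expect_true(all(networkMeanLoadings(prof2, parc)$meanLoading == 0.25))
  # one-node family average equals that node's loading
  one <- tags$predictor[tags$network == "LN" & tags$kind == "SC" &
                          tags$scope == "intra"][1]
  expect_true(any(abs(ns$meanLoading - vals[one]) < 1e-12) ||
                sum(tags$network == "LN" & tags$kind == "SC" &
                      tags$scope == "intra") > 1)
})

test_that("frontal-vs-rest test matches the textbook pooled t and its edge cases", {
  parc <- makeParcellation(40, frontalFraction = 0.5)
  lob <- nodeLobes(parc)
  vals <- numeric(240)
  names(vals) <- featureNames(parc, includeCog = FALSE)
  tags <- agingProfiles:::featureTags(parc, includeCog = FALSE)
  sel <- tags$kind == "SC" & tags$scope == "intra"
  set.seed(76)
  base <- rnorm(sum(lob == "frontal"))
  # identical group values: zero mean difference
  vals[tags$predictor[sel & tags$lobe == "frontal"]] <- base
  vals[tags$predictor[sel & tags$lobe == "other"]] <-
    rep(base, length.out = sum(lob == "other"))
  prof <- new("AgingProfile", component = 1L, predictorMeans = vals,
              predictorSds = vals * 0, cogMean = 0, cogSd = 0,
              networkSummary = data.frame(), ageCorrelation = -0.3,
              ageCorrelationP = 0.001)
  idT <- frontalVsRestTest(prof, parc, "SC_intra")
  expect_equal(idT$t, 0, tolerance = 1e-12)
  expect_equal(idT$p, 1, tolerance = 1e-12)
  # random groups: equality with a hand-computed pooled t
  vals[tags$predictor[sel]] <- rnorm(40)
  prof@predictorMeans <- vals
  got <- frontalVsRestTest(prof, parc, "SC_intra")
  a <- vals[tags$predictor[sel & tags$lobe == "frontal"]]
  b <- vals[tags$predictor[sel & tags$lobe == "other"]]
  expect_equal(got$t, pooledT(a, b), tolerance = 1e-10)
  # a +3-SD frontal shift is detected decisively
  shift <- vals
  shift[tags$predictor[sel & tags$lobe == "frontal"]] <-
    shift[tags$predictor[sel & tags$lobe == "frontal"]] + 3 * sd(b)
  prof@predictorMeans <- shift
  expect_lt(frontalVsRestTest(prof, parc, "SC_intra")$p, 0.001)
  expect_error(frontalVsRestTest(prof, parc, "NOPE_intra"), "family")
})

test_that("component-age correlations use the shared correlation kernel", {
  set.seed(77)
  n <- 500
  X <- matrix(rnorm(n * 10), n)
  age <- runif(n, 55, 85)
  fit <- nipalsFit(X, age, ncomp = 2)
  cc <- componentAgeCorrelation(fit, age)
  for (k in 1:2)
    expect_equal(cc$r[k], bruteCor(plsScores(fit)[, k], age),
                 tolerance = 1e-12)
  # scores equal to age give r = 1
  perfect <- fit
  perfect@scores[, 1] <- age
  expect_equal(componentAgeCorrelation(perfect, age)$r[1], 1)
  # independent scores stay near zero at this sample size
  expect_lt(abs(cc$r[1]), 0.15)
})
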