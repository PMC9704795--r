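test_that("parcellation construction is deterministic and validated", {
  p <- makeParcellation(400)
  expect_equal(nNodes(p), 400)
  expect_length(featureNames(p, includeCog = FALSE), 2400)
  expect_length(featureNames(p, includeCog = TRUE), 2401)
  expect_setequal(unique(nodeNetworks(p)), agingProfiles:::CANONICAL_NETWORKS)
  # deterministic: same arguments give the identical label table
  expect_identical(nodeTable(p), nodeTable(makeParcellation(400)))
  # several networks span both lobes
  spans <- tapply(nodeLobes(p) == "frontal", nodeNetworks(p),
                  function(x) any(x) && !all(x))
  expect_gte(sum(spans), 4)

  eq <- makeParcellation(14, networkSizes = c(VN = 2, SMN = 2, LN = 2,
                                              FPN = 2, DMN = 2, DAN = 2,
                                              VAN = 2))
  expect_true(all(table(nodeNetworks(eq)) == 2))
  expect_error(makeParcellation(13), "14")
  expect_error(makeParcellation(20, networkSizes = c(VN = 2, SMN = 2,
                                                     LN = 2, FPN = 2,
                                                     DMN = 2, DAN = 2,
                                                     VAN = 2)),
               "sum")
})

test_that("simulated time series have the requested length and network structure", {
  parc <- makeParcellation(21)
  tr <- makeGroundTruth(parc)
  set.seed(1)
  ts <- simulateTimeSeries(70, parc, tr, nVolumes = 300, discardVolumes = 4)
  expect_equal(dim(ts), c(21, 296))
  expect_error(simulateTimeSeries(70, parc, tr, nTimepoints = 20), "32")

  # zero noise, one latent per network: within-network |r| = 1
  tr0 <- makeGroundTruth(parc, noise = c(ts = 0, sc = 0.3, cog = 0.35),
                         couplings = list(global = 0, fcIntra = 0))
  set.seed(2)
  ts0 <- simulateTimeSeries(60, parc, tr0)
  r <- connValues(pearsonFC(ts0))
  same <- outer(nodeNetworks(parc), nodeNetworks(parc), "==")
  diag(same) <- FALSE
  expect_true(all(abs(abs(r[same]) - 1) < 1e-10))

  # default parameters: mean intra-network r exceeds mean inter-network r
  set.seed(3)
  rs <- replicate(25, {
    age <- runif(1, 55, 85)
    r1 <- connValues(pearsonFC(simulateTimeSeries(age, parc, tr)))
    c(mean(r1[same]), mean(r1[!same & !diag(21)]))
  })
  expect_gt(mean(rs[1, ]), mean(rs[2, ]))
})

test_that("structural weights decline faster on frontal-incident edges", {
  coh <- simulateCohort(120, nNodes = 30, seed = 5)
  parc <- parcellation(coh)
  f <- nodeLobes(parc) == "frontal"
  fe <- outer(f, f, "|"); ut <- upper.tri(fe)
  sl <- vapply(streamlineWeights(coh), function(w)
    c(mean(log(w[fe & ut])), mean(log(w[!fe & ut]))), numeric(2))
  age <- subjectTable(coh)$age
  bF <- coef(lm(sl[1, ] ~ age))[2]
  bO <- coef(lm(sl[2, ] ~ age))[2]
  expect_lt(bF, bO)        # more negative frontally
  expect_lt(bO, 0)
  # with zero decline rates the expected weights are age-independent
  tr0 <- makeGroundTruth(parc, frontalDeclineRate = 0, otherDeclineRate = 0)
  set.seed(9)
  w1 <- simulateSC(56, parc, tr0, latents = c(1, 0))
  set.seed(9)
  w2 <- simulateSC(84, parc, tr0, latents = c(1, 0))
  expect_equal(w1, w2)
  expect_true(isSymmetric(w1) && min(w1) >= 0 && all(diag(w1) == 0))
  expect_error(simulateSC(40, parc, tr0), "range")
})

test_that("cognition battery is calibrated to the target age correlation", {
  parc <- makeParcellation(21)
  tr <- makeGroundTruth(parc)
  set.seed(11)
  age <- runif(573, 55, 85)
  lat <- agingProfiles:::drawLatents(age, tr)
  latC <- vapply(seq_along(age), function(i)
    simulateCognition(age[i], tr, latents = lat[i, ])$latent, numeric(1))
  expect_lt(abs(cor(age, latC) - (-0.44)), 0.08)

  # zero unique noise: all 16 scores perfectly correlated
  tr0 <- makeGroundTruth(parc, noise = c(ts = 1, sc = 0.3, cog = 0))
  set.seed(12)
  sc0 <- t(replicate(40, simulateCognition(runif(1, 55, 85), tr0)$scores))
  cm <- cor(sc0)
  expect_true(all(abs(cm) > 1 - 1e-10))

  # missingness control
  set.seed(13)
  expect_false(anyNA(simulateCognition(70, tr, missingRate = 0)$scores))
  miss <- mean(is.na(replicate(400,
    simulateCognition(70, tr, missingRate = 0.3)$scores)))
  expect_lt(abs(miss - 0.3), 0.05)
})

test_that("cohorts are reproducible bit-for-bit from their seed", {
  a <- simulateCohort(6, nNodes = 20, seed = 99)
  b <- simulateCohort(6, nNodes = 20, seed = 99)
  expect_identical(subjectTable(a), subjectTable(b))
  expect_identical(timeSeries(a), timeSeries(b))
  expect_identical(streamlineWeights(a), streamlineWeights(b))
  c2 <- simulateCohort(6, nNodes = 20, seed = 100)
  expect_false(identical(timeSeries(a), timeSeries(c2)))
  # serialized byte-for-byte
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  writeCohort(a, d1); writeCohort(b, d2)
  h1 <- unname(tools::md5sum(list.files(d1, full.names = TRUE)))
  h2 <- unname(tools::md5sum(list.files(d2, full.names = TRUE)))
  expect_identical(h1, h2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted loadings are finite, signed as designed, and frontal-weighted", {
  parc <- makeParcellation(35)
  tr <- makeGroundTruth(parc)
  L <- tr@componentLoadings
  expect_true(all(is.finite(L)))
  expect_equal(nrow(L), 6 * 35 + 1)
  # structural profile: positive (decline) loadings, frontal above rest
  sc <- L[grep("SC_intra", rownames(L)), 1]
  expect_true(all(sc > 0))
  f <- nodeLobes(parc) == "frontal"
  expect_gt(mean(sc[f]), mean(sc[!f]))
  # functional profile: intra decline, inter rise
  expect_true(all(L[grep("FCpos_intra", rownames(L)), 2] > 0))
  expect_true(all(L[grep("FCpos_inter", rownames(L)), 2] < 0))
  expect_gt(L["COG", 2], 0)
})
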