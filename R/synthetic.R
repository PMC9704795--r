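# Age is drawn uniform on [55, 85]; its SD enters the latent scaling.
AGE_RANGE <- c(55, 85)
AGE_SD <- diff(AGE_RANGE) / sqrt(12)
AGE_MID <- mean(AGE_RANGE)

defaultCouplings <- function() {
  list(
    intra = 1,          # node coupling onto its network latent signal
    global = 0.5,       # node coupling onto the shared global signal
    fcIntra = 0.12,     # per-SD decrease of intra coupling with the FC latent
    fcInter = 0.10,     # per-SD increase of global coupling with the FC latent
    negBase = 0.3,      # anti-coupling base for the optional third component
    fcNeg = 0.5,        # per-SD growth of the anti-coupling
    cogWeights = c(0, 1, 0.2),  # latent weights entering the COG latent
    scBaseMean = 1.0,   # mean baseline log edge weight
    scBaseSd = 0.5,     # between-edge spread of baseline log weights
    scIntraBonus = 0.4, # extra baseline log weight for within-network edges
    sexEffectSC = 0.05, # additive log-weight shift for male subjects
    eduEffect = 0.15,   # education effect on every cognitive test (z units)
    arPhi = 0.3,        # AR(1) coefficient of the latent BOLD-like signals
    testLoadings = seq(0.95, 0.5, length.out = 16),
    testOffsets = 20 + 3 * (1:16),
    testScales = rep(5, 16),
    baselineSeed = 1L   # internal seed fixing the SC baseline structure
  )
}

#' Construct the planted ground truth for a synthetic cohort
#'
#' Encodes the latent structure the generator plants: per-component signed
#' predictor loadings (in feature space, oriented so positive = lower value
#' at higher age), the target age-cognition correlation, and the per-year
#' structural decline rates with their frontal emphasis. Component 1 is a
#' structural profile (log edge weights decline with age, faster on
#' frontal-incident edges, accompanied by cognitive decline); component 2 is
#' a functional rebalancing profile (intra-network coupling down,
#' cross-network coupling up); an optional component 3 plants growing
#' cross-network anti-correlations.
#'
#' @param parc a \code{\linkS4class{Parcellation}}.
#' @param nComponents 2 (default) or 3 planted components.
#' @param ageEffectCog target correlation between age and the cognition
#'   latent; default -0.44.
#' @param frontalDeclineRate,otherDeclineRate per-year slopes of log edge
#'   weight for frontal-incident vs. remaining edges (defaults -0.004 and
#'   -0.00133, i.e. a few tenths of a percent per year, three times
#'   steeper on frontal-incident edges).
#' @param noise named numeric: noise SDs for channels \code{ts} (BOLD
#'   residual), \code{sc} (log edge weight) and \code{cog} (per-test unique
#'   noise); defaults \code{c(ts = 1, sc = 0.3, cog = 0.35)}.
#' @param latentAgeCor correlations of the planted latents with age;
#'   defaults 0.55 for the structural latent and \code{|ageEffectCog|} for
#'   the functional/cognitive latent (the cognition latent is then a clean
#'   readout of the functional one, making the age-cognition calibration
#'   exact by construction), plus 0.3 for a third component.
#' @param couplings optional list overriding entries of the internal
#'   coupling defaults (see \code{agingProfiles:::defaultCouplings}).
#' @param nTimepoints acquisition length the planted loading computation
#'   refers to (finite-length sampling shifts the expected sign-split FC
#'   strengths; default 296).
#'
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
makeGroundTruth <- function(parc, nComponents = 2L, ageEffectCog = -0.44,
                            frontalDeclineRate = -0.004,
                            otherDeclineRate = -0.00133,
                            noise = c(ts = 1, sc = 0.3, cog = 0.35),
                            latentAgeCor = NULL, couplings = list(),
                            nTimepoints = 296L) {
  stopifnot(is(parc, "Parcellation"))
  nComponents <- as.integer(nComponents)
  if (!nComponents %in% c(2L, 3L))
    stop("nComponents must be 2 or 3")
  cp <- utils::modifyList(defaultCouplings(), couplings)
  if (is.null(latentAgeCor))
    latentAgeCor <- c(0.55, min(abs(ageEffectCog), 0.9),
                      0.3)[seq_len(nComponents)]
  if (length(latentAgeCor) != nComponents || any(abs(latentAgeCor) >= 1) ||
      latentAgeCor[1] <= 0.05)
    stop("latentAgeCor must give one correlation in (0.05, 1) per component")
  if (sum(latentAgeCor^2) >= 1)
    stop("latent age correlations too strong jointly (sum of squares >= 1)")

  # cognition latent: C = -(b . u + b0 e) / norm, solved so that
  # cor(C, age) = ageEffectCog given the latent-age correlations
  b <- cp$cogWeights[seq_len(nComponents)]
  a <- latentAgeCor
  latCov <- diag(nComponents)   # latents are mutually uncorrelated
  signal <- sum(b * a)
  varB <- drop(t(b) %*% latCov %*% b)
  if (abs(ageEffectCog) > 1e-12) {
    b0sq <- (signal / abs(ageEffectCog))^2 - varB
    if (b0sq < 0)
      stop("ageEffectCog magnitude too large for the configured couplings")
  } else {
    b <- rep(0, nComponents); b0sq <- 1; signal <- 0
  }
  normC <- sqrt(varB + b0sq)

  params <- c(cp, list(latentAgeCor = a, cogB = b, cogB0 = sqrt(b0sq),
                       cogNorm = if (normC > 0) normC else 1,
                       baselineLog = scBaseline(parc, cp),
                       negSet = c("VN", "DAN"),
                       nTimepoints = as.integer(nTimepoints)))
  loadings <- plantedLoadings(parc, nComponents, frontalDeclineRate,
                              otherDeclineRate, params, noise)
  new("GroundTruth", nComponents = nComponents,
      componentLoadings = loadings, ageEffectCog = ageEffectCog,
      frontalDeclineRate = frontalDeclineRate,
      otherDeclineRate = otherDeclineRate,
      noise = noise, params = params)
}

# Deterministic baseline log edge weights; drawn under a private seed so the
# structural backbone is a property of the truth object, not of the cohort
# RNG stream.
scBaseline <- function(parc, cp) {
  n <- nNodes(parc)
  net <- nodeNetworks(parc)
  same <- outer(net, net, "==")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cp$baselineSeed)
  eps <- matrix(rnorm(n * n, sd = cp$scBaseSd), n, n)
  eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
  mu <- cp$scBaseMean + cp$scIntraBonus * same + eps
  diag(mu) <- -Inf  # no self-edges
  mu
}

# Signed planted loadings per predictor, in feature units per latent SD,
# oriented so positive = declines with age. Each loading is the analytic
# sensitivity of the expected strength feature to the planted latent,
# propagated through the generator model: log10(1 + w) for structural
# edges, and the sign-split Fisher-z correlation (with its finite-length
# sampling attenuation) for functional edges, both aggregated by the same
# strength formulas used downstream.
plantedLoadings <- function(parc, nComponents, frontalRate, otherRate,
                            pm, noise) {
  nd <- nodeTable(parc)
  n <- nrow(nd)
  net <- nd$network
  f <- nd$lobe == "frontal"
  nm <- featureNames(parc, includeCog = TRUE)
  L <- matrix(0, length(nm), nComponents,
              dimnames = list(nm, paste0("comp", seq_len(nComponents))))
  rowsOf <- function(fam) sprintf("node%03d_%s", nd$node_id, fam)
  cogSens <- pm$cogB / pm$cogNorm

  # component 1: structural decline, d log10(1+w)/d u1 per edge
  wbar <- exp(pm$baselineLog)
  rate <- ifelse(outer(f, f, "|"), frontalRate, otherRate)
  dSC <- rate * (AGE_SD / pm$latentAgeCor[1]) * (wbar / (1 + wbar)) / log(10)
  diag(dSC) <- 0
  st <- strengthTable(dSC, parc)
  L[rowsOf("SC_intra"), 1] <- -st$intra
  L[rowsOf("SC_inter"), 1] <- -st$inter
  L["COG", 1] <- cogSens[1]

  # functional components: edge-level dr through the coupling model
  lam <- pm$intra
  cvec <- rep(pm$global, n)
  if (nComponents >= 3L)
    cvec[net %in% pm$negSet] <- pm$global - pm$negBase
  same <- outer(net, net, "==")
  vi <- lam^2 + cvec^2 + noise[["ts"]]^2
  covM <- lam^2 * same + outer(cvec, cvec)
  sq <- sqrt(outer(vi, vi))
  rbar <- pmin(covM / sq, 1 - 1e-9)   # noiseless edges sit at the r -> 1 boundary
  zbar <- atanh(rbar)
  sigz <- 1 / sqrt(pm$nTimepoints - 3)
  for (cc in 2:nComponents) {
    if (cc == 2L) {
      dlam <- -pm$intra * pm$fcIntra
      dc <- rep(pm$global * pm$fcInter, n)
    } else {
      dlam <- 0
      dc <- ifelse(net %in% pm$negSet, -pm$negBase * pm$fcNeg, 0)
    }
    dcov <- 2 * lam * dlam * same + outer(dc, cvec) + outer(cvec, dc)
    dvi <- 2 * lam * dlam + 2 * cvec * dc
    rel <- outer(dvi / vi, rep(1, n)) + outer(rep(1, n), dvi / vi)
    dr <- (dcov - rbar * sq * rel / 2) / sq
    dz <- dr / (1 - rbar^2)
    dpos <- pnorm(zbar / sigz) * dz
    dneg <- -pnorm(-zbar / sigz) * dz
    diag(dpos) <- diag(dneg) <- 0
    stp <- strengthTable(dpos, parc)
    stn <- strengthTable(dneg, parc)
    L[rowsOf("FCpos_intra"), cc] <- -stp$intra
    L[rowsOf("FCpos_inter"), cc] <- -stp$inter
    L[rowsOf("FCneg_intra"), cc] <- -stn$intra
    L[rowsOf("FCneg_inter"), cc] <- -stn$inter
    L["COG", cc] <- cogSens[cc]
  }
  L
}

# Draw planted latent values conditional on age. Each latent u_c has unit
# variance and correlation a_c with age; the residuals are coupled so the
# latents are mutually uncorrelated (cov(u_c, u_d) = 0), mirroring the
# decomposition into independent components that the regression extracts.
drawLatents <- function(age, truth) {
  a <- truth@params$latentAgeCor
  z <- (age - AGE_MID) / AGE_SD
  k <- length(a)
  R <- -outer(a, a)
  diag(R) <- 1 - a^2
  U <- chol(R)
  e <- matrix(rnorm(length(age) * k), length(age), k) %*% U
  outer(z, a) + e
}

#' Simulate one subject's node-by-time BOLD-like series
#'
#' Latent-factor model: every node's signal is its network's shared AR(1)
#' latent signal plus a global AR(1) signal plus white noise. The planted
#' functional-aging latent shifts the balance: higher latent values (older
#' subjects, on average) weaken the intra-network coupling and strengthen
#' the cross-network (global) coupling, so intra-network correlations fall
#' and inter-network correlations rise with age. With a third planted
#' component, nodes of the anti-coupled network set couple negatively to the
#' global signal, creating cross-network anti-correlations that grow with
#' age.
#'
#' @param age subject age in years (within the generator range).
#' @param parc a \code{\linkS4class{Parcellation}}.
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param nTimepoints number of retained time points (default 296; at
#'   least 32). Ignored when \code{nVolumes} is given.
#' @param nVolumes optional number of acquired volumes; with
#'   \code{discardVolumes} initial volumes dropped, emulating the discard of
#'   pre-steady-state volumes (300 volumes minus 4 gives the default 296).
#' @param discardVolumes initial volumes to discard when \code{nVolumes}
#'   is given.
#' @param latents optional planted latent values for this subject (drawn
#'   conditional on age when missing).
#'
#' @return node x time numeric matrix.
#' @export
simulateTimeSeries <- function(age, parc, truth, nTimepoints = 296L,
                               nVolumes = NULL, discardVolumes = 0L,
                               latents = NULL) {
  nT <- if (!is.null(nVolumes)) as.integer(nVolumes) - as.integer(discardVolumes)
        else as.integer(nTimepoints)
  if (nT < 32L) stop("at least 32 retained time points are required")
  if (is.null(latents)) latents <- drawLatents(age, truth)
  cp <- truth@params
  u2 <- latents[2]
  u3 <- if (truth@nComponents >= 3L) latents[3] else 0

  net <- nodeNetworks(parc)
  netIdx <- match(net, CANONICAL_NETWORKS)
  nNet <- length(CANONICAL_NETWORKS)
  burn <- 20L
  phi <- cp$arPhi
  innov <- sqrt(1 - phi^2)
  G <- vapply(seq_len(nNet + 1L), function(k) {
    as.numeric(stats::filter(rnorm(nT + burn, sd = innov), phi,
                             method = "recursive"))[-seq_len(burn)]
  }, numeric(nT))

  lam <- max(cp$intra * (1 - cp$fcIntra * u2), 0.05)
  gam <- max(cp$global * (1 + cp$fcInter * u2), 0)
  g0coef <- rep(gam, length(net))
  if (truth@nComponents >= 3L) {
    neg <- net %in% cp$negSet
    g0coef[neg] <- gam - cp$negBase * max(1 + cp$fcNeg * u3, 0)
  }
  x <- lam * G[, netIdx, drop = FALSE] +
    outer(G[, nNet + 1L], g0coef)
  if (truth@noise[["ts"]] > 0)
    x <- x + matrix(rnorm(length(x), sd = truth@noise[["ts"]]), nrow(x))
  ts <- t(x)
  rownames(ts) <- sprintf("node%03d", nodeTable(parc)$node_id)
  ts
}

#' Simulate one subject's streamline-weight matrix
#'
#' Continuous positive weights on a log-normal scale around a fixed
#' structural backbone (stronger within networks). The planted structural
#' latent lowers log weights with age; frontal-incident edges decline at
#' \code{frontalDeclineRate} per year and all others at
#' \code{otherDeclineRate}, so the expected slope of mean frontal edge
#' weight on age is steeper than for non-frontal edges.
#'
#' @inheritParams simulateTimeSeries
#' @param sex optional \code{"female"}/\code{"male"}; males receive a small
#'   additive log-weight shift (removed downstream by residualization).
#'
#' @return symmetric non-negative node x node weight matrix, zero diagonal.
#' @export
simulateSC <- function(age, parc, truth, latents = NULL, sex = NULL) {
  if (age < AGE_RANGE[1] - 1e-9 || age > AGE_RANGE[2] + 1e-9)
    stop("age outside the generator range [55, 85]")
  if (is.null(latents)) latents <- drawLatents(age, truth)
  cp <- truth@params
  u1 <- latents[1]
  n <- nNodes(parc)
  f <- nodeLobes(parc) == "frontal"
  frontalEdge <- outer(f, f, "|")
  rate <- ifelse(frontalEdge, truth@frontalDeclineRate,
                 truth@otherDeclineRate)
  # scale so that the expected per-year slope of log weight equals the rate
  lw <- cp$baselineLog + rate * (AGE_SD / cp$latentAgeCor[1]) * u1
  if (!is.null(sex) && identical(sex, "male"))
    lw <- lw + cp$sexEffectSC
  if (truth@noise[["sc"]] > 0) {
    eps <- matrix(rnorm(n * n, sd = truth@noise[["sc"]]), n, n)
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    lw <- lw + eps
  }
  w <- exp(lw)
  diag(w) <- 0
  dimnames(w) <- rep(list(sprintf("node%03d", nodeTable(parc)$node_id)), 2)
  w
}

#' Simulate one subject's 16-test cognitive battery
#'
#' All tests share one dominant cognition latent that is negatively coupled
#' to age (target correlation \code{ageEffectCog}, default -0.44), with
#' per-test loadings, unique noise, test-native offsets/scales, an optional
#' additive education effect and an optional completely-at-random
#' missingness injector.
#'
#' @inheritParams simulateSC
#' @param education optional years of education (adds a small positive
#'   effect on every test when given).
#' @param missingRate probability that any single score is set missing.
#'
#' @return list with \code{scores} (named numeric, test_01..test_16) and
#'   \code{latent} (the subject's cognition latent value).
#' @export
simulateCognition <- function(age, truth, latents = NULL, education = NULL,
                              missingRate = 0) {
  if (is.null(latents)) latents <- drawLatents(age, truth)
  cp <- truth@params
  eC <- rnorm(1)
  C <- -(sum(cp$cogB * latents[seq_len(truth@nComponents)]) +
           cp$cogB0 * eC) / cp$cogNorm
  lam <- cp$testLoadings
  z <- lam * C
  if (truth@noise[["cog"]] > 0)
    z <- z + rnorm(16, sd = truth@noise[["cog"]])
  if (!is.null(education))
    z <- z + cp$eduEffect * (education - 13) / 2.5
  scores <- cp$testOffsets + cp$testScales * z
  names(scores) <- sprintf("test_%02d", 1:16)
  if (missingRate > 0)
    scores[runif(16) < missingRate] <- NA_real_
  list(scores = scores, latent = C)
}

#' Generate a full synthetic cohort
#'
#' Draws ages uniform on [55, 85], balanced sexes and an education
#' distribution, plants the latent aging components, and generates the
#' per-subject time series, streamline-weight matrices and cognitive
#' batteries. The cohort is bit-for-bit reproducible from its seed. The
#' planted latent values are kept in the subject table (columns
#' \code{latent_c*}, \code{latent_cog}) for recovery tests; they are
#' generator bookkeeping, not observables.
#'
#' @param nSubjects cohort size.
#' @param nNodes parcellation size (default 100, the package's test-scale
#'   default; use 400 for the full-scale scheme).
#' @param seed integer seed.
#' @param parcellation,truth optional pre-built
#'   \code{\linkS4class{Parcellation}} / \code{\linkS4class{GroundTruth}}.
#' @param nTimepoints retained time points per subject (default 296).
#' @param nVolumes,discardVolumes acquisition emulation: generate
#'   \code{nVolumes} volumes and discard the first \code{discardVolumes}
#'   (overrides \code{nTimepoints} when \code{nVolumes} is given).
#' @param missingRate completely-at-random missingness rate for cognitive
#'   scores.
#' @param nComponents number of planted components when \code{truth} is not
#'   supplied.
#' @param frontalFraction frontal node fraction when \code{parcellation} is
#'   not supplied.
#'
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @examples
#' coh <- simulateCohort(20, nNodes = 30, seed = 1)
#' coh
#' @export
simulateCohort <- function(nSubjects, nNodes = 100L, seed,
                           parcellation = NULL, truth = NULL,
                           nTimepoints = 296L, nVolumes = NULL,
                           discardVolumes = 4L, missingRate = 0,
                           nComponents = 2L, frontalFraction = 0.3) {
  seed <- as.integer(seed)
  set.seed(seed)
  if (is.null(parcellation))
    parcellation <- makeParcellation(nNodes,
                                     frontalFraction = frontalFraction)
  if (is.null(truth))
    truth <- makeGroundTruth(parcellation, nComponents = nComponents)
  n <- as.integer(nSubjects)

  age <- runif(n, AGE_RANGE[1], AGE_RANGE[2])
  sex <- sample(rep(c("female", "male"), length.out = n))
  education <- pmin(pmax(round(rnorm(n, 13, 2.5)), 8), 18)
  lat <- drawLatents(age, truth)
  if (n == 1L) lat <- matrix(lat, nrow = 1)

  ts <- vector("list", n)
  sc <- vector("list", n)
  tests <- matrix(NA_real_, n, 16,
                  dimnames = list(NULL, sprintf("test_%02d", 1:16)))
  cogLatent <- numeric(n)
  for (i in seq_len(n)) {
    ts[[i]] <- simulateTimeSeries(age[i], parcellation, truth,
                                  nTimepoints = nTimepoints,
                                  nVolumes = nVolumes,
                                  discardVolumes = discardVolumes,
                                  latents = lat[i, ])
    sc[[i]] <- simulateSC(age[i], parcellation, truth,
                          latents = lat[i, ], sex = sex[i])
    cg <- simulateCognition(age[i], truth, latents = lat[i, ],
                            education = education[i],
                            missingRate = missingRate)
    tests[i, ] <- cg$scores
    cogLatent[i] <- cg$latent
  }
  ids <- sprintf("sub-%04d", seq_len(n))
  names(ts) <- names(sc) <- ids
  subjects <- data.frame(subject_id = ids, age = age, sex = sex,
                         education = education, tests,
                         stringsAsFactors = FALSE)
  for (k in seq_len(truth@nComponents))
    subjects[[paste0("latent_c", k)]] <- lat[, k]
  subjects$latent_cog <- cogLatent
  new("SyntheticCohort", subjects = subjects, timeseries = ts, sc = sc,
      parcellation = parcellation, truth = truth, seed = seed)
}
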