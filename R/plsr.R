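# accept either a FeatureBlock (predictors x subjects, age in colData) or a
# plain subjects x predictors matrix plus response vector
xyFrom <- function(X, y = NULL) {
  if (is(X, "FeatureBlock")) {
    list(X = t(SummarizedExperiment::assay(X, "features")),
         y = SummarizedExperiment::colData(X)$age)
  } else {
    if (is.null(y)) stop("a response vector y is required with a plain matrix")
    list(X = as.matrix(X), y = as.numeric(y))
  }
}

#' Residualize predictors for nuisance covariates
#'
#' Replaces every predictor by the residuals of a least-squares fit on an
#' intercept plus the covariates (by default sex and education), so the
#' subsequent regression on age cannot pick up variance attributable to
#' them. The response (age) is untouched.
#'
#' @param X a \code{\linkS4class{FeatureBlock}} (covariates taken from
#'   \code{colData}) or a subjects x predictors matrix.
#' @param covariates covariate column names (FeatureBlock input) or a
#'   \code{data.frame} of covariate values (matrix input).
#' @return object of the same type with residualized predictor values.
#' @export
residualize <- function(X, covariates = c("sex", "education")) {
  if (is(X, "FeatureBlock")) {
    cd <- as.data.frame(SummarizedExperiment::colData(X))
    miss <- setdiff(covariates, colnames(cd))
    if (length(miss)) stop("covariate(s) not found: ",
                           paste(miss, collapse = ", "))
    cov <- cd[, covariates, drop = FALSE]
    mat <- t(SummarizedExperiment::assay(X, "features"))
    res <- residualizeMatrix(mat, cov)
    SummarizedExperiment::assay(X, "features") <- t(res)
    return(X)
  }
  residualizeMatrix(as.matrix(X), as.data.frame(covariates))
}

residualizeMatrix <- function(mat, cov) {
  if (anyNA(cov)) stop("covariate values must be complete")
  D <- stats::model.matrix(~ ., data = cov)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("rank-deficient covariate design matrix")
  qr.resid(qrD, mat)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Nonlinear iterative partial least squares decomposition of the centered
#' (optionally unit-scaled) predictor block against a single centered
#' response: components are extracted one at a time by alternating
#' weight/score updates until the weight vector stabilizes (change below
#' \code{tol}, at most \code{maxIter} sweeps), followed by deflation of the
#' predictor block and response. Score vectors are mutually orthogonal by
#' construction.
#'
#' @param X \code{\linkS4class{FeatureBlock}} or subjects x predictors
#'   matrix.
#' @param y response (age in years); taken from \code{colData} for a
#'   FeatureBlock.
#' @param ncomp number of components (at most the predictor rank).
#' @param scale divide predictors by their SD before fitting? Default
#'   \code{FALSE}: predictors are centered but left on their native scale.
#' @param tol,maxIter inner-loop convergence control.
#' @return a \code{\linkS4class{PlsModel}}.
#' @export
nipalsFit <- function(X, y = NULL, ncomp, scale = FALSE, tol = 1e-12,
                      maxIter = 500L) {
  d <- xyFrom(X, y)
  Xm <- d$X; yv <- d$y
  n <- nrow(Xm); p <- ncol(Xm)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must lie in 1..min(n-1, p)")
  xMeans <- colMeans(Xm)
  E <- sweep(Xm, 2L, xMeans)
  if (scale) {
    xScales <- apply(Xm, 2L, sd)
    xScales[xScales == 0] <- 1
    E <- sweep(E, 2L, xScales, "/")
  } else xScales <- rep(1, p)
  yMean <- mean(yv)
  f <- yv - yMean

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    # NIPALS sweep: u starts at the response residual; with a single
    # response, u is always a positive multiple of f, so E'u keeps the
    # direction of s = E'f and the sweep stabilizes after one refresh.
    s <- drop(crossprod(E, f))
    mult <- 1
    w <- NULL
    tvec <- NULL; tt <- NA_real_; qa <- NA_real_
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      wNew <- mult * s                 # = E'u for u = mult * f
      nw <- sqrt(sum(wNew^2))
      if (nw < 1e-300)
        stop(sprintf("component %d: predictor block exhausted (rank exceeded)", a))
      wNew <- wNew / nw
      if (!is.null(w) && sqrt(sum((wNew - w)^2)) <= tol) {
        w <- wNew; converged <- TRUE; break
      }
      w <- wNew
      tvec <- drop(E %*% w)
      tt <- sum(tvec^2)
      if (tt < 1e-300)
        stop(sprintf("component %d: degenerate score vector", a))
      qa <- sum(f * tvec) / tt
      mult <- qa                       # refreshed u = qa * f
    }
    if (!converged)
      stop(sprintf("NIPALS did not converge for component %d", a))
    pvec <- drop(crossprod(E, tvec)) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - qa * tvec
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; qv[a] <- qa
  }
  dimnames(W) <- dimnames(P) <- list(colnames(Xm), paste0("comp", 1:ncomp))
  new("PlsModel", weights = W, xLoadings = P, yLoadings = qv, scores = Tm,
      xMeans = xMeans, yMean = yMean, xScales = xScales, ncomp = ncomp)
}

# regression coefficients (on the raw predictor scale) using 1..k components
plsCoef <- function(model, k = model@ncomp) {
  idx <- seq_len(k)
  W <- model@weights[, idx, drop = FALSE]
  P <- model@xLoadings[, idx, drop = FALSE]
  q <- model@yLoadings[idx]
  R <- W %*% solve(crossprod(P, W))
  drop(R %*% q) / model@xScales
}

#' Predict the response from a fitted PLS model
#'
#' @param object a \code{\linkS4class{PlsModel}}.
#' @param newdata subjects x predictors matrix (or FeatureBlock).
#' @param ncomp component depth(s) to use; each depth k uses components
#'   1..k cumulatively. Default: the fitted depth.
#' @return numeric vector (single depth) or matrix with one column per
#'   requested depth.
#' @export
setMethod("predict", "PlsModel", function(object, newdata,
                                          ncomp = object@ncomp) {
  if (is(newdata, "FeatureBlock"))
    newdata <- t(SummarizedExperiment::assay(newdata, "features"))
  newdata <- as.matrix(newdata)
  out <- vapply(ncomp, function(k) {
    b <- plsCoef(object, k)
    drop(newdata %*% b) + object@yMean - sum(object@xMeans * b)
  }, numeric(nrow(newdata)))
  if (length(ncomp) == 1L) drop(out)
  else matrix(out, nrow(newdata), length(ncomp),
              dimnames = list(rownames(newdata), paste0("comp", ncomp)))
})

#' Training-data variance accounting of a PLS model
#'
#' Cumulative percentage of the centered predictor sum-of-squares captured
#' by the score/loading reconstruction ("used" predictor variance) and
#' cumulative percentage of response variance explained by the scores, per
#' component depth. Both are computed on the data the model was fitted to.
#'
#' @param model a \code{\linkS4class{PlsModel}}.
#' @param X,y the training data (FeatureBlock or matrix + response).
#' @return list with \code{xVarianceUsed} and \code{yVarianceExplained},
#'   each a cumulative percentage vector over depths 1..ncomp.
#' @export
varianceAccounting <- function(model, X, y = NULL) {
  d <- xyFrom(X, y)
  E0 <- sweep(sweep(d$X, 2L, model@xMeans), 2L, model@xScales, "/")
  xTotal <- sum(E0^2)
  yTotal <- sum((d$y - model@yMean)^2)
  tt <- colSums(model@scores^2)
  pp <- colSums(model@xLoadings^2)
  list(xVarianceUsed = 100 * cumsum(tt * pp) / xTotal,
       yVarianceExplained = 100 * cumsum(model@yLoadings^2 * tt) / yTotal)
}

#' Leave-one-out RMSEP over candidate component counts
#'
#' For every depth k in 0..maxComponents, each subject is held out in turn,
#' the model is refit on the remaining subjects and the held-out age is
#' predicted with k components (k = 0 is the mean-only model); RMSEP(k) is
#' the root mean of the held-out squared errors. The per-subject squared
#' errors are kept for the component-selection randomization test, and the
#' report carries the full-sample training variance accounting.
#'
#' @inheritParams nipalsFit
#' @param maxComponents largest candidate depth K (default 10).
#' @return a \code{\linkS4class{CvReport}}.
#' @export
looRmsep <- function(X, y = NULL, maxComponents = 10L, scale = FALSE) {
  d <- xyFrom(X, y)
  Xm <- d$X; yv <- d$y
  n <- nrow(Xm)
  K <- min(as.integer(maxComponents), n - 2L, ncol(Xm))
  if (n < K + 2L) stop("need at least maxComponents + 2 subjects")
  err <- matrix(NA_real_, n, K + 1L,
                dimnames = list(rownames(Xm), as.character(0:K)))
  for (i in seq_len(n)) {
    if (K >= 1L) {
      fit <- nipalsFit(Xm[-i, , drop = FALSE], yv[-i], ncomp = K,
                       scale = scale)
      pred <- predict(fit, Xm[i, , drop = FALSE], ncomp = 1:K)
    } else pred <- NULL
    err[i, ] <- (yv[i] - c(mean(yv[-i]), pred))^2
  }
  va <- if (K >= 1L) {
    full <- nipalsFit(Xm, yv, ncomp = K, scale = scale)
    varianceAccounting(full, Xm, yv)
  } else list(xVarianceUsed = numeric(0), yVarianceExplained = numeric(0))
  new("CvReport", rmsep = sqrt(colMeans(err)), looErrors = err,
      xVarianceUsed = va$xVarianceUsed,
      yVarianceExplained = va$yVarianceExplained,
      maxComponents = K)
}

#' Select the number of components by a randomization test on LOO errors
#'
#' Starting from the depth with globally minimal RMSEP, the smallest depth
#' whose held-out squared errors are not significantly worse than the
#' minimizer's is selected, using a sign-randomization test on the paired
#' per-subject differences of squared LOO errors at level \code{alpha}
#' (one-sided: "worse than the best model").
#'
#' @param cv a \code{\linkS4class{CvReport}}.
#' @param alpha significance level (default 0.01).
#' @param nPerm number of sign randomizations (default 1999).
#' @return selected component count (0 = mean-only model).
#' @export
selectNcomp <- function(cv, alpha = 0.01, nPerm = 1999L) {
  err <- cv@looErrors
  kmin <- which.min(cv@rmsep) - 1L    # depths are 0-based
  if (kmin == 0L) return(0L)
  n <- nrow(err)
  S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
  for (k in 0:(kmin - 1L)) {
    d <- err[, k + 1L] - err[, kmin + 1L]
    obs <- mean(d)
    perm <- drop(S %*% d) / n
    p <- (1 + sum(perm >= obs)) / (nPerm + 1)
    if (p >= alpha) return(as.integer(k))
  }
  as.integer(kmin)
}

#' Scrambled null data
#'
#' Permutes the rows of every predictor column independently and permutes
#' the response, destroying the predictor-response association and the
#' between-predictor dependence while preserving every marginal
#' distribution exactly.
#'
#' @inheritParams nipalsFit
#' @return list with scrambled \code{X} and \code{y}.
#' @export
scrambledNull <- function(X, y = NULL) {
  d <- xyFrom(X, y)
  n <- nrow(d$X)
  Xs <- apply(d$X, 2L, function(col) col[sample.int(n)])
  list(X = Xs, y = d$y[sample.int(n)])
}

#' Repeated random train/test splits
#'
#' Splits the sample \code{nReps} times into training and test sets
#' (train size \code{round(trainFraction * n)}; for 573 subjects at 0.8
#' that is 458 train / 115 test), fits the PLS model on each training set
#' and predicts age on the held-out subjects, recording the held-out
#' correlation between predicted and chronological age and the held-out
#' RMSEP at every cumulative depth 1..ncomp, together with the
#' per-replicate loadings for profile averaging. Per-replicate seeds are
#' derived deterministically from the master seed.
#'
#' @inheritParams nipalsFit
#' @param trainFraction training fraction in (0.5, 0.95); 0.9, 0.7 and 0.6
#'   support the sensitivity splits.
#' @param nReps number of splits (default 1000).
#' @param seed master seed for the split randomness.
#' @return a \code{\linkS4class{SplitEnsemble}}.
#' @export
repeatedSplits <- function(X, y = NULL, trainFraction = 0.8, nReps = 1000L,
                           ncomp, seed = 1L, scale = FALSE) {
  d <- xyFrom(X, y)
  Xm <- d$X; yv <- d$y
  n <- nrow(Xm); p <- ncol(Xm)
  if (trainFraction <= 0.5 || trainFraction >= 0.95)
    stop("trainFraction must lie in (0.5, 0.95)")
  ncomp <- as.integer(ncomp)
  nReps <- as.integer(nReps)
  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, nReps)
  reference <- nipalsFit(Xm, yv, ncomp = ncomp, scale = scale)

  nTrain <- round(trainFraction * n)
  loadA <- array(NA_real_, c(p, ncomp, nReps),
                 dimnames = list(colnames(Xm), paste0("comp", 1:ncomp), NULL))
  wA <- loadA
  qM <- matrix(NA_real_, ncomp, nReps)
  xmM <- matrix(NA_real_, p, nReps)
  ymV <- numeric(nReps)
  testR <- matrix(NA_real_, nReps, ncomp,
                  dimnames = list(NULL, paste0("comp", 1:ncomp)))
  testRmsep <- testR
  trainIdx <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    set.seed(childSeeds[r])
    tr <- sort(sample.int(n, nTrain))
    te <- setdiff(seq_len(n), tr)
    fit <- nipalsFit(Xm[tr, , drop = FALSE], yv[tr], ncomp = ncomp,
                     scale = scale)
    pred <- predict(fit, Xm[te, , drop = FALSE], ncomp = 1:ncomp)
    pred <- matrix(pred, length(te), ncomp)
    testR[r, ] <- apply(pred, 2L, cor, y = yv[te])
    testRmsep[r, ] <- sqrt(colMeans((yv[te] - pred)^2))
    loadA[, , r] <- fit@xLoadings
    wA[, , r] <- fit@weights
    qM[, r] <- fit@yLoadings
    xmM[, r] <- fit@xMeans
    ymV[r] <- fit@yMean
    trainIdx[[r]] <- tr
  }
  new("SplitEnsemble", xLoadings = loadA, weights = wA, yLoadings = qM,
      xMeans = xmM, yMeans = ymV, testR = testR, testRmsep = testRmsep,
      trainIndices = trainIdx, reference = reference,
      trainFraction = trainFraction, seed = as.integer(seed),
      aligned = FALSE)
}

#' Null-model ensemble of LOO RMSEPs
#'
#' Repeats the scrambled-null construction, refits the model at a fixed
#' depth on each null dataset and records the LOO RMSEP at that depth,
#' giving the null distribution against which the real model's RMSEP is
#' compared.
#'
#' @inheritParams nipalsFit
#' @param ncomp fixed component depth for every null replicate.
#' @param nNull number of null replicates (default 1000).
#' @return numeric vector of null RMSEPs at depth \code{ncomp}.
#' @export
nullRmsep <- function(X, y = NULL, ncomp, nNull = 1000L, scale = FALSE) {
  d <- xyFrom(X, y)
  vapply(seq_len(nNull), function(b) {
    nd <- scrambledNull(d$X, d$y)
    cv <- looRmsep(nd$X, nd$y, maxComponents = ncomp, scale = scale)
    unname(cv@rmsep[as.character(ncomp)])
  }, numeric(1))
}
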