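# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# SIMPLS (covariance-deflation) PLS1: an algorithmically independent route
# to the same regression; predictions at every depth 1..ncomp.
simplsPredict <- function(X, y, newX, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  s <- drop(crossprod(Xc, yc))
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  preds <- matrix(0, nrow(newX), ncomp)
  Nc <- sweep(as.matrix(newX), 2, xm)
  for (a in seq_len(ncomp)) {
    r <- s
    tvec <- drop(Xc %*% r)
    nt <- sqrt(sum(tvec^2))
    tvec <- tvec / nt; r <- r / nt
    pvec <- drop(crossprod(Xc, tvec))
    Q[a] <- sum(yc * tvec)
    v <- pvec
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pvec)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    R[, a] <- r; V[, a] <- v
    B <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
    preds[, a] <- drop(Nc %*% B) + ym
  }
  preds
}

# plain least-squares predictions through QR
olsPredict <- function(X, y, newX) {
  fit <- lm.fit(cbind(1, X), y)
  drop(cbind(1, as.matrix(newX)) %*% fit$coefficients)
}

# strength estimates by explicit edge enumeration
bruteStrengths <- function(m, parc) {
  nd <- nodeTable(parc)
  n <- nrow(nd)
  intra <- inter <- numeric(n)
  for (i in seq_len(n)) {
    neti <- nd$network[i]
    nk <- sum(nd$network == neti)
    sIn <- sOut <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (nd$network[j] == neti) sIn <- sIn + m[i, j]
      else sOut <- sOut + m[i, j]
    }
    intra[i] <- sIn / (nk * (nk - 1) / 2)
    inter[i] <- sOut / (n - nk)
  }
  list(intra = intra, inter = inter)
}

# textbook pooled-variance two-sample t statistic
pooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Pearson correlation from first principles
bruteCor <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# full feature pipeline for a (small) cohort: cognition composite,
# connectomes, strengths, residualization; mirrors the analysis defaults
cohortToFeatures <- function(coh, alpha = NULL, nSurrogates = 99L) {
  sub <- subjectTable(coh)
  cg <- cognitionComposite(sub)
  keep <- cg$composite@subjectIds
  coh@subjects <- sub[match(keep, sub$subject_id), ]
  coh@timeseries <- coh@timeseries[keep]
  coh@sc <- coh@sc[keep]
  fb <- cohortFeatures(coh, cog = cogScores(cg$composite)[keep],
                       alpha = alpha, nSurrogates = nSurrogates)
  list(fb = residualize(fb), cohort = coh, composite = cg$composite)
}
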