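#' Pearson functional connectivity
#'
#' Correlates every pair of node time series with Pearson's product-moment
#' correlation, yielding a symmetric node-by-node FC matrix (diagonal set to
#' zero; self-edges carry no information).
#'
#' @param ts node x time numeric matrix (at least 32 time points, no
#'   missing values); row order binds to the parcellation.
#' @return a \code{\linkS4class{ConnectivityMatrix}} of kind \code{"FC"}.
#' @export
pearsonFC <- function(ts) {
  checkTimeSeries(ts)
  r <- cor(t(ts))
  # guard against tiny asymmetries / overshoot from floating point
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 0
  new("ConnectivityMatrix", values = r, kind = "FC")
}

checkTimeSeries <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts))
    stop("time series must be a numeric node x time matrix")
  if (anyNA(ts)) stop("time series must not contain missing values")
  if (ncol(ts) < 32L) stop("at least 32 time points are required")
  v <- apply(ts, 1L, var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stop("zero-variance series at node(s): ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Phase-randomization surrogate of a time series
#'
#' Returns a series with the identical amplitude spectrum but independently
#' randomized phases: the Fourier transform is taken, every positive
#' frequency receives a uniform random phase (mirrored to its conjugate
#' bin), and the transform is inverted. The DC bin and, for even lengths,
#' the Nyquist bin are left untouched, so the surrogate is real-valued and
#' preserves the mean and the full autocorrelation structure while
#' destroying any dependence on other series.
#'
#' @param x numeric vector of length at least 4.
#' @return numeric surrogate of the same length.
#' @export
phaseSurrogate <- function(x) {
  n <- length(x)
  if (n < 4L) stop("series must have at least 4 points")
  ph <- surrogatePhases(n, 1L)[, 1]
  Re(fft(fft(x) * ph, inverse = TRUE)) / n
}

# complex unit phase factors for m surrogates of length n: DC (and Nyquist
# for even n) fixed at 1, conjugate-symmetric elsewhere
surrogatePhases <- function(n, m) {
  half <- (n - 1L) %/% 2L
  ph <- matrix(1 + 0i, n, m)
  if (half >= 1L) {
    theta <- matrix(runif(half * m, 0, 2 * pi), half, m)
    ph[2:(half + 1L), ] <- exp(1i * theta)
    ph[n:(n - half + 1L), ] <- Conj(ph[2:(half + 1L), , drop = FALSE])
  }
  ph
}

#' Surrogate-based edge significance test
#'
#' Tests every FC edge against a null in which both node series are replaced
#' by independent phase-randomization surrogates, preserving each series'
#' amplitude spectrum (hence autocorrelation) while destroying cross-series
#' dependence. Per edge, the two-sided p-value is
#' \code{(1 + #surrogate |r| >= observed |r|) / (nSurrogates + 1)} (ties
#' count against significance); an edge is retained iff \code{p < alpha}.
#'
#' @param ts node x time matrix.
#' @param nSurrogates number of surrogate replicates (at least 19;
#'   default 1000).
#' @param alpha per-edge retention level (default 0.05, uncorrected).
#' @return list with \code{p} (symmetric p-value matrix, diagonal NA),
#'   \code{mask} (logical retained-edge matrix) and \code{values} (observed
#'   r with non-retained edges set to zero).
#' @export
edgeSignificance <- function(ts, nSurrogates = 1000L, alpha = 0.05) {
  checkTimeSeries(ts)
  nSurrogates <- as.integer(nSurrogates)
  if (nSurrogates < 19L) stop("at least 19 surrogates are required")
  n <- nrow(ts)
  robs <- connValues(pearsonFC(ts))
  aobs <- abs(robs)
  X <- t(ts)                      # time x node
  F0 <- mvfft(X)
  nT <- nrow(X)
  exceed <- matrix(0L, n, n)
  for (s in seq_len(nSurrogates)) {
    ph <- surrogatePhases(nT, n)
    surr <- Re(mvfft(F0 * ph, inverse = TRUE)) / nT
    rs <- cor(surr)
    exceed <- exceed + (abs(rs) >= aobs)
  }
  p <- (1 + exceed) / (nSurrogates + 1)
  diag(p) <- NA_real_
  mask <- !is.na(p) & p < alpha
  vals <- robs
  vals[!mask] <- 0
  list(p = p, mask = mask, values = vals)
}

#' Fisher r-to-z transform of an FC matrix
#'
#' Applies \code{atanh} entry-wise; zeros (masked edges and the diagonal)
#' stay exactly zero, and the transform is odd, so masking and transforming
#' commute. Correlations at the +/-1 boundary are clipped to
#' \code{1 - clip} beforehand; with \code{clip = 0} a boundary value is an
#' error.
#'
#' @param m a \code{\linkS4class{ConnectivityMatrix}} of kind \code{"FC"}
#'   or a plain numeric matrix of correlations.
#' @param clip clipping margin for |r| -> 1 (default 1e-7).
#' @return a \code{\linkS4class{ConnectivityMatrix}} of kind \code{"FCz"}
#'   (or a plain matrix when the input was plain).
#' @export
fisherZ <- function(m, clip = 1e-7) {
  plain <- !is(m, "ConnectivityMatrix")
  v <- if (plain) m else connValues(m)
  if (any(abs(v) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  if (clip > 0) {
    v[v > 1 - clip] <- 1 - clip
    v[v < -(1 - clip)] <- -(1 - clip)
  } else if (any(abs(v) >= 1)) {
    stop("|r| = 1 encountered with clipping disabled")
  }
  z <- atanh(v)
  z[v == 0] <- 0
  if (plain) z else new("ConnectivityMatrix", values = z, kind = "FCz")
}

#' Split a signed FC matrix into its positive and negative halves
#'
#' Produces \code{FCpos = max(z, 0)} and \code{FCneg = max(-z, 0)}:
#' positive couplings and the absolute values of negative couplings are
#' analyzed separately so they cannot cancel inside strength sums.
#' \code{FCpos - FCneg} reconstructs the input exactly.
#'
#' @param z a \code{\linkS4class{ConnectivityMatrix}} (kind \code{"FCz"} or
#'   \code{"FC"}) or a plain symmetric matrix.
#' @return list with \code{FCpos} and \code{FCneg}
#'   \code{\linkS4class{ConnectivityMatrix}} objects.
#' @export
splitSigned <- function(z) {
  v <- if (is(z, "ConnectivityMatrix")) connValues(z) else z
  if (max(abs(v - t(v))) > 1e-9) stop("input must be symmetric")
  list(FCpos = new("ConnectivityMatrix", values = pmax(v, 0), kind = "FCpos"),
       FCneg = new("ConnectivityMatrix", values = pmax(-v, 0), kind = "FCneg"))
}

#' Build the thresholded, sign-split FC matrices for one subject
#'
#' Full functional-connectome construction: Pearson correlation, optional
#' surrogate-based edge significance masking (non-significant edges set to
#' zero), Fisher r-to-z transform, and the positive/negative split.
#'
#' @inheritParams edgeSignificance
#' @param alpha per-edge significance level; \code{NULL} skips the
#'   surrogate masking step entirely.
#' @param keepP also return the p-value matrix?
#' @return list with \code{FCpos}, \code{FCneg} and (optionally) \code{p}.
#' @export
buildFC <- function(ts, alpha = 0.05, nSurrogates = 1000L, keepP = FALSE) {
  if (is.null(alpha)) {
    r <- connValues(pearsonFC(ts))
    p <- NULL
  } else {
    sig <- edgeSignificance(ts, nSurrogates = nSurrogates, alpha = alpha)
    r <- sig$values
    p <- sig$p
  }
  out <- splitSigned(fisherZ(r))
  if (keepP) out$p <- p
  out
}
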