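#' Log-transform a streamline-weight matrix
#'
#' Converts non-negative streamline-derived edge weights to
#' \code{log10(offset + w)} with the default offset 1, so absent edges
#' (w = 0) map to exactly 0 and the ordering of weights is preserved. The
#' result is tagged as already log-transformed; applying the transform to a
#' tagged matrix is refused rather than silently compounding.
#'
#' @param w symmetric non-negative node x node weight matrix (zero
#'   diagonal) or a \code{\linkS4class{ConnectivityMatrix}} of kind
#'   \code{"SC"}.
#' @param logOffset additive offset inside the log (default 1).
#' @return a \code{\linkS4class{ConnectivityMatrix}} of kind \code{"SC"}
#'   with \code{logTransformed = TRUE}.
#' @examples
#' w <- matrix(c(0, 99, 99, 0), 2)
#' connValues(scTransform(w))   # 0 / 2 / 2 / 0
#' @export
scTransform <- function(w, logOffset = 1) {
  if (is(w, "ConnectivityMatrix")) {
    if (w@logTransformed)
      stop("matrix is already log-transformed; refusing to transform twice")
    if (connKind(w) != "SC") stop("expected a matrix of kind 'SC'")
    v <- connValues(w)
  } else {
    v <- w
  }
  if (!is.numeric(v) || nrow(v) != ncol(v))
    stop("weights must form a square numeric matrix")
  if (min(v) < 0) stop("streamline weights must be non-negative")
  if (max(abs(v - t(v))) > 1e-9) stop("weight matrix must be symmetric")
  out <- log10(logOffset + v)
  out[v == 0] <- 0
  diag(out) <- 0
  new("ConnectivityMatrix", values = out, kind = "SC", logTransformed = TRUE)
}

#' Upper-triangle edge list of a connectivity matrix
#'
#' Since connectivity is undirected, only the upper triangle (i < j)
#' carries information; this returns it as an edge list of exactly
#' N(N-1)/2 rows with the diagonal excluded.
#'
#' @param m a \code{\linkS4class{ConnectivityMatrix}} or a symmetric
#'   numeric matrix (asymmetry beyond 1e-9 is an error).
#' @return \code{data.frame} with columns \code{i}, \code{j} (0-based node
#'   ids, i < j) and \code{weight}.
#' @seealso \code{\link{edgesToMatrix}} for the inverse.
#' @export
triangularize <- function(m) {
  v <- if (is(m, "ConnectivityMatrix")) connValues(m) else m
  if (!is.matrix(v) || nrow(v) != ncol(v))
    stop("input must be a square matrix")
  if (max(abs(v - t(v))) > 1e-9) stop("input must be symmetric")
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  data.frame(i = ut[, "row"] - 1L, j = ut[, "col"] - 1L,
             weight = v[ut])
}

#' Rebuild a symmetric matrix from an upper-triangle edge list
#'
#' @param edges \code{data.frame} as returned by \code{\link{triangularize}}.
#' @param nNodes matrix dimension.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
edgesToMatrix <- function(edges, nNodes) {
  m <- matrix(0, nNodes, nNodes)
  idx <- cbind(edges$i + 1L, edges$j + 1L)
  m[idx] <- edges$weight
  m[idx[, 2:1, drop = FALSE]] <- edges$weight
  m
}
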