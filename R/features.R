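#' Node-wise intra-network strength
#'
#' Sum of the weights of all within-network edges incident to a node,
#' divided by the number of possible edges in that node's network,
#' n(n-1)/2 for a network of n nodes. Note the deliberate asymmetry of the
#' estimate: a per-node edge sum over a network-level possible-edge count.
#'
#' @param m a \code{\linkS4class{ConnectivityMatrix}} or symmetric matrix.
#' @param parc a \code{\linkS4class{Parcellation}} matching the matrix.
#' @param node 0-based node id (default: all nodes).
#' @return named numeric vector of strength values.
#' @export
intraStrength <- function(m, parc, node = NULL) {
  s <- strengthTable(m, parc)$intra
  if (is.null(node)) s else s[node + 1L]
}

#' Node-wise inter-network strength
#'
#' Sum of the weights of all edges from a node to nodes outside its
#' network, divided by the number of such possible edges for that node,
#' N - n (with N total nodes and n the node's network size). A
#' network-total denominator n(N - n) is available via
#' \code{\link{nodeStrengths}}.
#'
#' @inheritParams intraStrength
#' @return named numeric vector of strength values.
#' @export
interStrength <- function(m, parc, node = NULL) {
  s <- strengthTable(m, parc)$inter
  if (is.null(node)) s else s[node + 1L]
}

#' All six strength estimates are built from this kernel
#'
#' @param m connectivity matrix (object or plain symmetric matrix).
#' @param parc parcellation.
#' @param interDenominator \code{"per-node"} (default, N - n possible
#'   edges from one node) or \code{"network-total"} (n(N - n) possible
#'   edges of the whole network).
#' @return \code{data.frame} with columns \code{node_id}, \code{intra},
#'   \code{inter}.
#' @export
nodeStrengths <- function(m, parc, interDenominator = c("per-node",
                                                        "network-total")) {
  strengthTable(m, parc, match.arg(interDenominator))
}

strengthTable <- function(m, parc, interDenominator = "per-node") {
  v <- if (is(m, "ConnectivityMatrix")) connValues(m) else m
  nd <- nodeTable(parc)
  n <- nrow(nd)
  if (nrow(v) != n)
    stop(sprintf("matrix has %d nodes, parcellation %d", nrow(v), n))
  diag(v) <- 0
  net <- nd$network
  sizes <- table(net)
  if (any(sizes < 2L))
    stop("singleton network(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  same <- outer(net, net, "==")
  nk <- as.numeric(sizes[net])
  intraSum <- rowSums(v * same)          # self term is zero
  interSum <- rowSums(v * !same)
  intra <- intraSum / (nk * (nk - 1) / 2)
  interDen <- switch(interDenominator,
                     "per-node" = n - nk,
                     "network-total" = nk * (n - nk))
  inter <- interSum / interDen
  data.frame(node_id = nd$node_id, intra = intra, inter = inter)
}

#' Assemble the subjects-by-predictors feature block
#'
#' Reduces every subject's three connectivity matrices (SC, FCpos, FCneg)
#' to the six node-wise strength estimates and stacks them, node-major, in
#' the canonical predictor order (SC_intra, SC_inter, FCpos_intra,
#' FCpos_inter, FCneg_intra, FCneg_inter per node), optionally appending
#' the cognition score COG; a 400-node parcellation yields 2400
#' connectivity predictors (2401 with COG). Per-predictor node, kind,
#' scope, network and lobe tags go to \code{rowData}; the subject
#' covariates go to \code{colData}.
#'
#' @param sc,fcpos,fcneg named lists of per-subject connectivity matrices
#'   (\code{\linkS4class{ConnectivityMatrix}} or plain symmetric); all
#'   three must cover the same subjects.
#' @param parc the shared \code{\linkS4class{Parcellation}}.
#' @param subjects \code{data.frame} with at least \code{subject_id} and
#'   \code{age}; carried into \code{colData}.
#' @param cog optional per-subject COG values (same order as
#'   \code{subjects}); when given, appended as the final predictor.
#' @param interDenominator passed to \code{\link{nodeStrengths}}.
#' @return a \code{\linkS4class{FeatureBlock}}.
#' @export
assembleFeatures <- function(sc, fcpos, fcneg, parc, subjects, cog = NULL,
                             interDenominator = "per-node") {
  ids <- subjects$subject_id
  for (nmList in list(sc = sc, fcpos = fcpos, fcneg = fcneg)) {
    missing <- setdiff(ids, names(nmList))
    if (length(missing))
      stop("subject(s) without a matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  includeCog <- !is.null(cog)
  if (includeCog && (length(cog) != length(ids) || anyNA(cog)))
    stop("COG must provide one non-missing value per subject")
  nm <- featureNames(parc, includeCog = includeCog)
  X <- matrix(NA_real_, length(nm), length(ids),
              dimnames = list(nm, ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    row6 <- vapply(list(sc[[id]], fcpos[[id]], fcneg[[id]]), function(m) {
      st <- strengthTable(m, parc, interDenominator)
      rbind(st$intra, st$inter)
    }, matrix(0, 2, nNodes(parc)))
    # row6: 2 (intra/inter) x nodes x 3 (SC, FCpos, FCneg) -> node-major 6
    feats <- as.vector(aperm(row6, c(1, 3, 2)))
    X[seq_along(feats), i] <- feats
    if (includeCog) X[nrow(X), i] <- cog[i]
  }
  tags <- featureTags(parc, includeCog = includeCog)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    rowData = S4Vectors::DataFrame(tags, row.names = tags$predictor),
    colData = S4Vectors::DataFrame(subjects, row.names = ids))
  new("FeatureBlock", se)
}

#' Convenience: features straight from a synthetic cohort
#'
#' Runs the connectome builders (\code{\link{buildFC}},
#' \code{\link{scTransform}}) and \code{\link{assembleFeatures}} on every
#' subject of a cohort, optionally appending a supplied COG vector.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param cog optional per-subject COG values.
#' @param alpha,nSurrogates edge-significance settings for
#'   \code{\link{buildFC}} (\code{alpha = NULL} skips the masking).
#' @param logOffset for \code{\link{scTransform}}.
#' @param interDenominator passed through to strength estimation.
#' @return a \code{\linkS4class{FeatureBlock}}.
#' @export
cohortFeatures <- function(cohort, cog = NULL, alpha = 0.05,
                           nSurrogates = 1000L, logOffset = 1,
                           interDenominator = "per-node") {
  ids <- cohort@subjects$subject_id
  parc <- parcellation(cohort)
  scL <- fpL <- fnL <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    fc <- buildFC(cohort@timeseries[[id]], alpha = alpha,
                  nSurrogates = nSurrogates)
    fpL[[id]] <- fc$FCpos
    fnL[[id]] <- fc$FCneg
    scL[[id]] <- scTransform(cohort@sc[[id]], logOffset = logOffset)
  }
  assembleFeatures(scL, fpL, fnL, parc, cohort@subjects, cog = cog,
                   interDenominator = interDenominator)
}
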