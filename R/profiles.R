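#' Align component signs and order across split replicates
#'
#' PLS component signs (and, in principle, order) are arbitrary: flipping a
#' component's weight, loading and score vectors jointly leaves every
#' prediction unchanged. Before loadings can be averaged across replicates,
#' each replicate's components are therefore matched one-to-one to the
#' full-sample reference model by maximal absolute loading correlation
#' (greedy) and flipped jointly whenever that correlation is negative. An
#' ambiguous match (two candidates within 1e-6) triggers a warning and an
#' index-order fallback for that replicate.
#'
#' @param ensemble a \code{\linkS4class{SplitEnsemble}}.
#' @param reference a \code{\linkS4class{PlsModel}} fitted on the full
#'   sample at the same depth (default: the ensemble's stored reference).
#' @return the ensemble with aligned loadings, weights and response
#'   loadings (\code{aligned = TRUE}).
#' @export
alignSigns <- function(ensemble, reference = ensemble@reference) {
  k <- dim(ensemble@xLoadings)[2]
  if (reference@ncomp != k)
    stop("reference depth must equal the ensemble depth")
  refL <- reference@xLoadings
  nReps <- dim(ensemble@xLoadings)[3]
  for (r in seq_len(nReps)) {
    L <- ensemble@xLoadings[, , r, drop = FALSE][, , 1]
    L <- matrix(L, nrow(refL), k)
    C <- suppressWarnings(cor(refL, L))
    C[!is.finite(C)] <- 0
    perm <- integer(k); sgn <- numeric(k)
    usedRef <- usedRep <- rep(FALSE, k)
    ambiguous <- FALSE
    A <- abs(C)
    for (step in seq_len(k)) {
      A[usedRef, ] <- -Inf; A[, usedRep] <- -Inf
      best <- which(A == max(A), arr.ind = TRUE)[1, ]
      i <- best[1]; j <- best[2]
      others <- A[i, ]; others[j] <- -Inf
      if (any(is.finite(others)) && A[i, j] - max(others) < 1e-6) {
        ambiguous <- TRUE
        break
      }
      perm[i] <- j
      sgn[i] <- sign(C[i, j])
      usedRef[i] <- TRUE; usedRep[j] <- TRUE
    }
    if (ambiguous) {
      warning(sprintf(
        "replicate %d: ambiguous component matching; using index order", r))
      perm <- seq_len(k)
      sgn <- sign(diag(C))
    }
    sgn[sgn == 0] <- 1
    ensemble@xLoadings[, , r] <- sweep(L[, perm, drop = FALSE], 2L, sgn, "*")
    Wr <- matrix(ensemble@weights[, , r], nrow(refL), k)
    ensemble@weights[, , r] <- sweep(Wr[, perm, drop = FALSE], 2L, sgn, "*")
    ensemble@yLoadings[, r] <- ensemble@yLoadings[perm, r] * sgn
  }
  ensemble@aligned <- TRUE
  ensemble
}

#' Mean loadings across replicates: the aging profiles
#'
#' Averages the aligned per-replicate predictor loadings into one
#' \code{\linkS4class{AgingProfile}} per component (mean and SD per
#' predictor; the COG loading reported separately when present). A single
#' global orientation rule is applied consistently: each component is
#' flipped, jointly with its scores, so that its full-sample score values
#' correlate non-positively with age — a positive loading then marks a
#' predictor whose value is lower at higher ages.
#'
#' @param ensemble an aligned \code{\linkS4class{SplitEnsemble}}.
#' @param age per-subject chronological age (full sample, the data the
#'   reference model was fitted on).
#' @param parc optional \code{\linkS4class{Parcellation}}; when given, the
#'   network-wise summary is filled in via
#'   \code{\link{networkMeanLoadings}}.
#' @return list of \code{\linkS4class{AgingProfile}} objects, one per
#'   component.
#' @export
meanLoadings <- function(ensemble, age, parc = NULL) {
  if (!ensemble@aligned)
    stop("align the ensemble with alignSigns() before averaging")
  L <- ensemble@xLoadings
  p <- dim(L)[1]; k <- dim(L)[2]; nReps <- dim(L)[3]
  mu <- apply(L, c(1, 2), mean)
  sdv <- if (nReps > 1) apply(L, c(1, 2), sd) else matrix(0, p, k)
  dimnames(sdv) <- dimnames(mu)
  ref <- ensemble@reference
  ageCor <- vapply(seq_len(k), function(c)
    cor(ref@scores[, c], age), numeric(1))
  ageP <- vapply(seq_len(k), function(c)
    stats::cor.test(ref@scores[, c], age)$p.value, numeric(1))
  hasCog <- "COG" %in% rownames(mu)
  out <- vector("list", k)
  for (c in seq_len(k)) {
    m <- mu[, c]; s <- sdv[, c]
    rc <- ageCor[c]
    if (rc > 0) { m <- -m; rc <- -rc }   # orient: scores anti-correlate with age
    prof <- new("AgingProfile", component = as.integer(c),
                predictorMeans = m[setdiff(names(m), "COG")],
                predictorSds = s[setdiff(names(s), "COG")],
                cogMean = if (hasCog) unname(m["COG"]) else NA_real_,
                cogSd = if (hasCog) unname(s["COG"]) else NA_real_,
                networkSummary = data.frame(),
                ageCorrelation = rc, ageCorrelationP = ageP[c])
    if (!is.null(parc))
      prof@networkSummary <- networkMeanLoadings(prof, parc)
    out[[c]] <- prof
  }
  out
}

#' Network-wise average mean loadings
#'
#' Unweighted average of the per-node mean loadings within each network,
#' computed separately for each of the six predictor families (matrix kind
#' x intra/inter scope).
#'
#' @param profile an \code{\linkS4class{AgingProfile}}.
#' @param parc the matching \code{\linkS4class{Parcellation}}.
#' @return \code{data.frame} with columns \code{network}, \code{kind},
#'   \code{scope}, \code{meanLoading}, \code{sdLoading}.
#' @export
networkMeanLoadings <- function(profile, parc) {
  tags <- featureTags(parc, includeCog = FALSE)
  m <- profile@predictorMeans[tags$predictor]
  key <- interaction(tags$network, tags$kind, tags$scope, sep = "|")
  agg <- tapply(m, key, mean)
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  data.frame(network = parts[, 1], kind = parts[, 2], scope = parts[, 3],
             meanLoading = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Frontal versus rest-of-brain loading comparison
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch via
#' \code{welch = TRUE}) comparing the node-level mean loadings of one
#' predictor family between frontal nodes and all remaining nodes.
#'
#' @param profile an \code{\linkS4class{AgingProfile}}.
#' @param parc the matching \code{\linkS4class{Parcellation}}.
#' @param family predictor family, e.g. \code{"SC_intra"},
#'   \code{"FCpos_inter"}.
#' @param welch use the Welch (unpooled) variant?
#' @return list with \code{t}, \code{p}, \code{df} and the two group means.
#' @export
frontalVsRestTest <- function(profile, parc, family = "SC_intra",
                              welch = FALSE) {
  tags <- featureTags(parc, includeCog = FALSE)
  sel <- paste(tags$kind, tags$scope, sep = "_") == family
  if (!any(sel)) stop("unknown predictor family: ", family)
  tags <- tags[sel, ]
  m <- profile@predictorMeans[tags$predictor]
  frontal <- m[tags$lobe == "frontal"]
  rest <- m[tags$lobe == "other"]
  if (length(frontal) < 2L || length(rest) < 2L)
    stop("both lobe groups need at least 2 nodes")
  tt <- t.test(frontal, rest, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       meanFrontal = mean(frontal), meanRest = mean(rest))
}

#' Correlation between component scores and chronological age
#'
#' Pearson correlation (with p-value) of each component's per-subject score
#' values with age, taken from a fitted full-sample model or from the
#' reference model of a split ensemble.
#'
#' @param x a \code{\linkS4class{PlsModel}} or
#'   \code{\linkS4class{SplitEnsemble}}.
#' @param age per-subject chronological age.
#' @return \code{data.frame} with columns \code{component}, \code{r},
#'   \code{p}.
#' @export
componentAgeCorrelation <- function(x, age) {
  model <- if (is(x, "SplitEnsemble")) x@reference else x
  if (!is(model, "PlsModel")) stop("x must be a PlsModel or SplitEnsemble")
  k <- model@ncomp
  res <- lapply(seq_len(k), function(c) {
    ct <- stats::cor.test(model@scores[, c], age)
    data.frame(component = c, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
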