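# Default network proportions follow the 400-node seven-network scheme
# (VN 61, SMN 77, LN 26, FPN 52, DMN 91, DAN 46, VAN 47 of 400).
DEFAULT_NETWORK_PROP <- c(VN = 61, SMN = 77, LN = 26, FPN = 52,
                          DMN = 91, DAN = 46, VAN = 47) / 400

# Relative tendency of each network to own frontal nodes; FPN/DMN/SMN/VAN
# span both lobes prominently, VN/LN/DAN are mostly posterior.
FRONTAL_WEIGHT <- c(VN = 0.2, SMN = 1.0, LN = 0.5, FPN = 1.6,
                    DMN = 1.4, DAN = 0.6, VAN = 1.0)

#' Build a deterministic parcellation
#'
#' Assigns \code{nNodes} cortical nodes to the seven canonical resting-state
#' networks and labels each node with a lobe (frontal vs. other) and a
#' hemisphere. The assignment is fully deterministic: calling the function
#' twice with the same arguments yields an identical label table. Frontal
#' nodes are spread over networks proportionally to how much each network
#' extends into the frontal lobe, so that several networks span both lobes.
#'
#' @param nNodes total number of nodes (default 400; at least 14 so every
#'   network can hold two nodes).
#' @param networkSizes optional named integer vector of per-network node
#'   counts; must sum to \code{nNodes}. Defaults to the canonical
#'   proportions of the 400-node scheme, scaled by largest remainder.
#' @param frontalFraction overall fraction of nodes labelled frontal
#'   (default 0.3).
#'
#' @return a \code{\linkS4class{Parcellation}}.
#' @examples
#' p <- makeParcellation(100)
#' table(nodeNetworks(p), nodeLobes(p))
#' @export
makeParcellation <- function(nNodes = 400L, networkSizes = NULL,
                             frontalFraction = 0.3) {
  nNodes <- as.integer(nNodes)
  if (nNodes < 14L)
    stop("nNodes must be >= 14 (at least two nodes per network)")
  if (is.null(networkSizes)) {
    networkSizes <- largestRemainder(DEFAULT_NETWORK_PROP * nNodes)
    # small parcellations: keep every network at >= 2 nodes
    while (any(networkSizes < 2L)) {
      lo <- which.min(networkSizes); hi <- which.max(networkSizes)
      networkSizes[lo] <- networkSizes[lo] + 1L
      networkSizes[hi] <- networkSizes[hi] - 1L
    }
  } else {
    if (is.null(names(networkSizes)) ||
        !setequal(names(networkSizes), CANONICAL_NETWORKS))
      stop("networkSizes must be named with the seven canonical networks")
    networkSizes <- as.integer(networkSizes[CANONICAL_NETWORKS])
    names(networkSizes) <- CANONICAL_NETWORKS
  }
  if (sum(networkSizes) != nNodes)
    stop(sprintf("network sizes sum to %d, expected nNodes = %d",
                 sum(networkSizes), nNodes))
  if (any(networkSizes < 2L))
    stop("every network needs at least 2 nodes")

  network <- rep(CANONICAL_NETWORKS, times = networkSizes)
  # frontal counts per network: proportional to size x frontal weight,
  # scaled so the total matches frontalFraction * nNodes
  w <- networkSizes * FRONTAL_WEIGHT[CANONICAL_NETWORKS]
  target <- frontalFraction * nNodes
  nFrontal <- largestRemainder(w / sum(w) * target)
  nFrontal <- pmin(nFrontal, networkSizes)
  lobe <- unlist(lapply(seq_along(networkSizes), function(k) {
    c(rep("frontal", nFrontal[k]),
      rep("other", networkSizes[k] - nFrontal[k]))
  }), use.names = FALSE)
  hemisphere <- unlist(lapply(networkSizes, function(nk) {
    rep(c("left", "right"), length.out = nk)
  }), use.names = FALSE)

  nodes <- data.frame(node_id = 0:(nNodes - 1L), network = network,
                      lobe = lobe, hemisphere = hemisphere,
                      stringsAsFactors = FALSE)
  new("Parcellation", nodes = nodes)
}

# integer apportionment of fractional counts, deterministic
largestRemainder <- function(x) {
  base <- floor(x)
  rem <- x - base
  short <- round(sum(x)) - sum(base)
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  structure(as.integer(base), names = names(x))
}

#' Predictor names of the node-wise strength features
#'
#' Canonical node-major ordering of the 6 strength estimates per node
#' (SC_intra, SC_inter, FCpos_intra, FCpos_inter, FCneg_intra, FCneg_inter),
#' optionally followed by the cognition score COG. A 400-node parcellation
#' therefore yields 2400 connectivity predictors (2401 with COG).
#'
#' @param parc a \code{\linkS4class{Parcellation}}.
#' @param includeCog append the \code{"COG"} predictor name?
#' @return character vector of predictor names.
#' @export
featureNames <- function(parc, includeCog = TRUE) {
  stopifnot(is(parc, "Parcellation"))
  fam <- c("SC_intra", "SC_inter", "FCpos_intra", "FCpos_inter",
           "FCneg_intra", "FCneg_inter")
  ids <- nodeTable(parc)$node_id
  nm <- as.vector(t(outer(sprintf("node%03d", ids), fam, paste, sep = "_")))
  if (includeCog) nm <- c(nm, "COG")
  nm
}

# per-predictor tags aligned with featureNames()
featureTags <- function(parc, includeCog = TRUE) {
  nd <- nodeTable(parc)
  fam <- c("SC_intra", "SC_inter", "FCpos_intra", "FCpos_inter",
           "FCneg_intra", "FCneg_inter")
  kind <- sub("_(intra|inter)$", "", fam)
  scope <- sub("^.*_", "", fam)
  tags <- data.frame(
    predictor = featureNames(parc, includeCog = FALSE),
    node_id = rep(nd$node_id, each = 6L),
    kind = rep(kind, times = nrow(nd)),
    scope = rep(scope, times = nrow(nd)),
    network = rep(nd$network, each = 6L),
    lobe = rep(nd$lobe, each = 6L),
    stringsAsFactors = FALSE)
  if (includeCog)
    tags <- rbind(tags, data.frame(predictor = "COG", node_id = NA_integer_,
                                   kind = "COG", scope = "global",
                                   network = NA_character_,
                                   lobe = NA_character_))
  tags
}
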