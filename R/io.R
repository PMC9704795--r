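# full-precision numeric formatting so text round-trips are loss-free
fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a connectivity matrix as annotated TSV
#'
#' Plain-text matrix format: comment header lines carry the kind tag, the
#' log-transform flag and the node order; the body is a tab-separated
#' full-precision numeric matrix. Reading restores the
#' \code{\linkS4class{ConnectivityMatrix}} exactly; an \code{expectKind}
#' mismatch on load is an error.
#'
#' @param m a \code{\linkS4class{ConnectivityMatrix}}.
#' @param path file path.
#' @return \code{writeConnectivityMatrix} returns \code{path} invisibly;
#'   \code{readConnectivityMatrix} returns the matrix object.
#' @export
writeConnectivityMatrix <- function(m, path) {
  stopifnot(is(m, "ConnectivityMatrix"))
  v <- connValues(m)
  nodes <- rownames(v)
  if (is.null(nodes)) nodes <- sprintf("node%03d", seq_len(nrow(v)) - 1L)
  hdr <- c(sprintf("# kind: %s", connKind(m)),
           sprintf("# logTransformed: %s", m@logTransformed),
           sprintf("# nodes: %s", paste(nodes, collapse = "\t")))
  body <- apply(v, 1L, function(r) paste(fmtNum(r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @param expectKind optional kind tag the caller requires.
#' @export
readConnectivityMatrix <- function(path, expectKind = NULL) {
  if (!file.exists(path)) stop("no such matrix file: ", path)
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  kind <- sub("^# kind: ", "", grep("^# kind:", hdr, value = TRUE))
  logT <- as.logical(sub("^# logTransformed: ", "",
                         grep("^# logTransformed:", hdr, value = TRUE)))
  nodes <- strsplit(sub("^# nodes: ", "",
                        grep("^# nodes:", hdr, value = TRUE)), "\t")[[1]]
  if (!is.null(expectKind) && !identical(kind, expectKind))
    stop(sprintf("matrix file %s has kind '%s', expected '%s'",
                 path, kind, expectKind))
  body <- ln[!grepl("^#", ln)]
  v <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  dimnames(v) <- list(nodes, nodes)
  new("ConnectivityMatrix", values = v, kind = kind, logTransformed = logT)
}

#' Write / read a parcellation lookup TSV
#'
#' Columns: \code{node_id}, \code{network}, \code{lobe},
#' \code{hemisphere}.
#'
#' @param parc a \code{\linkS4class{Parcellation}}.
#' @param path file path.
#' @export
writeParcellation <- function(parc, path) {
  utils::write.table(nodeTable(parc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeParcellation
#' @export
readParcellation <- function(path) {
  if (!file.exists(path)) stop("no such parcellation file: ", path)
  nd <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  new("Parcellation", nodes = nd)
}

#' Serialize / restore a synthetic cohort as plain text
#'
#' Layout under \code{dir}: \code{subjects.tsv} (subject table),
#' \code{parcellation.tsv}, \code{truth.json} (planted ground truth
#' including the per-subject latent values), and per-subject matrix files
#' \code{ts_<id>.tsv} / \code{sc_<id>.tsv}.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub <- subjectTable(cohort)
  latCols <- grep("^latent_", colnames(sub), value = TRUE)
  pub <- sub[, setdiff(colnames(sub), latCols)]
  num <- vapply(pub, is.numeric, logical(1))
  pub[num] <- lapply(pub[num], fmtNum)
  utils::write.table(pub, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeParcellation(parcellation(cohort), file.path(dir, "parcellation.tsv"))
  tr <- groundTruth(cohort)
  jsonlite::write_json(list(
    nComponents = tr@nComponents,
    ageEffectCog = tr@ageEffectCog,
    frontalDeclineRate = tr@frontalDeclineRate,
    otherDeclineRate = tr@otherDeclineRate,
    noise = as.list(tr@noise),
    componentLoadings = tr@componentLoadings,
    seed = cohort@seed,
    latents = sub[, latCols, drop = FALSE]
  ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  for (id in sub$subject_id) {
    writePlainMatrix(cohort@timeseries[[id]],
                     file.path(dir, sprintf("ts_%s.tsv", id)))
    writePlainMatrix(cohort@sc[[id]],
                     file.path(dir, sprintf("sc_%s.tsv", id)))
  }
  invisible(dir)
}

writePlainMatrix <- function(m, path) {
  writeLines(apply(m, 1L, function(r) paste(fmtNum(r), collapse = "\t")),
             path)
  invisible(path)
}

readPlainMatrix <- function(path) {
  do.call(rbind, lapply(strsplit(readLines(path), "\t"), as.numeric))
}

#' Write a feature block as TSV plus a JSON tag sidecar
#'
#' The TSV holds subjects in rows and named predictors in columns (plus the
#' subject covariates up front); the sidecar records the per-predictor
#' node/kind/scope/network/lobe tags.
#'
#' @param fb a \code{\linkS4class{FeatureBlock}}.
#' @param path TSV path; the sidecar is \code{<path>.tags.json}.
#' @export
writeFeatureBlock <- function(fb, path) {
  X <- t(SummarizedExperiment::assay(fb, "features"))
  cd <- as.data.frame(SummarizedExperiment::colData(fb))
  keep <- intersect(c("subject_id", "age", "sex", "education"), colnames(cd))
  out <- cbind(cd[, keep, drop = FALSE], as.data.frame(X))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmtNum)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.data.frame(SummarizedExperiment::rowData(fb)),
                       paste0(path, ".tags.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a named list of metrics as JSON
#'
#' @param metrics named list of scalars/vectors.
#' @param path JSON path.
#' @export
writeMetrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
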