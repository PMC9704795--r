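testColumns <- function(battery) grep("^test_", colnames(battery), value = TRUE)

# sex x age-decade stratum labels; the decades cover 55-64, 65-74, 75-84
# and 85+ (contiguous cover of the cohort range)
strataLabels <- function(battery) {
  dec <- cut(battery$age, breaks = c(-Inf, 65, 75, 85, Inf),
             labels = c("55-64", "65-74", "75-84", "85+"), right = FALSE)
  interaction(battery$sex, dec, drop = FALSE, sep = ":")
}

#' Screen the cognitive battery and impute sparse missingness
#'
#' Subjects with three or more missing test scores are excluded; a subject's
#' one or two remaining missing values are replaced by the median of that
#' test within the subject's sex-by-age-decade stratum (decades 55-64,
#' 65-74, 75-84, 85+), computed over the screened sample.
#'
#' @param battery \code{data.frame} with \code{subject_id}, \code{age},
#'   \code{sex} and the 16 \code{test_*} columns.
#' @return the screened, fully imputed battery (same columns, possibly
#'   fewer rows).
#' @export
screenAndImpute <- function(battery) {
  tests <- testColumns(battery)
  if (length(tests) == 0L) stop("no test_* columns found")
  nMiss <- rowSums(is.na(battery[, tests, drop = FALSE]))
  keep <- nMiss < 3L
  out <- battery[keep, , drop = FALSE]
  if (!any(is.na(out[, tests]))) return(out)
  strata <- strataLabels(out)
  for (tc in tests) {
    miss <- which(is.na(out[[tc]]))
    for (i in miss) {
      inStratum <- out[[tc]][strata == strata[i]]
      med <- median(inStratum, na.rm = TRUE)
      if (is.na(med))
        stop(sprintf("stratum '%s' has no observed values for %s",
                     as.character(strata[i]), tc))
      out[[tc]][i] <- med
    }
  }
  out
}

#' Exclude per-test outliers beyond mean +/- 3 SD
#'
#' A subject is removed when any test score lies outside the interval
#' mean +/- 3 SD of that test, with the mean and SD computed on the
#' screened sample handed in. Tests with zero SD exclude nobody.
#'
#' @param battery screened, imputed battery (at least 3 subjects).
#' @return the retained battery.
#' @export
excludeOutliers <- function(battery) {
  tests <- testColumns(battery)
  if (nrow(battery) < 3L) stop("at least 3 subjects are required")
  X <- as.matrix(battery[, tests, drop = FALSE])
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  lo <- mu - 3 * s
  hi <- mu + 3 * s
  bad <- sweep(X, 2L, lo, "<") | sweep(X, 2L, hi, ">")
  bad[, s == 0] <- FALSE
  battery[rowSums(bad) == 0L, , drop = FALSE]
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO index of a battery: the ratio of the summed squared
#' off-diagonal correlations to that sum plus the summed squared
#' anti-image partial correlations, the latter obtained from the inverse
#' correlation matrix. Values near 1 indicate data well suited to
#' PCA/factor analysis; values near 0.5 or below indicate unsuitability.
#'
#' @param x numeric matrix or battery \code{data.frame} (test columns are
#'   used when present).
#' @return KMO value in [0, 1].
#' @export
kmo <- function(x) {
  if (is.data.frame(x)) {
    tests <- testColumns(x)
    x <- as.matrix(x[, if (length(tests)) tests else seq_along(x)])
  }
  r <- cor(x)
  inv <- tryCatch(solve(r),
                  error = function(e) stop("correlation matrix is singular"))
  d <- 1 / sqrt(diag(inv))
  q <- -inv * outer(d, d)          # anti-image partial correlations
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' PCA-based global cognition score
#'
#' First principal component of the standardized test battery (PCA on the
#' correlation matrix, since the tests carry incommensurate units). The
#' component sign is fixed so that the majority of test loadings are
#' positive, i.e. higher COG = better performance; scores are standardized
#' to zero mean and unit variance over the retained subjects.
#'
#' @param battery screened, imputed, outlier-cleaned battery.
#' @return a \code{\linkS4class{CogComposite}}.
#' @export
pcaCog <- function(battery) {
  tests <- testColumns(battery)
  if (nrow(battery) < length(tests))
    stop("fewer subjects than tests; PCA would be degenerate")
  X <- as.matrix(battery[, tests, drop = FALSE])
  s <- apply(X, 2L, sd)
  if (any(s == 0)) stop("constant test score(s); cannot standardize")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (mean(load > 0) < 0.5) {
    load <- -load
    scores <- -scores
  }
  scores <- as.numeric(scale(scores))
  names(scores) <- battery$subject_id
  new("CogComposite", scores = scores, loadings = load,
      explainedVariance = pc$sdev[1]^2 / sum(pc$sdev^2),
      kmo = kmo(X), subjectIds = as.character(battery$subject_id))
}

#' Full cognition pipeline: screen, impute, exclude, KMO, PCA
#'
#' Fixed-order composition of \code{\link{screenAndImpute}},
#' \code{\link{excludeOutliers}} and \code{\link{pcaCog}} (which records the
#' KMO of the battery it decomposes).
#'
#' @param battery raw battery \code{data.frame}.
#' @return list with \code{composite} (a
#'   \code{\linkS4class{CogComposite}}) and \code{battery} (the retained,
#'   cleaned battery).
#' @export
cognitionComposite <- function(battery) {
  cleaned <- excludeOutliers(screenAndImpute(battery))
  list(composite = pcaCog(cleaned), battery = cleaned)
}
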