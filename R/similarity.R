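# Fixed-length pooling and the five similarity/distance measures.

METRICS <- c("jaccard", "correlation", "cosine", "cityblock", "euclidean")
FEATURE_KINDS <- c("rasta_plpcc", "mfcc", "lsf")

#' Pool frame features to a fixed-length vector
#'
#' Element-wise mean (default) or median across frames; the whole-call
#' feature vector the similarity measures operate on.
#'
#' @param ff A `frame_features` matrix (or any numeric matrix with one row
#'   per frame).
#' @param method `"mean"` or `"median"`.
#' @return Numeric vector of length `ncol(ff)` with attributes `kind` and
#'   `pooling`.
#' @export
pool_frames <- function(ff, method = c("mean", "median")) {
  method <- match.arg(method)
  m <- unclass(as.matrix(ff))
  if (nrow(m) < 1L) abort("no valid frames to pool")
  if (!all(is.finite(m))) abort("frame features must be finite")
  v <- if (method == "mean") colMeans(m) else apply(m, 2L, median)
  structure(v, kind = attr(ff, "kind"), pooling = method)
}

#' Jaccard distance between two feature vectors
#'
#' In `"magnitude"` mode (default) the generalized (Ruzicka) form on
#' magnitudes: `1 - sum(min(|a|, |b|)) / sum(max(|a|, |b|))`. In `"binary"`
#' mode the vectors are reduced to support indicators (nonzero entries) and
#' the classical set form `1 - |A n B| / |A u B|` is used. Satisfies
#' non-negativity, symmetry and the triangle inequality; two all-zero
#' vectors are defined as identical (distance 0).
#'
#' @param a,b Numeric vectors of equal length.
#' @param mode `"magnitude"` or `"binary"`.
#' @return Distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b, mode = c("magnitude", "binary")) {
  mode <- match.arg(mode)
  check_dims(a, b)
  if (mode == "binary") {
    a <- as.numeric(a != 0)
    b <- as.numeric(b != 0)
  } else {
    a <- abs(a)
    b <- abs(b)
  }
  denom <- sum(pmax(a, b))
  if (denom == 0) {
    inform("both vectors all-zero: Jaccard distance defined as 0")
    return(0)
  }
  1 - sum(pmin(a, b)) / denom
}

#' Correlation coefficient between two feature vectors
#'
#' The uncentered normalized inner product `<a, b> / (||a|| ||b||)` (the
#' cosine of the angle between the vectors), ranging from +1 (perfect
#' correlation) to -1 (perfect anticorrelation). A centered (mean-removed)
#' variant is available behind `centered = TRUE`.
#'
#' @param a,b Numeric vectors of equal length, both nonzero.
#' @param centered Subtract each vector's mean first.
#' @return Value in \[-1, 1\].
#' @export
correlation_coefficient <- function(a, b, centered = FALSE) {
  check_dims(a, b)
  if (centered) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("correlation undefined for a zero vector")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Angular similarity between two feature vectors
#'
#' The arc cosine of the [correlation_coefficient]: the angle between the
#' vectors, in radians.
#'
#' @inheritParams correlation_coefficient
#' @return Angle in \[0, pi\].
#' @export
angular_similarity <- function(a, b, centered = FALSE) {
  acos(correlation_coefficient(a, b, centered = centered))
}

#' Minkowski distance between two feature vectors
#'
#' `p = 1` is the city-block metric, `p = 2` the Euclidean metric.
#'
#' @param a,b Numeric vectors of equal length.
#' @param p Norm order (>= 1).
#' @return Non-negative distance.
#' @export
lp_distance <- function(a, b, p = 2) {
  check_dims(a, b)
  if (p < 1) abort("p must be >= 1")
  sum(abs(a - b)^p)^(1 / p)
}

check_dims <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("dimension mismatch: %d vs %d", length(a), length(b)))
  }
  invisible(TRUE)
}

# Distance under a named metric; similarities are mapped to distances
# (correlation -> 1 - r) so ranking is uniformly ascending.
metric_distance <- function(a, b, metric = METRICS) {
  metric <- match.arg(metric)
  switch(metric,
    jaccard     = jaccard_distance(a, b),
    correlation = 1 - correlation_coefficient(a, b),
    cosine      = angular_similarity(a, b),
    cityblock   = lp_distance(a, b, 1),
    euclidean   = lp_distance(a, b, 2)
  )
}

#' Rank a candidate library against a query
#'
#' Computes the distance from the query vector to every candidate under the
#' chosen metric and ranks candidates by ascending distance. Ties are broken
#' deterministically by lexicographic candidate id.
#'
#' @param query Numeric feature vector.
#' @param candidates Named list of numeric vectors (or a matrix with row
#'   names), all of the query's dimension.
#' @param metric One of `"jaccard"`, `"correlation"`, `"cosine"`,
#'   `"cityblock"`, `"euclidean"`.
#' @param query_id Identifier recorded in the output.
#' @return A `ranked_matches` tibble with columns `query_id`,
#'   `candidate_id`, `distance`, `rank` (1 = closest), and attributes
#'   `metric` and `kind`.
#' @export
rank_library <- function(query, candidates, metric = METRICS,
                         query_id = "query") {
  metric <- match.arg(metric)
  if (is.matrix(candidates)) {
    candidates <- stats::setNames(
      lapply(seq_len(nrow(candidates)), function(i) candidates[i, ]),
      rownames(candidates))
  }
  if (length(candidates) == 0L) abort("candidate list is empty")
  ids <- names(candidates)
  if (is.null(ids) || anyNA(ids)) abort("candidates must be named")
  d <- vapply(candidates, function(v) metric_distance(query, v, metric),
              numeric(1))
  ord <- order(d, ids, method = "radix")
  out <- tibble(
    query_id = query_id,
    candidate_id = ids[ord],
    distance = unname(d[ord]),
    rank = seq_along(ord)
  )
  attr(out, "metric") <- metric
  attr(out, "kind") <- attr(query, "kind")
  class(out) <- c("ranked_matches", class(out))
  out
}
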