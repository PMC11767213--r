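# Proximity geometry: dissimilarity from forest proximity, classical
# (Torgerson) multidimensional scaling, multivariate-normal confidence
# ellipses and within-class distance summaries.

#' Convert a proximity matrix to a dissimilarity matrix
#'
#' `d = 1 - proximity`, zero diagonal. The result is not guaranteed to
#' satisfy the triangle inequality.
#'
#' @param proximity Symmetric matrix with values in [0, 1], unit diagonal.
#' @return Distance matrix of the same shape.
#' @export
proximity_to_distance <- function(proximity) {
  if (!isSymmetric(unname(proximity), tol = 1e-8)) {
    stopf("proximity matrix must be symmetric")
  }
  d <- 1 - proximity
  diag(d) <- 0
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres `-D^2 / 2` and embeds on the top eigenvectors scaled by
#' the square roots of their eigenvalues. Deterministic up to sign and
#' rotation. Negative eigenvalues among the requested dimensions are
#' truncated to zero with a warning (the distances are then not Euclidean).
#'
#' @param distances Square symmetric distance matrix.
#' @param dims Embedding dimension.
#' @return An `ordination_result`: list with `points` (n x dims), `eig`
#'   (all eigenvalues).
#' @export
classical_mds <- function(distances, dims = 2) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
    stopf("distances must be a square symmetric matrix")
  }
  n <- nrow(d)
  if (dims >= n) stopf("dims must be smaller than the number of samples")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  lambda <- e$values[seq_len(dims)]
  if (any(lambda < 0)) {
    warnf("negative eigenvalue(s) truncated to zero; distances are non-Euclidean")
    lambda <- pmax(lambda, 0)
  }
  pts <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lambda), dims)
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = e$values), class = "ordination_result")
}

#' Multivariate-normal confidence ellipse for a class cloud
#'
#' Centre = mean, shape = sample covariance, boundary at the chi-square
#' quantile with 2 degrees of freedom of the requested level. A point `p`
#' lies inside iff its squared Mahalanobis distance from the centre is at
#' most `qchisq(level, 2)`.
#'
#' @param coords n x 2 coordinate matrix of one class (n >= 3).
#' @param level Confidence level.
#' @return List with `centre`, `cov`, `radius` (= sqrt of the chi-square
#'   quantile) and `level`.
#' @export
confidence_ellipse <- function(coords, level = 0.95) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stopf("confidence ellipse needs at least 3 points")
  if (ncol(coords) != 2) stopf("coords must be 2-dimensional")
  centre <- colMeans(coords)
  covm <- stats::cov(coords)
  if (any(eigen(covm, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stopf("covariance is not positive semi-definite")
  }
  list(centre = centre, cov = covm,
       radius = sqrt(stats::qchisq(level, df = 2)), level = level)
}

#' Fraction of points inside a confidence ellipse
#'
#' @param ellipse Result of [confidence_ellipse()].
#' @param points m x 2 matrix of test points.
#' @return Fraction inside the ellipse boundary.
#' @export
ellipse_coverage <- function(ellipse, points) {
  md2 <- stats::mahalanobis(as.matrix(points), ellipse$centre, ellipse$cov)
  mean(md2 <= ellipse$radius^2)
}

#' Within-class pairwise distance summary
#'
#' For each class, the multiset of pairwise distances between its samples
#' and the median of that multiset. Classes of size 1 yield an empty
#' multiset and an `NA` median, flagged in the summary.
#'
#' @param distances Square symmetric distance matrix with sample ids as
#'   dimnames.
#' @param classes Class labels aligned with the rows of `distances`.
#' @return List with `distances` (named list of numeric vectors) and
#'   `summary` (data.frame: `class`, `n_samples`, `n_pairs`, `median`).
#' @export
intraclass_distance_summary <- function(distances, classes) {
  d <- as.matrix(distances)
  if (length(classes) != nrow(d)) {
    stopf("classes must have one label per sample")
  }
  cls <- split(seq_len(nrow(d)), classes)
  dist_list <- lapply(cls, function(idx) {
    if (length(idx) < 2) return(numeric(0))
    sub <- d[idx, idx, drop = FALSE]
    sub[upper.tri(sub)]
  })
  summary <- data.frame(
    class = names(cls),
    n_samples = lengths(cls),
    n_pairs = vapply(dist_list, length, integer(1)),
    median = vapply(dist_list, function(v) {
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(distances = dist_list, summary = summary)
}
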