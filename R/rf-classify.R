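# Random-forest classification of fingerprint matrices: out-of-bag vote
# margins, permutation-based significance and out-of-bag proximity
# geometry. The forest engine is randomForest; margins, permutation nulls
# and proximity handling are defined here.

#' Fit a random-forest classifier on a fingerprint matrix
#'
#' Trains a forest and returns out-of-bag vote fractions, the mean vote
#' margin and (optionally) the out-of-bag proximity matrix, i.e. the
#' fraction of trees in which two samples co-occupy a terminal node,
#' counted over trees where both are out of bag.
#'
#' @param x Numeric matrix, samples x features (log2 intensities).
#' @param y Class labels (coerced to factor); at least 2 classes with at
#'   least 2 samples each.
#' @param n_trees Number of trees.
#' @param seed RNG seed.
#' @param proximity Compute the OOB proximity matrix.
#' @param importance Compute permutation importance (mean decrease in
#'   accuracy).
#' @return An `rf_class_result`: list with `classes`, `votes` (rows sum to
#'   1), `per_sample_margin`, `margin`, `proximity` (or `NULL`),
#'   `importance` (or `NULL`), `n_trees`, `seed`.
#' @export
fit_rf_classifier <- function(x, y, n_trees = 1000, seed = 1,
                              proximity = TRUE, importance = FALSE) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("classification needs at least 2 classes")
  if (any(table(y) < 2)) stopf("every class needs at least 2 samples")
  if (nrow(x) != length(y)) stopf("x and y disagree on the number of samples")
  if (all(apply(x, 2, stats::sd) == 0)) {
    warnf("feature matrix is constant; votes will be uninformative")
  }
  rf <- with_seed(seed, randomForest::randomForest(
    x, y, ntree = n_trees, proximity = proximity, oob.prox = proximity,
    importance = importance
  ))
  votes <- rf$votes / rowSums(rf$votes)  # guard against zero-OOB rounding
  prox <- NULL
  if (proximity) {
    prox <- rf$proximity
    diag(prox) <- 1
    dimnames(prox) <- list(rownames(x), rownames(x))
  }
  imp <- if (importance) rf$importance[, "MeanDecreaseAccuracy"] else NULL
  m <- margin_statistic(votes, y, per_sample = TRUE)
  structure(
    list(classes = levels(y), y = y, votes = votes,
         per_sample_margin = m, margin = mean(m, na.rm = TRUE),
         proximity = prox, importance = imp,
         n_trees = n_trees, seed = seed),
    class = "rf_class_result"
  )
}

#' @export
print.rf_class_result <- function(x, ...) {
  cat(sprintf("rf_class_result: %d samples, classes {%s}, margin %.4f\n",
              nrow(x$votes), paste(x$classes, collapse = ", "), x$margin))
  invisible(x)
}

#' Vote margin statistic
#'
#' Per-sample margin = vote fraction for the true class minus the largest
#' vote fraction among the other classes; the statistic is the mean over
#' samples. Ranges over [-1, 1]; 0 is chance-level separation.
#'
#' @param votes Matrix of vote fractions (samples x classes, rows sum to 1).
#' @param y True class labels aligned with the rows of `votes`.
#' @param per_sample Return the per-sample margins instead of their mean.
#' @return Mean margin, or the per-sample margin vector.
#' @export
margin_statistic <- function(votes, y, per_sample = FALSE) {
  y <- as.character(y)
  if (!all(y %in% colnames(votes))) {
    stopf("labels missing from the vote matrix columns")
  }
  idx <- match(y, colnames(votes))
  own <- votes[cbind(seq_len(nrow(votes)), idx)]
  other <- vapply(seq_len(nrow(votes)), function(i) {
    max(votes[i, -idx[i]])
  }, numeric(1))
  m <- own - other
  if (per_sample) m else mean(m, na.rm = TRUE)
}

#' Permutation test for forest statistics
#'
#' Permutes the labels (or numeric response) `n_perm` times, refitting a
#' fresh forest each time, and compares the observed statistic with the
#' permutation null using the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so p is never 0.
#'
#' @param x Feature matrix.
#' @param y Class labels (`statistic = "margin"`) or numeric response
#'   (`statistic = "r2"`).
#' @param statistic `"margin"` or `"r2"`.
#' @param n_perm Number of permutations.
#' @param n_trees Trees per forest (observed and null fits alike).
#' @param seed RNG seed governing both the forests and the permutations.
#' @return List with `observed`, `null` (length `n_perm`), `p`, `n_perm`.
#' @export
permutation_test <- function(x, y, statistic = c("margin", "r2"),
                             n_perm = 3000, n_trees = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  stat_fun <- switch(statistic,
    margin = function(yy, s) {
      fit_rf_classifier(x, yy, n_trees = n_trees, seed = s,
                        proximity = FALSE)$margin
    },
    r2 = function(yy, s) {
      fit_rf_regressor(x, yy, n_trees = n_trees, seed = s,
                       n_perm_importance = 0)$r_squared
    }
  )
  observed <- stat_fun(y, derive_seed(seed, "observed"))
  null <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) {
      yy <- y[sample.int(length(y))]
      stat_fun(yy, derive_seed(seed, paste0("perm", b)))
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm), n_perm = n_perm)
}

#' Pairwise binary-classification margin dendrogram
#'
#' Fits a binary forest for every pair of classes, records its margin
#' (larger margin = more separable = more distant) and clusters the classes
#' by average linkage on the margin matrix treated as a dissimilarity.
#' Classes with fewer than 2 samples are excluded with a message.
#'
#' @param x Feature matrix.
#' @param y Class labels over k >= 3 classes.
#' @param n_trees Trees per pairwise forest.
#' @param seed RNG seed.
#' @param n_perm Permutations for per-pair significance (0 skips the test).
#' @return List with `margins` (symmetric k x k matrix), `p_values` (same
#'   shape, `NA` when `n_perm = 0`), `hclust` (average-linkage tree).
#' @export
pairwise_margin_dendrogram <- function(x, y, n_trees = 1000, seed = 1,
                                       n_perm = 0) {
  y <- droplevels(as.factor(y))
  sizes <- table(y)
  drop_cls <- names(sizes)[sizes < 2]
  if (length(drop_cls)) {
    message(sprintf("excluding class(es) with < 2 samples: %s",
                    paste(drop_cls, collapse = ", ")))
    keep <- !y %in% drop_cls
    x <- x[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  k <- nlevels(y)
  if (k < 3) stopf("pairwise dendrogram needs at least 3 usable classes")
  cls <- levels(y)  # lexicographic factor order breaks ties deterministically
  margins <- matrix(0, k, k, dimnames = list(cls, cls))
  p_values <- matrix(NA_real_, k, k, dimnames = list(cls, cls))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      sel <- y %in% cls[c(i, j)]
      xi <- x[sel, , drop = FALSE]
      yi <- droplevels(y[sel])
      s <- derive_seed(seed, paste0("pair", i, "_", j))
      margins[i, j] <- margins[j, i] <-
        fit_rf_classifier(xi, yi, n_trees = n_trees, seed = s,
                          proximity = FALSE)$margin
      if (n_perm > 0) {
        p_values[i, j] <- p_values[j, i] <-
          permutation_test(xi, yi, "margin", n_perm = n_perm,
                           n_trees = n_trees, seed = s)$p
      }
    }
  }
  hc <- stats::hclust(stats::as.dist(margins), method = "average")
  list(margins = margins, p_values = p_values, hclust = hc)
}
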