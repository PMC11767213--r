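# Diurnal trend analysis: per-feature log2 abundance ratios relative to the
# baseline sampling time, k-means clustering of the ratio profiles, and
# box-plot summaries of single features.

#' Log2 abundance-ratio profiles relative to a baseline timepoint
#'
#' For each feature and timepoint, the median log2 intensity across that
#' timepoint's samples minus the baseline timepoint's median (a difference
#' of log2 values, i.e. a log2 ratio). The baseline entry is 0 by
#' construction and profiles are invariant to adding a constant to all
#' log2 values of a feature.
#'
#' @param fm [feature_matrix()] at stage `log2`.
#' @param samples Sample metadata with `sample_id`, `role`, `timepoint`.
#' @param features Feature (bin) ids to profile; default all.
#' @param baseline Baseline timepoint label.
#' @param timepoints Timepoint ordering; defaults to order of appearance.
#' @return A `trend_profiles` object: matrix features x timepoints of log2
#'   ratios, with the timepoint labels as colnames.
#' @export
log2_ratio_profiles <- function(fm, samples, features = NULL,
                                baseline = "09:00", timepoints = NULL) {
  check_stage(fm, "log2", "log2_ratio_profiles")
  features <- features %||% colnames(fm$values)
  missing_feat <- setdiff(features, colnames(fm$values))
  if (length(missing_feat)) {
    stopf("features not in the matrix: %s",
          paste(utils::head(missing_feat, 5), collapse = ", "))
  }
  bio <- samples[samples$role == "sample" & !is.na(samples$timepoint), ,
                 drop = FALSE]
  timepoints <- timepoints %||% unique(bio$timepoint)
  if (!baseline %in% timepoints) {
    stopf("baseline timepoint '%s' not present", baseline)
  }
  groups <- lapply(timepoints, function(tp) {
    ids <- bio$sample_id[bio$timepoint == tp]
    if (!length(ids)) stopf("timepoint '%s' has zero samples", tp)
    intersect(ids, rownames(fm$values))
  })
  med <- vapply(groups, function(ids) {
    apply(fm$values[ids, features, drop = FALSE], 2, stats::median)
  }, numeric(length(features)))
  med <- matrix(med, nrow = length(features),
                dimnames = list(features, timepoints))
  prof <- med - med[, baseline]
  structure(prof, class = c("trend_profiles", "matrix"),
            baseline = baseline)
}

#' Cluster trend profiles with k-means
#'
#' Euclidean k-means with seeded random restarts; the restart with the
#' smallest total within-cluster sum of squares is kept. Centroid profiles
#' describe the cluster-average diurnal shapes.
#'
#' @param profiles A `trend_profiles` matrix (features x timepoints).
#' @param k Number of clusters.
#' @param n_restarts Random restarts.
#' @param seed RNG seed.
#' @return List with `cluster` (named assignment vector), `centroids`
#'   (k x timepoints), `withinss`, `tot_withinss`, `sizes`.
#' @export
kmeans_trends <- function(profiles, k = 5, n_restarts = 10, seed = 1) {
  m <- unclass(profiles)
  if (!all(is.finite(m))) stopf("trend profiles must be finite")
  if (k > nrow(m)) {
    stopf("k (%d) exceeds the number of features (%d)", k, nrow(m))
  }
  if (k == nrow(m)) {
    # degenerate: every feature is its own cluster
    return(list(cluster = stats::setNames(seq_len(nrow(m)), rownames(m)),
                centroids = m, withinss = rep(0, k), tot_withinss = 0,
                sizes = rep(1L, k)))
  }
  km <- with_seed(derive_seed(seed, "kmeans"), {
    stats::kmeans(m, centers = k, nstart = n_restarts, iter.max = 100)
  })
  list(cluster = stats::setNames(km$cluster, rownames(m)),
       centroids = km$centers, withinss = km$withinss,
       tot_withinss = km$tot.withinss, sizes = km$size)
}

#' Elbow / silhouette style report over candidate k
#'
#' Total within-cluster sum of squares for each candidate k, to support
#' choosing the cluster count.
#'
#' @param profiles A `trend_profiles` matrix.
#' @param k_range Candidate cluster counts.
#' @inheritParams kmeans_trends
#' @return data.frame with `k` and `tot_withinss`.
#' @export
kmeans_elbow <- function(profiles, k_range = 2:8, n_restarts = 10, seed = 1) {
  k_range <- k_range[k_range <= nrow(profiles)]
  data.frame(
    k = k_range,
    tot_withinss = vapply(k_range, function(k) {
      kmeans_trends(profiles, k, n_restarts, seed)$tot_withinss
    }, numeric(1))
  )
}

#' Box-plot summary of one feature by group
#'
#' Per group: quartiles (type-7), whisker limits at the most extreme data
#' points within 1.5 x IQR of the quartiles, and the outliers beyond them.
#'
#' @param fm A [feature_matrix()] (any stage).
#' @param samples Sample metadata.
#' @param feature Bin id.
#' @param group Metadata column to group by (e.g. `"timepoint"`).
#' @return data.frame with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `outliers` (`;`-joined).
#' @export
feature_boxplot_summary <- function(fm, samples, feature,
                                    group = "timepoint") {
  if (!feature %in% colnames(fm$values)) {
    stopf("feature '%s' not in the matrix", feature)
  }
  bio <- samples[samples$role == "sample" & !is.na(samples[[group]]), ,
                 drop = FALSE]
  grp <- split(bio$sample_id, bio[[group]])
  if (any(lengths(grp) == 0)) stopf("empty group")
  rows <- lapply(names(grp), function(g) {
    v <- fm$values[intersect(grp[[g]], rownames(fm$values)), feature]
    if (!length(v)) stopf("group '%s' has no samples in the matrix", g)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    iqr <- q[3] - q[1]
    lo_lim <- q[1] - 1.5 * iqr
    hi_lim <- q[3] + 1.5 * iqr
    inside <- v >= lo_lim & v <= hi_lim
    data.frame(
      group = g, n = length(v), median = unname(q[2]),
      q1 = unname(q[1]), q3 = unname(q[3]),
      whisker_lo = min(v[inside]), whisker_hi = max(v[inside]),
      outliers = paste(sort(v[!inside]), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
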