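# Spectral binning: centroided flow-infusion scans -> fixed-width m/z
# features, followed by the standard fingerprint post-processing chain
# (class occupancy filter, pooled-QC RSD filter, TIC normalisation, log2).

#' Select the infusion scan window
#'
#' Returns the maximal contiguous run of scans in which every scan's total
#' ion count is at least `tic_fraction` of the maximum scan TIC (the
#' infusion plateau). When several runs qualify, the one containing the TIC
#' maximum is returned.
#'
#' @param scans A [scan_set()] or a numeric vector of per-scan TICs.
#' @param tic_fraction Fraction of the maximum TIC a scan must reach.
#' @return Integer vector `c(first, last)` of scan indices.
#' @export
select_infusion_scans <- function(scans, tic_fraction = 0.5) {
  tic <- if (inherits(scans, "scan_set")) unname(scan_tic(scans)) else as.numeric(scans)
  if (!length(tic)) stopf("no scans to select from")
  if (all(tic == 0)) stopf("all scan TICs are zero; cannot locate the infusion profile")
  infusion_window(tic, tic_fraction)
}

infusion_window <- function(tic, tic_fraction) {
  ok <- tic >= tic_fraction * max(tic)
  peak <- which.max(tic)
  lo <- peak
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(tic) && ok[hi + 1]) hi <- hi + 1
  c(lo, hi)
}

#' Bin the scans of one sample into a feature vector
#'
#' Centroid intensities inside `mz_range` are summed into half-open
#' fixed-width bins `[k*w, (k+1)*w)` per ionisation mode and per scan, then
#' averaged over the scans in the infusion window. The bin id encodes the
#' mode and the bin's lower edge at bin-width precision; each bin also
#' carries its intensity-weighted mean centroid m/z as an accurate
#' representative mass for downstream annotation.
#'
#' @param scans A [scan_set()].
#' @param window Scan window `c(first, last)`; selected automatically with
#'   [select_infusion_scans()] when `NULL`.
#' @param bin_width Bin width in m/z units.
#' @param mz_range Half-open acquisition window `[lo, hi)`.
#' @param tic_fraction Used when `window` is `NULL`.
#' @return List with `intensity` (named vector over bin ids), `bins`
#'   (data.frame `bin_id`, `mode`, `mz`) and `n_excluded` (centroids outside
#'   `mz_range`).
#' @export
bin_scans <- function(scans, window = NULL, bin_width = 0.01,
                      mz_range = c(55, 1200), tic_fraction = 0.5) {
  if (!inherits(scans, "scan_set")) stopf("bin_scans expects a scan_set")
  if (bin_width <= 0) stopf("bin_width must be positive")
  pk <- scans$peaks
  if (!nrow(pk)) {
    return(list(intensity = stats::setNames(numeric(0), character(0)),
                bins = data.frame(bin_id = character(), mode = character(),
                                  mz = numeric(), stringsAsFactors = FALSE),
                n_excluded = 0L))
  }
  if (is.null(window)) window <- select_infusion_scans(scans, tic_fraction)
  if (window[1] < 1 || window[2] < window[1]) stopf("invalid scan window")
  n_window <- window[2] - window[1] + 1
  inside <- pk$mz >= mz_range[1] & pk$mz < mz_range[2]
  n_excluded <- sum(!inside)
  pk <- pk[inside & pk$scan >= window[1] & pk$scan <= window[2], , drop = FALSE]
  # half-open binning with a small guard against representation error at edges
  k <- floor(pk$mz / bin_width + 1e-6)
  key <- paste0(ifelse(pk$mode == "positive", "p", "n"), k)
  total <- tapply(pk$intensity, key, sum)
  wmz <- tapply(pk$intensity * pk$mz, key, sum) / total
  keys <- names(total)
  mode <- ifelse(substr(keys, 1, 1) == "p", "positive", "negative")
  k_out <- as.numeric(substring(keys, 2))
  bins <- data.frame(
    bin_id = bin_id_label(mode, k_out * bin_width, bin_width),
    mode = mode, mz = as.numeric(wmz), stringsAsFactors = FALSE
  )
  ord <- order(match(bins$mode, c("positive", "negative")), k_out)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  intensity <- as.numeric(total)[ord] / n_window
  names(intensity) <- bins$bin_id
  list(intensity = intensity, bins = bins, n_excluded = n_excluded)
}

#' Bin a collection of samples into a feature matrix
#'
#' Applies [bin_scans()] to every sample and assembles the union of bins
#' into a raw-stage [feature_matrix()]; bins absent from a sample get
#' intensity 0. Representative bin m/z is the intensity-weighted mean over
#' samples.
#'
#' @inheritParams bin_scans
#' @param scan_sets Named list of [scan_set()] objects.
#' @return A raw-stage [feature_matrix()].
#' @export
bin_samples <- function(scan_sets, window = NULL, bin_width = 0.01,
                        mz_range = c(55, 1200), tic_fraction = 0.5) {
  rows <- lapply(scan_sets, bin_scans, window = window, bin_width = bin_width,
                 mz_range = mz_range, tic_fraction = tic_fraction)
  all_bins <- unique(do.call(rbind, lapply(rows, `[[`, "bins"))["bin_id"])$bin_id
  values <- matrix(0, length(rows), length(all_bins),
                   dimnames = list(names(scan_sets) %||%
                                     vapply(scan_sets, `[[`, "", "sample_id"),
                                   all_bins))
  mz_num <- stats::setNames(numeric(length(all_bins)), all_bins)
  mz_den <- mz_num
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    values[i, r$bins$bin_id] <- r$intensity
    mz_num[r$bins$bin_id] <- mz_num[r$bins$bin_id] + r$bins$mz * r$intensity
    mz_den[r$bins$bin_id] <- mz_den[r$bins$bin_id] + r$intensity
  }
  bins <- parse_bin_ids(all_bins, bin_width)
  has <- mz_den > 0
  bins$mz[has] <- mz_num[has] / mz_den[has]
  ord <- order(match(bins$mode, c("positive", "negative")), bins$mz)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  feature_matrix(values[, bins$bin_id, drop = FALSE], bins = bins,
                 stage = "raw", bin_width = bin_width)
}

#' Class-occupancy filter
#'
#' Retains a bin iff in at least one class the fraction of biological
#' samples with non-zero intensity reaches `min_occupancy`. QC rows are
#' ignored when computing occupancy but kept in the matrix.
#'
#' @param fm [feature_matrix()] at stage `raw` (or re-applied at
#'   `occupancy_filtered`, a no-op-compatible stage).
#' @param samples Sample metadata with `sample_id`, `role` and the class
#'   column.
#' @param class_key Name of the class column.
#' @param min_occupancy Required within-class occupancy fraction.
#' @return Filtered matrix at stage `occupancy_filtered`.
#' @export
occupancy_filter <- function(fm, samples, class_key = "class",
                             min_occupancy = 2 / 3) {
  check_stage(fm, c("raw", "occupancy_filtered"), "occupancy_filter")
  if (!class_key %in% names(samples)) {
    stopf("class column '%s' not found in the sample table", class_key)
  }
  bio <- samples[samples$role == "sample", , drop = FALSE]
  if (!nrow(bio)) stopf("no biological samples in the sample table")
  cls <- split(bio$sample_id, bio[[class_key]])
  if (any(lengths(cls) == 0)) stopf("class with zero samples")
  occ <- matrix(
    unlist(lapply(cls, function(ids) colMeans(fm$values[ids, , drop = FALSE] > 0))),
    ncol = length(cls)
  )
  keep <- apply(occ, 1, max) >= min_occupancy
  message(sprintf("occupancy_filter: %d -> %d bins (threshold %.3f)",
                  ncol(fm$values), sum(keep), min_occupancy))
  subset_bins(fm, keep, stage = "occupancy_filtered")
}

#' Pooled-QC relative standard deviation filter
#'
#' Retains a bin iff its RSD (sd/mean, n-1 denominator) over the pooled-QC
#' injections is at most `max_rsd`. Bins whose QC mean is zero are dropped.
#'
#' @param fm [feature_matrix()] at stage `occupancy_filtered` (or
#'   re-applied at `qc_filtered`).
#' @param samples Sample metadata; QC rows are those with `role == "QC"`.
#' @param max_rsd Maximum allowed RSD (inclusive).
#' @return Filtered matrix at stage `qc_filtered`.
#' @export
qc_rsd_filter <- function(fm, samples, max_rsd = 0.5) {
  check_stage(fm, c("occupancy_filtered", "qc_filtered"), "qc_rsd_filter")
  qc_ids <- samples$sample_id[samples$role == "QC"]
  qc_ids <- intersect(qc_ids, rownames(fm$values))
  if (length(qc_ids) < 2) {
    stopf("qc_rsd_filter needs at least 2 QC injections, found %d",
          length(qc_ids))
  }
  qc <- fm$values[qc_ids, , drop = FALSE]
  m <- colMeans(qc)
  s <- apply(qc, 2, stats::sd)
  rsd <- ifelse(m > 0, s / m, Inf)
  if (any(m == 0)) {
    message(sprintf("qc_rsd_filter: %d bin(s) dropped for zero QC mean",
                    sum(m == 0)))
  }
  keep <- rsd <= max_rsd
  message(sprintf("qc_rsd_filter: %d -> %d bins (max RSD %.2f over %d QCs)",
                  ncol(fm$values), sum(keep), max_rsd, length(qc_ids)))
  subset_bins(fm, keep, stage = "qc_filtered")
}

#' Total-ion-current normalisation
#'
#' Scales every sample row so its bin sum equals the median
#' pre-normalisation row sum (a fixed, scale-free target).
#'
#' @param fm [feature_matrix()] at stage `qc_filtered`.
#' @return Matrix at stage `normalised`.
#' @export
normalise_tic <- function(fm) {
  check_stage(fm, "qc_filtered", "normalise_tic")
  sums <- rowSums(fm$values)
  if (any(sums == 0)) {
    stopf("cannot normalise all-zero sample row(s): %s",
          paste(rownames(fm$values)[sums == 0], collapse = ", "))
  }
  target <- stats::median(sums)
  fm$values <- fm$values * (target / sums)
  fm$stage <- "normalised"
  fm
}

#' Log2 transformation with half-minimum zero imputation
#'
#' Zeros are replaced by half the smallest non-zero value in the matrix,
#' then all values are log2-transformed.
#'
#' @param fm [feature_matrix()] at stage `normalised`.
#' @return Matrix at stage `log2`.
#' @export
log2_transform <- function(fm) {
  check_stage(fm, "normalised", "log2_transform")
  if (any(fm$values < 0)) stopf("negative intensities; input is corrupt")
  v <- fm$values
  nz <- v[v > 0]
  if (length(nz) && any(v == 0)) v[v == 0] <- min(nz) / 2
  fm$values <- log2(v)
  fm$stage <- "log2"
  fm
}
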