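# Specification object for the synthetic fingerprint generator. Defaults
# emulate the field design the pipeline targets: two classes of leaf samples
# (e.g. two garden locations of one cultivar), four diurnal sampling times
# (09:00, 12:00, 18:00, 00:00 over a single day, i.e. hours 0/3/9/15 since
# first sampling), pooled-QC injections with low technical dispersion, and a
# small planted set of class-discriminating and trend-following bins.

#' Specification for synthetic fingerprint data
#'
#' Defines the sampling design and signal structure of a synthetic FIE-MS
#' fingerprint dataset with known ground truth.
#'
#' @param classes Character vector of class labels (varieties or gardens).
#' @param n_per_class Biological samples per class.
#' @param class_key Name of the class column in the metadata.
#' @param timepoints Ordered clock labels of the sampling times.
#' @param hours Numeric hour offsets of `timepoints` (strictly increasing).
#' @param n_features Total number of m/z bins (split across both modes).
#' @param n_discriminating Number of planted class-separating bins.
#' @param effect_size Log2 mean shift applied to planted bins (>= 0).
#' @param trend_archetypes Named list of numeric vectors, one log2 offset per
#'   timepoint, describing planted diurnal trend shapes.
#' @param n_trend_features_per_archetype Planted bins per archetype
#'   (recycled across archetypes).
#' @param noise_sd Residual standard deviation on the log2 scale (> 0).
#' @param qc_n Number of pooled-QC injections.
#' @param qc_rsd Target relative standard deviation of QC intensities.
#' @param zero_rate Probability that an intensity in the lowest-intensity
#'   quartile is recorded as zero (detection-limit dropout), in [0, 1).
#' @param baseline_log2_range Range the per-bin baseline log2 intensity is
#'   drawn from (log-uniform on the raw scale).
#' @param mz_range Acquisition window for bin placement.
#' @param bin_width Bin width in m/z units.
#' @param seed RNG seed making all generators deterministic.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = c("garden3", "garden4"),
                           n_per_class = 24,
                           class_key = "class",
                           timepoints = c("09:00", "12:00", "18:00", "00:00"),
                           hours = c(0, 3, 9, 15),
                           n_features = 500,
                           n_discriminating = 10,
                           effect_size = 1,
                           trend_archetypes = NULL,
                           n_trend_features_per_archetype = 0,
                           noise_sd = 0.3,
                           qc_n = 5,
                           qc_rsd = 0.05,
                           zero_rate = 0,
                           baseline_log2_range = c(10, 20),
                           mz_range = c(55, 1200),
                           bin_width = 0.01,
                           seed = 1) {
  spec <- list(
    classes = as.character(classes), n_per_class = n_per_class,
    class_key = class_key, timepoints = as.character(timepoints),
    hours = as.numeric(hours), n_features = n_features,
    n_discriminating = n_discriminating, effect_size = effect_size,
    trend_archetypes = trend_archetypes,
    n_trend_features_per_archetype = n_trend_features_per_archetype,
    noise_sd = noise_sd, qc_n = qc_n, qc_rsd = qc_rsd,
    zero_rate = zero_rate, baseline_log2_range = as.numeric(baseline_log2_range),
    mz_range = as.numeric(mz_range), bin_width = bin_width, seed = seed
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!ok) stopf("invalid synthetic_spec field '%s': %s", field, msg)
  }
  chk(length(spec$classes) >= 1 && !anyDuplicated(spec$classes),
      "classes", "must be non-empty and unique")
  chk(length(spec$n_per_class) == 1 && spec$n_per_class >= 1,
      "n_per_class", "must be a positive count")
  chk(length(spec$timepoints) == length(spec$hours),
      "hours", "must have one offset per timepoint")
  chk(all(diff(spec$hours) > 0), "hours", "offsets must be strictly increasing")
  chk(spec$n_features >= 1, "n_features", "must be positive")
  chk(spec$n_discriminating >= 0, "n_discriminating", "must be non-negative")
  chk(spec$effect_size >= 0, "effect_size", "must be >= 0")
  chk(spec$noise_sd > 0, "noise_sd", "must be > 0")
  chk(spec$qc_n >= 0, "qc_n", "must be non-negative")
  chk(spec$qc_rsd >= 0, "qc_rsd", "must be non-negative")
  chk(spec$zero_rate >= 0 && spec$zero_rate < 1,
      "zero_rate", "must be in [0, 1)")
  n_trend <- 0L
  if (!is.null(spec$trend_archetypes)) {
    chk(is.list(spec$trend_archetypes) && length(spec$trend_archetypes) > 0,
        "trend_archetypes", "must be a non-empty list of numeric vectors")
    lens <- vapply(spec$trend_archetypes, length, integer(1))
    if (!all(lens == length(spec$timepoints))) {
      stopf("trend archetype length (%s) must equal the number of timepoints (%d)",
            paste(unique(lens), collapse = ","), length(spec$timepoints))
    }
    per <- rep_len(spec$n_trend_features_per_archetype,
                   length(spec$trend_archetypes))
    chk(all(per >= 0), "n_trend_features_per_archetype", "must be non-negative")
    n_trend <- sum(per)
  }
  chk(spec$n_discriminating + n_trend <= spec$n_features,
      "n_features",
      "planted discriminating + trend bins must not exceed n_features")
  invisible(spec)
}
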