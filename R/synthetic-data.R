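# Synthetic fingerprint generators. All generators are pure functions of
# (spec, seed): the same spec yields byte-identical output on every call.
#
# Latent model, per biological sample i and bin j (log2 scale):
#   y_ij = b_j + class shift + archetype offset at t(i) + N(0, noise_sd)
# with b_j ~ Uniform(baseline_log2_range). The returned matrix is raw-scale
# (2^y). Pooled-QC rows are drawn multiplicatively around the per-bin grand
# mean with relative s.d. qc_rsd. Detection-limit dropout sets raw
# intensities in the lowest-intensity quartile to zero with probability
# zero_rate.

#' Generate the sample metadata table
#'
#' One row per biological sample plus `qc_n` pooled-QC injections; run order
#' is a seeded random permutation of all injections.
#'
#' @param spec A [synthetic_spec()].
#' @return data.frame with columns `sample_id`, `role`, the class column
#'   (named by `spec$class_key`), `timepoint`, `hour`, `batch`, `run_order`.
#' @export
generate_metadata <- function(spec) {
  validate_synthetic_spec(spec)
  n_bio <- length(spec$classes) * spec$n_per_class
  tp_idx <- rep_len(seq_along(spec$timepoints), spec$n_per_class)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_bio)),
    role = "sample",
    class = rep(spec$classes, each = spec$n_per_class),
    timepoint = spec$timepoints[rep(tp_idx, length(spec$classes))],
    hour = spec$hours[rep(tp_idx, length(spec$classes))],
    batch = 1L,
    stringsAsFactors = FALSE
  )
  if (spec$qc_n > 0) {
    qc <- data.frame(
      sample_id = sprintf("QC%02d", seq_len(spec$qc_n)),
      role = "QC", class = "QC",
      timepoint = NA_character_, hour = NA_real_, batch = 1L,
      stringsAsFactors = FALSE
    )
    samples <- rbind(samples, qc)
  }
  names(samples)[names(samples) == "class"] <- spec$class_key
  samples$run_order <- with_seed(derive_seed(spec$seed, "metadata"),
                                 sample.int(nrow(samples)))
  samples
}

# lay out bins: alternating ionisation mode, unique m/z on the bin grid
generate_bins <- function(spec) {
  with_seed(derive_seed(spec$seed, "bins"), {
    n <- spec$n_features
    w <- spec$bin_width
    k_lo <- ceiling(spec$mz_range[1] / w)
    k_hi <- floor(spec$mz_range[2] / w) - 1L
    mode <- rep(c("positive", "negative"), length.out = n)
    # sample bin indices without replacement within each mode
    bins <- do.call(rbind, lapply(c("positive", "negative"), function(m) {
      nm <- sum(mode == m)
      if (!nm) return(NULL)
      k <- sort(sample(seq(k_lo, k_hi), nm))
      data.frame(bin_id = bin_id_label(m, k * w, w), mode = m,
                 mz = k * w + w / 2, stringsAsFactors = FALSE)
    }))
    rownames(bins) <- NULL
    bins
  })
}

#' Generate a synthetic feature matrix with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param reference Optional reference list from [generate_reference()]; when
#'   supplied, planted bins are placed at theoretical adduct m/z of reference
#'   compounds and the mapping is recorded in the ground truth.
#' @return A list with elements `samples` (metadata), `matrix` (raw-stage
#'   [feature_matrix()] including QC rows) and `truth` (list with
#'   `discriminating_bins`, `trend_bins`, `compound_truth`).
#' @export
generate_feature_matrix <- function(spec, reference = NULL) {
  validate_synthetic_spec(spec)
  samples <- generate_metadata(spec)
  bins <- generate_bins(spec)
  n <- spec$n_features
  bio <- samples[samples$role == "sample", , drop = FALSE]
  n_bio <- nrow(bio)
  cls <- bio[[spec$class_key]]
  tp <- match(bio$timepoint, spec$timepoints)

  # planted structure: first the discriminating bins, then the trend bins
  disc_idx <- seq_len(spec$n_discriminating)
  arch <- spec$trend_archetypes
  per <- if (is.null(arch)) integer(0) else
    rep_len(spec$n_trend_features_per_archetype, length(arch))
  trend_idx <- if (sum(per)) spec$n_discriminating + seq_len(sum(per)) else integer(0)
  trend_arch <- rep(seq_along(per), per)

  compound_truth <- NULL
  if (!is.null(reference) && length(c(disc_idx, trend_idx))) {
    planted <- c(disc_idx, trend_idx)
    compound_truth <- with_seed(derive_seed(spec$seed, "compound_truth"), {
      plant_compounds(bins, planted, reference, spec$bin_width)
    })
    bins <- attr(compound_truth, "bins")
    attr(compound_truth, "bins") <- NULL
  }

  out <- with_seed(derive_seed(spec$seed, "matrix"), {
    b <- stats::runif(n, spec$baseline_log2_range[1], spec$baseline_log2_range[2])
    latent <- matrix(rep(b, each = n_bio), n_bio, n)
    disc <- NULL
    if (length(disc_idx)) {
      # each planted bin separates one (cycled) non-reference class, with
      # alternating shift direction
      target <- rep_len(if (length(spec$classes) > 1)
        spec$classes[-1] else spec$classes, length(disc_idx))
      direction <- rep_len(c(1, -1), length(disc_idx))
      for (d in seq_along(disc_idx)) {
        j <- disc_idx[d]
        latent[cls == target[d], j] <-
          latent[cls == target[d], j] + direction[d] * spec$effect_size
      }
      disc <- data.frame(bin_id = bins$bin_id[disc_idx], class = target,
                         direction = direction, stringsAsFactors = FALSE)
    }
    trend <- NULL
    if (length(trend_idx)) {
      for (d in seq_along(trend_idx)) {
        j <- trend_idx[d]
        latent[, j] <- latent[, j] + arch[[trend_arch[d]]][tp]
      }
      trend <- data.frame(
        bin_id = bins$bin_id[trend_idx],
        archetype = names(arch)[trend_arch] %||% as.character(trend_arch),
        stringsAsFactors = FALSE
      )
    }
    latent <- latent + matrix(stats::rnorm(n_bio * n, 0, spec$noise_sd), n_bio, n)
    raw <- 2^latent
    if (spec$zero_rate > 0) {
      thr <- stats::quantile(raw, 0.25)
      drop <- raw < thr & matrix(stats::runif(n_bio * n) < spec$zero_rate, n_bio, n)
      raw[drop] <- 0
    }
    if (spec$qc_n > 0) {
      grand <- colMeans(raw)
      qc <- matrix(stats::rnorm(spec$qc_n * n, 0, spec$qc_rsd),
                   spec$qc_n, n, byrow = FALSE)
      qc <- sweep(pmax(1 + qc, 1e-6), 2, grand, `*`)
      raw <- rbind(raw, qc)
    }
    rownames(raw) <- samples$sample_id
    colnames(raw) <- bins$bin_id
    list(raw = raw, disc = disc, trend = trend)
  })

  list(
    samples = samples,
    matrix = feature_matrix(out$raw, bins = bins, stage = "raw",
                            bin_width = spec$bin_width),
    truth = list(
      discriminating_bins = out$disc,
      trend_bins = out$trend,
      compound_truth = compound_truth
    )
  )
}

# Re-site planted bins at theoretical adduct m/z of reference compounds so
# that annotation ground truth is exact. Caller wraps in with_seed.
plant_compounds <- function(bins, planted, reference, bin_width) {
  db <- reference$compounds
  rules <- reference$rules %||% adduct_rules()
  picks <- sample(nrow(db), length(planted), replace = nrow(db) < length(planted))
  rows <- vector("list", length(planted))
  for (i in seq_along(planted)) {
    j <- planted[i]
    cmp <- db[picks[i], ]
    ok <- rules[rules$polarity == bins$mode[j], , drop = FALSE]
    h <- tryCatch(parse_formula(cmp$formula)[["H"]], error = function(e) 0L)
    if (is.na(h)) h <- 0L
    ok <- ok[ok$min_h <= h & ok$n == 1, , drop = FALSE]
    rule <- ok[sample(nrow(ok), 1), ]
    mz <- theoretical_mz(cmp$mass, rule)
    k <- floor(mz / bin_width + 1e-9)
    bins$mz[j] <- mz
    bins$bin_id[j] <- bin_id_label(bins$mode[j], k * bin_width, bin_width)
    rows[[i]] <- data.frame(
      bin_id = bins$bin_id[j], compound_id = cmp$compound_id,
      formula = cmp$formula, adduct = rule$name, mz = mz,
      lineage = cmp$lineage, pathway_ids = cmp$pathway_ids,
      stringsAsFactors = FALSE
    )
  }
  # bin collisions with unplanted bins: drop the random bin by re-siting it
  out <- do.call(rbind, rows)
  dup <- duplicated(bins$bin_id)
  while (any(dup)) {
    for (j in which(dup)) {
      if (!j %in% planted) {
        k <- floor(bins$mz[j] / bin_width + 1e-9) + sample(100:1000, 1)
        bins$mz[j] <- k * bin_width + bin_width / 2
        bins$bin_id[j] <- bin_id_label(bins$mode[j], k * bin_width, bin_width)
      }
    }
    dup <- duplicated(bins$bin_id)
    if (any(dup[planted])) {
      stopf("planted compounds collide in the same bin; use a larger reference")
    }
  }
  attr(out, "bins") <- bins
  out
}

#' Expand a feature matrix into synthetic flow-infusion scans
#'
#' The inverse of binning, used for round-trip validation: each sample row
#' becomes `n_scans` centroided scans whose per-scan intensities follow a
#' triangular infusion profile, with centroid m/z jittered around the bin's
#' representative m/z by at most `centroid_jitter_ppm`.
#'
#' With `scale = "window"` (default) the profile is normalised so that its
#' mean over the scans retained by [select_infusion_scans()] at
#' `tic_fraction` is 1; binning the scans with matching parameters then
#' reproduces the matrix exactly (jitter 0). With `scale = "tic"` the
#' profile sums to 1 so the summed scan TIC equals the sample's total
#' intensity.
#'
#' @param fm Raw-stage [feature_matrix()].
#' @param centroid_jitter_ppm Maximum |jitter| in ppm; must stay below half
#'   a bin width at the top of the m/z range.
#' @param n_scans Scans per sample.
#' @param seed RNG seed.
#' @param scale Profile normalisation, `"window"` or `"tic"`.
#' @param tic_fraction TIC fraction defining the scan window (see
#'   [select_infusion_scans()]).
#' @return Named list of [scan_set()] objects, one per sample.
#' @export
matrix_to_scans <- function(fm, centroid_jitter_ppm = 0, n_scans = 5,
                            seed = 1, scale = c("window", "tic"),
                            tic_fraction = 0.5) {
  check_stage(fm, "raw", "matrix_to_scans")
  scale <- match.arg(scale)
  w <- fm$bin_width
  mz_max <- max(fm$bins$mz)
  max_jitter_da <- centroid_jitter_ppm * 1e-6 * mz_max
  if (max_jitter_da >= w / 2) {
    stopf(paste0("centroid jitter of %g ppm exceeds half a bin width at m/z %g; ",
                 "binned features would no longer be identifiable"),
          centroid_jitter_ppm, mz_max)
  }
  profile <- triangular_profile(n_scans)
  win <- infusion_window(profile, tic_fraction)
  weights <- switch(scale,
    window = profile / mean(profile[win[1]:win[2]]),
    tic = profile / sum(profile)
  )
  with_seed(seed, {
    out <- lapply(rownames(fm$values), function(sid) {
      v <- fm$values[sid, ]
      nonzero <- which(v > 0)
      if (!length(nonzero)) {
        return(scan_set(sid, data.frame(scan = integer(), mode = character(),
                                        mz = numeric(), intensity = numeric()),
                        mz_range = range(fm$bins$mz) + c(-1, 1)))
      }
      jit <- if (centroid_jitter_ppm > 0) {
        stats::runif(length(nonzero) * n_scans, -centroid_jitter_ppm,
                     centroid_jitter_ppm)
      } else numeric(length(nonzero) * n_scans)
      mz0 <- fm$bins$mz[nonzero]
      peaks <- data.frame(
        scan = rep(seq_len(n_scans), each = length(nonzero)),
        mode = rep(fm$bins$mode[nonzero], n_scans),
        mz = rep(mz0, n_scans) * (1 + jit * 1e-6),
        intensity = as.vector(outer(v[nonzero], weights)),
        stringsAsFactors = FALSE
      )
      scan_set(sid, peaks, mz_range = c(min(peaks$mz) - 1, max(peaks$mz) + 1))
    })
    names(out) <- rownames(fm$values)
    out
  })
}

# symmetric triangular infusion profile peaking at the middle scan
triangular_profile <- function(n_scans) {
  if (n_scans < 1) stopf("n_scans must be >= 1")
  if (n_scans == 1) return(1)
  c0 <- (n_scans + 1) / 2
  1 - abs(seq_len(n_scans) - c0) / c0
}
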