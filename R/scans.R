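# ScanSet container and mzML IO. One scan set holds all centroided scans of
# a single flow-infusion acquisition (one sample), both ionisation modes.

#' Construct a scan set
#'
#' @param sample_id Sample identifier.
#' @param peaks data.frame with columns `scan` (integer scan index), `mode`
#'   (`"positive"`/`"negative"`), `mz` and `intensity`. m/z must be sorted
#'   ascending within each (scan, mode) spectrum and intensities
#'   non-negative.
#' @param mz_range Acquisition window; peaks are validated against it.
#' @return Object of class `scan_set`.
#' @export
scan_set <- function(sample_id, peaks, mz_range = c(55, 1200)) {
  need <- c("scan", "mode", "mz", "intensity")
  if (!all(need %in% names(peaks))) {
    stopf("peaks must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(peaks)) {
    if (!all(peaks$mode %in% c("positive", "negative"))) {
      stopf("mode must be 'positive' or 'negative'")
    }
    if (any(peaks$intensity < 0)) stopf("intensities must be non-negative")
    if (any(peaks$mz < mz_range[1] | peaks$mz > mz_range[2])) {
      stopf("peaks outside the acquisition window [%g, %g]",
            mz_range[1], mz_range[2])
    }
    ord <- order(peaks$scan, peaks$mode, peaks$mz)
    peaks <- peaks[ord, , drop = FALSE]
    rownames(peaks) <- NULL
  } else {
    warnf("scan set '%s' contains no peaks", sample_id)
  }
  structure(list(sample_id = sample_id, peaks = peaks, mz_range = mz_range),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("scan_set '%s': %d scans, %d centroids (%s)\n",
              x$sample_id, length(unique(x$peaks$scan)), nrow(x$peaks),
              paste(sprintf("%s=%d", names(table(x$peaks$mode)),
                            table(x$peaks$mode)), collapse = ", ")))
  invisible(x)
}

scan_tic <- function(scans) {
  idx <- sort(unique(scans$peaks$scan))
  tic <- vapply(idx, function(s) {
    sum(scans$peaks$intensity[scans$peaks$scan == s])
  }, numeric(1))
  names(tic) <- idx
  tic
}

#' Read centroided flow-infusion spectra from an mzML file
#'
#' Requires the `mzR` package. Spectra are partitioned by ionisation
#' polarity; profile-mode spectra and spectra with unknown polarity are
#' rejected with an explicit error.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample id to attach; defaults to the file name.
#' @param mz_range Acquisition window used for validation.
#' @return A `scan_set`.
#' @export
read_mzml <- function(path, sample_id = NULL, mz_range = c(55, 1200)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stopf("read_mzml requires the mzR package")
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0) {
    warnf("mzML file '%s' contains no spectra", path)
    return(scan_set(sample_id,
                    data.frame(scan = integer(), mode = character(),
                               mz = numeric(), intensity = numeric()),
                    mz_range))
  }
  if (any(!hdr$centroided, na.rm = TRUE) || anyNA(hdr$centroided)) {
    stopf("'%s' contains profile-mode spectra; centroid the data first", path)
  }
  if (anyNA(hdr$polarity) || any(hdr$polarity < 0)) {
    stopf("'%s' has spectra with missing polarity metadata", path)
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  # scan index counts acquisitions within each polarity separately
  mode <- ifelse(hdr$polarity == 1, "positive", "negative")
  scan_idx <- stats::ave(seq_len(nrow(hdr)), mode, FUN = seq_along)
  parts <- lapply(seq_len(nrow(hdr)), function(i) {
    m <- pk[[i]]
    if (!nrow(m)) return(NULL)
    data.frame(scan = scan_idx[i], mode = mode[i],
               mz = m[, 1], intensity = m[, 2])
  })
  peaks <- do.call(rbind, parts)
  if (is.null(peaks)) {
    peaks <- data.frame(scan = integer(), mode = character(),
                        mz = numeric(), intensity = numeric())
  }
  scan_set(sample_id, peaks, mz_range)
}

#' Write a scan set to an mzML file
#'
#' Requires the `mzR` package. Scans are written in scan order with positive
#' polarity before negative within each scan index, flagged as centroided.
#'
#' @param scans A `scan_set`.
#' @param path Output path (`.mzML`).
#' @export
write_mzml <- function(scans, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stopf("write_mzml requires the mzR package")
  }
  pk <- scans$peaks
  key <- unique(pk[, c("scan", "mode")])
  key <- key[order(key$scan, match(key$mode, c("positive", "negative"))), ,
             drop = FALSE]
  spectra <- vector("list", nrow(key))
  hdr_rows <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    sel <- pk$scan == key$scan[i] & pk$mode == key$mode[i]
    m <- cbind(mz = pk$mz[sel], intensity = pk$intensity[sel])
    m <- m[order(m[, 1]), , drop = FALSE]
    spectra[[i]] <- m
    hdr_rows[[i]] <- data.frame(
      seqNum = i, acquisitionNum = i, msLevel = 1L,
      polarity = if (key$mode[i] == "positive") 1L else 0L,
      peaksCount = nrow(m), totIonCurrent = sum(m[, 2]),
      retentionTime = key$scan[i], basePeakMZ = m[which.max(m[, 2]), 1],
      basePeakIntensity = max(m[, 2]), collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = min(m[, 1]), highMZ = max(m[, 1]),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = "", spectrumId = sprintf("scan=%d", i),
      centroided = TRUE, ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = scans$mz_range[1],
      scanWindowUpperLimit = scans$mz_range[2],
      stringsAsFactors = FALSE
    )
  }
  mzR::writeMSData(spectra, file = path, header = do.call(rbind, hdr_rows))
  invisible(path)
}
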