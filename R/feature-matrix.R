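# FeatureMatrix container: samples x m/z-bin intensities plus bin metadata
# and a processing-stage flag that advances raw -> occupancy_filtered ->
# qc_filtered -> normalised -> log2.

.fm_stages <- c("raw", "occupancy_filtered", "qc_filtered", "normalised", "log2")

#' Construct a feature matrix
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   bins in columns (colnames = bin ids such as `"n341.11"`).
#' @param bins Optional data.frame with columns `bin_id`, `mode`
#'   (`"positive"`/`"negative"`) and `mz` (representative accurate m/z).
#'   Derived from the column names when omitted.
#' @param stage Processing stage flag.
#' @param bin_width Bin width in m/z units used to derive bin centres.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, bins = NULL, stage = "raw", bin_width = 0.01) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must have sample ids as rownames and bin ids as colnames")
  }
  if (anyDuplicated(colnames(values))) stopf("bin ids must be unique")
  if (anyDuplicated(rownames(values))) stopf("sample ids must be unique")
  stage <- match.arg(stage, .fm_stages)
  if (stage != "log2" && any(values < 0)) {
    stopf("negative intensities are not allowed at stage '%s'", stage)
  }
  if (is.null(bins)) bins <- parse_bin_ids(colnames(values), bin_width)
  if (!all(c("bin_id", "mode", "mz") %in% names(bins))) {
    stopf("bins must have columns bin_id, mode, mz")
  }
  if (!identical(bins$bin_id, colnames(values))) {
    stopf("bins$bin_id must match colnames(values) in order")
  }
  structure(
    list(values = values, bins = bins, stage = stage, bin_width = bin_width),
    class = "feature_matrix"
  )
}

# Bin ids encode mode (p/n prefix) and the bin's lower m/z edge at bin-width
# precision; the representative m/z defaults to the bin midpoint.
parse_bin_ids <- function(ids, bin_width = 0.01) {
  mode_chr <- substr(ids, 1, 1)
  if (!all(mode_chr %in% c("p", "n"))) {
    stopf("bin ids must start with 'p' (positive) or 'n' (negative)")
  }
  lo <- suppressWarnings(as.numeric(substring(ids, 2)))
  if (anyNA(lo)) stopf("bin ids must encode a numeric m/z, e.g. 'n341.11'")
  data.frame(
    bin_id = ids,
    mode = ifelse(mode_chr == "p", "positive", "negative"),
    mz = lo + bin_width / 2,
    stringsAsFactors = FALSE
  )
}

bin_id_label <- function(mode, mz_lo, bin_width = 0.01) {
  dp <- max(0L, ceiling(-log10(bin_width)))
  paste0(ifelse(mode == "positive", "p", "n"), sprintf(paste0("%.", dp, "f"), mz_lo))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d bins, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  modes: %s\n",
              paste(sprintf("%s=%d", names(table(x$bins$mode)),
                            table(x$bins$mode)), collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# enforce legal stage transitions; filters may re-enter their own stage
check_stage <- function(fm, allowed, op) {
  if (!inherits(fm, "feature_matrix")) stopf("%s expects a feature_matrix", op)
  if (!fm$stage %in% allowed) {
    stopf("%s requires stage %s, got '%s'", op,
          paste(sQuote(allowed), collapse = " or "), fm$stage)
  }
  invisible(fm)
}

subset_bins <- function(fm, keep, stage = fm$stage) {
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$bins <- fm$bins[match(colnames(fm$values), fm$bins$bin_id), , drop = FALSE]
  rownames(fm$bins) <- NULL
  fm$stage <- stage
  fm
}

#' Write / read a feature matrix as delimited text
#'
#' The matrix is written samples x bins with an extra leading `sample_id`
#' column; bin metadata (mode and representative m/z) and the stage flag are
#' stored in commented header lines so a round trip is lossless.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", fm$stage), con)
  writeLines(sprintf("# bin_width: %.12g", fm$bin_width), con)
  writeLines(sprintf("# mz: %s", paste(sprintf("%.9f", fm$bins$mz), collapse = ",")), con)
  df <- data.frame(sample_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- readLines(path, n = 3L)
  stage <- sub("^# stage: ", "", hdr[1])
  bin_width <- as.numeric(sub("^# bin_width: ", "", hdr[2]))
  mz <- as.numeric(strsplit(sub("^# mz: ", "", hdr[3]), ",")[[1]])
  df <- utils::read.table(path, sep = ",", header = TRUE, skip = 3L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample_id
  bins <- parse_bin_ids(colnames(vals), bin_width)
  if (length(mz) == nrow(bins)) bins$mz <- mz
  feature_matrix(vals, bins = bins, stage = stage, bin_width = bin_width)
}

#' Write / read a sample metadata table
#'
#' @param samples A data.frame with at least `sample_id` and `role` columns.
#' @param path File path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, sep = ",", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}
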