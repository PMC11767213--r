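test_that("infusion window is the contiguous plateau above the TIC fraction", {
  tri <- 1 - abs(1:9 - 5) / 5          # triangular profile peaking at scan 5
  expect_equal(select_infusion_scans(tri, 0.5), c(3, 7))
  expect_equal(select_infusion_scans(42), c(1, 1))         # single scan
  expect_equal(select_infusion_scans(rep(7, 6), 0.5), c(1, 6))  # flat profile
  expect_error(select_infusion_scans(c(0, 0, 0)), "zero")
})

test_that("binning sums within half-open bins and averages over scans", {
  # two centroids in the same 0.01 bin
  s <- peaks_scan_set(scan = c(1, 1), mode = "positive",
                      mz = c(100.004, 100.006), intensity = c(10, 5))
  r <- bin_scans(s, window = c(1, 1))
  expect_equal(unname(r$intensity), 15)
  expect_equal(r$bins$bin_id, "p100.00")
  # boundary centroid falls into the upper bin (half-open convention)
  s2 <- peaks_scan_set(1, "positive", 100.010, 7)
  r2 <- bin_scans(s2, window = c(1, 1))
  expect_equal(r2$bins$bin_id, "p100.01")
  # mean across the scans in the window
  s3 <- peaks_scan_set(c(1, 2), "negative", c(200.003, 200.004), c(10, 20))
  r3 <- bin_scans(s3, window = c(1, 2))
  expect_equal(unname(r3$intensity), 15)
  # out-of-range centroids are excluded and counted
  s4 <- peaks_scan_set(c(1, 1), "positive", c(100.004, 30), c(5, 9),
                       mz_range = c(20, 1200))
  r4 <- bin_scans(s4, window = c(1, 1), mz_range = c(55, 1200))
  expect_equal(r4$n_excluded, 1L)
  expect_equal(unname(r4$intensity), 5)
})

test_that("per-scan binned intensity conserves in-range centroid intensity", {
  set.seed(31)
  for (rep in 1:5) {
    mz <- runif(60, 55, 1200)
    s <- peaks_scan_set(rep(1, 60), sample(c("positive", "negative"), 60, TRUE),
                        mz, rgamma(60, 2))
    r <- bin_scans(s, window = c(1, 1))
    expect_equal(sum(r$intensity), sum(s$peaks$intensity), tolerance = 1e-12)
  }
})

test_that("occupancy filter keeps bins reaching the threshold in any class", {
  vals <- rbind(
    A1 = c(1, 1, 0), A2 = c(2, 1, 0), A3 = c(3, 0, 0), A4 = c(0, 0, 0),
    B1 = c(0, 1, 0), B2 = c(0, 0, 0), B3 = c(0, 1, 0), B4 = c(0, 0, 0)
  )
  colnames(vals) <- c("p100.00", "p100.01", "p100.02")
  fm <- feature_matrix(vals)
  samples <- data.frame(sample_id = rownames(vals), role = "sample",
                        class = rep(c("A", "B"), each = 4))
  out <- suppressMessages(occupancy_filter(fm, samples, "class", 2 / 3))
  # bin 1: 3/4 in A -> kept; bin 2: 1/2 in every class -> dropped;
  # bin 3: all zero -> dropped
  expect_equal(colnames(out$values), "p100.00")
  expect_equal(out$stage, "occupancy_filtered")
  # idempotent
  out2 <- suppressMessages(occupancy_filter(out, samples, "class", 2 / 3))
  expect_equal(out2$values, out$values)
})

test_that("QC RSD filter applies the inclusive sd/mean rule", {
  vals <- rbind(
    S1 = c(5, 4, 1), S2 = c(6, 5, 2),
    QC1 = c(10, 5, 0), QC2 = c(10, 10, 0), QC3 = c(10, 15, 0)
  )
  colnames(vals) <- c("n200.00", "n200.01", "n200.02")
  fm <- feature_matrix(vals, stage = "occupancy_filtered")
  samples <- data.frame(sample_id = rownames(vals),
                        role = c("sample", "sample", "QC", "QC", "QC"),
                        class = c("A", "A", "QC", "QC", "QC"))
  out <- suppressMessages(qc_rsd_filter(fm, samples, max_rsd = 0.5))
  # (10,10,10): RSD 0 kept; (5,10,15): RSD exactly 0.5 kept (inclusive);
  # (0,0,0): zero mean dropped
  expect_setequal(colnames(out$values), c("n200.00", "n200.01"))
  expect_error(
    qc_rsd_filter(feature_matrix(vals[1:3, ], stage = "occupancy_filtered"),
                  samples[1:3, ]),
    "at least 2 QC"
  )
})

test_that("TIC normalisation equalises row sums at the median", {
  vals <- rbind(S1 = c(40, 60), S2 = c(100, 200))
  colnames(vals) <- c("p100.00", "p100.01")
  fm <- feature_matrix(vals, stage = "qc_filtered")
  out <- normalise_tic(fm)
  expect_equal(unname(rowSums(out$values)), rep(200, 2), tolerance = 1e-12)
  # two samples with sums 100 and 300 -> factors 2 and 2/3
  expect_equal(unname(out$values["S1", ]), c(80, 120))
  expect_equal(unname(out$values["S2", ]), c(100, 200) * 2 / 3)
  # single sample is its own median
  one <- normalise_tic(feature_matrix(vals[1, , drop = FALSE],
                                      stage = "qc_filtered"))
  expect_equal(one$values, vals[1, , drop = FALSE])
  vals0 <- rbind(S1 = c(0, 0)); colnames(vals0) <- colnames(vals)
  expect_error(normalise_tic(feature_matrix(vals0, stage = "qc_filtered")),
               "S1")
})

test_that("log2 transform uses global half-minimum imputation", {
  vals <- rbind(S1 = c(8, 0), S2 = c(2, 4))
  colnames(vals) <- c("p100.00", "p100.01")
  out <- log2_transform(feature_matrix(vals, stage = "normalised"))
  expect_equal(out$values["S1", "p100.00"], 3)
  # zero -> half of the smallest non-zero (2) -> log2(1) = 0
  expect_equal(out$values["S1", "p100.01"], 0)
  expect_equal(out$stage, "log2")
})

test_that("stage ordering is enforced", {
  vals <- rbind(S1 = c(1, 2), S2 = c(3, 4))
  colnames(vals) <- c("p100.00", "p100.01")
  fm <- feature_matrix(vals, stage = "raw")
  samples <- data.frame(sample_id = rownames(vals), role = "sample",
                        class = "A")
  expect_error(normalise_tic(fm), "requires stage")
  expect_error(log2_transform(fm), "requires stage")
  expect_error(qc_rsd_filter(fm, samples), "requires stage")
})

test_that("sample order is irrelevant to the filter chain", {
  spec <- synthetic_spec(n_per_class = 6, n_features = 60, zero_rate = 0.3,
                         qc_n = 4, seed = 21)
  ds <- generate_feature_matrix(spec)
  run_chain <- function(fm) {
    fm <- occupancy_filter(fm, ds$samples, "class")
    fm <- qc_rsd_filter(fm, ds$samples)
    log2_transform(normalise_tic(fm))
  }
  a <- suppressMessages(run_chain(ds$matrix))
  perm <- sample(nrow(ds$matrix$values))
  fm_p <- feature_matrix(ds$matrix$values[perm, ], bins = ds$matrix$bins,
                         stage = "raw")
  b <- suppressMessages(run_chain(fm_p))
  expect_equal(b$values[rownames(a$values), ], a$values)
})

test_that("mzML files round-trip scan sets through mzR", {
  spec <- synthetic_spec(n_per_class = 2, n_features = 30, qc_n = 0, seed = 2)
  ds <- generate_feature_matrix(spec)
  scans <- matrix_to_scans(ds$matrix, n_scans = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(scans[[1]], f)
  back <- read_mzml(f, sample_id = scans[[1]]$sample_id)
  expect_equal(back$peaks$mz, scans[[1]]$peaks$mz)
  expect_equal(back$peaks$intensity, scans[[1]]$peaks$intensity)
  expect_equal(table(back$peaks$mode), table(scans[[1]]$peaks$mode))
  # binning the re-read scans matches binning the in-memory scans
  r1 <- bin_scans(scans[[1]], mz_range = c(50, 1210))
  r2 <- bin_scans(back, mz_range = c(50, 1210))
  expect_equal(r2$intensity, r1$intensity, tolerance = 1e-12)
})
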