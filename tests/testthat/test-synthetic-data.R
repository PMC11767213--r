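test_that("metadata reflects the sampling design and is seed-deterministic", {
  spec <- synthetic_spec(classes = c("g3", "g4"), n_per_class = 24, qc_n = 5)
  md <- generate_metadata(spec)
  expect_equal(nrow(md), 53)
  expect_equal(sum(md$role == "sample"), 48)
  expect_setequal(unique(md$hour[md$role == "sample"]), c(0, 3, 9, 15))
  expect_setequal(md$run_order, seq_len(53))
  expect_identical(md, generate_metadata(spec))
})

test_that("spec validation errors name the offending field", {
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(zero_rate = 1), "zero_rate")
  expect_error(synthetic_spec(effect_size = -1), "effect_size")
  expect_error(synthetic_spec(hours = c(0, 3, 3, 15)), "hours")
  expect_error(
    synthetic_spec(n_features = 5, n_discriminating = 10),
    "n_features"
  )
  expect_error(
    synthetic_spec(trend_archetypes = list(a = c(0, 1)),
                   n_trend_features_per_archetype = 2),
    "archetype length"
  )
})

test_that("planted trend archetypes are visible in per-timepoint medians", {
  spec <- synthetic_spec(
    classes = "sinass", n_per_class = 40, n_features = 50,
    n_discriminating = 0, noise_sd = 0.15,
    trend_archetypes = list(rise_fall = c(0, 1, 2, 1)),
    n_trend_features_per_archetype = 8, qc_n = 0, seed = 4
  )
  ds <- generate_feature_matrix(spec)
  bio <- ds$samples[ds$samples$role == "sample", ]
  lg <- log2(as.matrix(ds$matrix)[bio$sample_id, ])
  for (b in ds$truth$trend_bins$bin_id) {
    med <- tapply(lg[, b], bio$timepoint, stats::median)[spec$timepoints]
    prof <- as.numeric(med - med[1])
    expect_equal(prof, c(0, 1, 2, 1), tolerance = 0.35)
  }
})

test_that("pooled-QC rows reproduce the requested relative dispersion", {
  spec <- synthetic_spec(n_per_class = 10, n_features = 400, qc_n = 40,
                         qc_rsd = 0.05, seed = 9)
  ds <- generate_feature_matrix(spec)
  qc <- as.matrix(ds$matrix)[ds$samples$sample_id[ds$samples$role == "QC"], ]
  rsd <- apply(qc, 2, stats::sd) / colMeans(qc)
  expect_equal(mean(rsd), 0.05, tolerance = 0.01)
})

test_that("generators are pure functions of spec and seed", {
  spec <- synthetic_spec(n_per_class = 6, n_features = 40, zero_rate = 0.2,
                         seed = 12)
  a <- generate_feature_matrix(spec)
  b <- generate_feature_matrix(spec)
  expect_identical(a, b)
  ref1 <- generate_reference(25, 3, 5, seed = 8)
  ref2 <- generate_reference(25, 3, 5, seed = 8)
  expect_identical(ref1, ref2)
})

test_that("zero injection only affects the lowest-intensity quartile", {
  spec <- synthetic_spec(n_per_class = 10, n_features = 200, zero_rate = 0.5,
                         qc_n = 0, seed = 3)
  ds <- generate_feature_matrix(spec)
  v <- as.matrix(ds$matrix)
  expect_gt(sum(v == 0), 0)
  spec0 <- synthetic_spec(n_per_class = 10, n_features = 200, zero_rate = 0,
                          qc_n = 0, seed = 3)
  v0 <- as.matrix(generate_feature_matrix(spec0)$matrix)
  zeroed <- v == 0 & v0 > 0
  expect_true(all(v0[zeroed] < stats::quantile(v0, 0.25)))
})

test_that("scan expansion conserves TIC under the 'tic' profile scaling", {
  spec <- synthetic_spec(n_per_class = 2, n_features = 30, qc_n = 0, seed = 2)
  ds <- generate_feature_matrix(spec)
  scans <- matrix_to_scans(ds$matrix, n_scans = 10, seed = 5, scale = "tic")
  for (sid in names(scans)) {
    expect_equal(sum(scans[[sid]]$peaks$intensity),
                 sum(as.matrix(ds$matrix)[sid, ]), tolerance = 1e-12)
  }
})

test_that("scan expansion refuses jitter that breaks bin identifiability", {
  spec <- synthetic_spec(n_per_class = 2, n_features = 20, qc_n = 0, seed = 2)
  ds <- generate_feature_matrix(spec)
  # at m/z 1200 and 0.01 Da bins, half a bin width is ~4.2 ppm
  expect_error(matrix_to_scans(ds$matrix, centroid_jitter_ppm = 10),
               "half a bin width")
  # 2 ppm at m/z <= 1200 stays inside the bin: 2e-6 * 1200 < 0.005
  scans <- matrix_to_scans(ds$matrix, centroid_jitter_ppm = 2, n_scans = 3,
                           seed = 1)
  pk <- scans[[1]]$peaks
  k_lo <- floor(pk$mz / 0.01 + 1e-6) * 0.01
  truth_k <- floor((ds$matrix$bins$mz) / 0.01 + 1e-9) * 0.01
  expect_true(all(round(k_lo, 2) %in% round(truth_k, 2)))
})

test_that("toy reference compounds carry exact masses and reachable pathways", {
  ref <- generate_reference(n_compounds = 30, n_pathways = 3,
                            taxonomy_depth = 5, seed = 5)
  calc <- vapply(ref$compounds$formula, monoisotopic_mass, numeric(1))
  expect_equal(unname(calc), ref$compounds$mass, tolerance = 1e-10)
  expect_false(anyDuplicated(ref$compounds$formula) > 0)
  expect_true(all(lengths(strsplit(ref$compounds$lineage, "|", fixed = TRUE)) == 5))
  g <- suppressMessages(build_knowledge_graph(ref$compounds, ref$edges))
  pw <- igraph::V(g)$name[igraph::V(g)$type == "pathway"]
  expect_length(pw, 3)
  cmp <- igraph::V(g)$name[igraph::V(g)$type == "compound"]
  d <- igraph::distances(g, v = pw, to = cmp)
  expect_true(all(apply(d, 1, min) < Inf))
})

test_that("reference files round-trip through delimited text", {
  ref <- generate_reference(15, 2, 4, seed = 6)
  dir <- withr::local_tempdir()
  write_reference(ref, dir)
  back <- read_reference(dir)
  expect_equal(back$compounds, ref$compounds, tolerance = 1e-9)
  expect_equal(back$edges, ref$edges)
})
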