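# End-to-end orchestration: configuration defaults, input validation, and
# a deterministic multi-stage run (bin/filter/normalise -> annotate ->
# classify -> regress -> trends -> enrich) writing delimited outputs and a
# JSON manifest. Per-stage seeds are derived from a single master seed so
# stages are independently reproducible.

#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; any subset
#' can be overridden via `run_pipeline(config = list(...))` or a YAML file.
#' Unknown keys are rejected.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    bin_width = 0.01,          # m/z units
    mz_min = 55, mz_max = 1200,
    tic_fraction = 0.5,        # infusion scan-window rule
    occupancy = 2 / 3,         # within-best-class occupancy threshold
    qc_rsd = 0.5,              # max pooled-QC RSD
    ppm = 3,                   # annotation tolerance
    consensus = 0.66,          # taxonomy consensus threshold
    n_trees = 1000,
    n_perm = 3000,             # permutation-test draws
    n_perm_importance = 1000,  # importance-null refits for feature selection
    alpha = 0.05,
    k = 5,                     # trend clusters
    n_restarts = 10,
    damping = 0.85,
    n_null = 1000,             # PageRank null draws
    class_key = "class",
    baseline_timepoint = "09:00",
    seed = 1
  )
}

merge_config <- function(config) {
  base <- default_config()
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(base, config)
}

#' Validate a feature matrix against its sample metadata
#'
#' Checks id agreement, role values, intensity signs and the stage flag.
#' Issues are returned as data, not raised as errors.
#'
#' @param fm A [feature_matrix()].
#' @param samples Sample metadata table.
#' @return data.frame with columns `issue`, `detail`; zero rows when clean.
#' @export
validate_inputs <- function(fm, samples) {
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1]] <<- data.frame(
      issue = issue, detail = detail, stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(samples$sample_id)) {
    add("duplicate sample id",
        paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
              collapse = ", "))
  }
  unmatched <- setdiff(rownames(fm$values), samples$sample_id)
  for (s in unmatched) add("unmatched sample", s)
  bad_role <- setdiff(unique(samples$role), c("sample", "QC", "blank"))
  for (r in bad_role) add("invalid role", r)
  if (fm$stage != "log2") {
    neg <- which(fm$values < 0, arr.ind = TRUE)
    for (i in seq_len(min(nrow(neg), 10))) {
      add("negative intensity",
          sprintf("%s / %s", rownames(fm$values)[neg[i, 1]],
                  colnames(fm$values)[neg[i, 2]]))
    }
  }
  if (!fm$stage %in% .fm_stages) add("invalid stage flag", fm$stage)
  if (length(issues)) do.call(rbind, issues) else
    data.frame(issue = character(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Run the full fingerprint analysis pipeline
#'
#' Executes the requested stages on a raw feature matrix (or scan sets) and
#' writes every stage's output as delimited text plus a JSON manifest into
#' `out_dir`. Re-running with an identical config and inputs reproduces
#' identical outputs. On stage failure, outputs produced so far are kept
#' and a `FAILED` marker file records the stage and message.
#'
#' @param matrix Raw-stage [feature_matrix()], or a named list of
#'   [scan_set()] objects to be binned first.
#' @param samples Sample metadata table.
#' @param out_dir Output directory (created if needed).
#' @param config Partial configuration list or path to a YAML file; see
#'   [default_config()].
#' @param reference Optional compound reference (as from
#'   [generate_reference()]) enabling annotation and enrichment.
#' @param stages Stages to run, a subset of
#'   `c("bin", "annotate", "classify", "regress", "trends", "enrich")`.
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(matrix, samples, out_dir, config = list(),
                         reference = NULL,
                         stages = c("bin", "annotate", "classify", "regress",
                                    "trends", "enrich")) {
  cfg <- merge_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("leafprint")),
    config = cfg, stages = stages, counts = list()
  )
  results <- list()
  current <- NULL
  fail <- function(stage, e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }

  if (inherits(matrix, "feature_matrix")) {
    current <- matrix
  } else if ("bin" %in% stages) {
    current <- tryCatch(
      bin_samples(matrix, bin_width = cfg$bin_width,
                  mz_range = c(cfg$mz_min, cfg$mz_max),
                  tic_fraction = cfg$tic_fraction),
      error = function(e) fail("bin", e)
    )
  } else {
    stopf("matrix must be a feature_matrix or scan sets with stage 'bin'")
  }

  issues <- validate_inputs(current, samples)
  if (nrow(issues)) {
    utils::write.table(issues, file.path(out_dir, "issues.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    stopf("input validation failed: %s",
          paste(unique(issues$issue), collapse = "; "))
  }

  # filtering / normalisation chain
  if ("bin" %in% stages) {
    current <- tryCatch({
      fm <- occupancy_filter(current, samples, cfg$class_key, cfg$occupancy)
      fm <- qc_rsd_filter(fm, samples, cfg$qc_rsd)
      fm <- normalise_tic(fm)
      log2_transform(fm)
    }, error = function(e) fail("bin", e))
    write_feature_matrix(current, file.path(out_dir, "matrix_log2.csv"))
    manifest$counts$bins <- ncol(current$values)
    manifest$counts$samples <- nrow(current$values)
  } else if (current$stage != "log2") {
    stopf("matrix must be at stage 'log2' when the bin stage is skipped")
  }
  results$matrix <- current

  records <- NULL
  if ("annotate" %in% stages && !is.null(reference)) {
    records <- tryCatch(
      annotate_features(current, reference$compounds,
                        rules = reference$rules %||% adduct_rules(),
                        tolerance_ppm = cfg$ppm,
                        consensus_threshold = cfg$consensus),
      error = function(e) fail("annotate", e)
    )
    ann <- annotation_table(records)
    utils::write.table(ann, file.path(out_dir, "annotations.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(composition_summary(records),
                       file.path(out_dir, "composition.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    manifest$counts$annotated <- sum(vapply(records, function(r)
      nrow(r$candidates) > 0, logical(1)))
    results$annotations <- records
  }

  bio <- samples[samples$role == "sample", , drop = FALSE]
  x <- current$values[bio$sample_id, , drop = FALSE]

  if ("classify" %in% stages) {
    results$classification <- tryCatch({
      y <- bio[[cfg$class_key]]
      fit <- fit_rf_classifier(x, y, n_trees = cfg$n_trees,
                               seed = derive_seed(cfg$seed, "classify"))
      pt <- permutation_test(x, y, "margin", n_perm = cfg$n_perm,
                             n_trees = cfg$n_trees,
                             seed = derive_seed(cfg$seed, "classify_perm"))
      d <- proximity_to_distance(fit$proximity)
      mds <- classical_mds(d, dims = 2)
      intra <- intraclass_distance_summary(d, y)
      utils::write.table(
        data.frame(sample_id = rownames(mds$points), dim1 = mds$points[, 1],
                   dim2 = mds$points[, 2], class = y),
        file.path(out_dir, "mds.csv"), sep = ",", row.names = FALSE,
        quote = FALSE)
      utils::write.table(intra$summary,
                         file.path(out_dir, "intraclass_distances.csv"),
                         sep = ",", row.names = FALSE, quote = FALSE)
      list(fit = fit, permutation = pt, mds = mds, intraclass = intra)
    }, error = function(e) fail("classify", e))
    manifest$counts$margin <- results$classification$fit$margin
    manifest$counts$margin_p <- results$classification$permutation$p
  }

  reg <- NULL
  if ("regress" %in% stages) {
    results$regression <- reg <- tryCatch({
      fit_rf_regressor(x, bio$hour, n_trees = cfg$n_trees,
                       seed = derive_seed(cfg$seed, "regress"),
                       n_perm_importance = cfg$n_perm_importance,
                       alpha = cfg$alpha)
    }, error = function(e) fail("regress", e))
    utils::write.table(
      data.frame(bin_id = names(reg$importance), inc_mse = reg$importance,
                 p_value = reg$importance_p %||% NA_real_,
                 explanatory = names(reg$importance) %in% reg$explanatory),
      file.path(out_dir, "importances.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
    manifest$counts$r_squared <- reg$r_squared
    manifest$counts$n_explanatory <- length(reg$explanatory)
  }

  clusters <- NULL
  if ("trends" %in% stages) {
    results$trends <- tryCatch({
      feats <- if (!is.null(reg) && length(reg$explanatory)) reg$explanatory
               else colnames(x)
      prof <- log2_ratio_profiles(current, samples, feats,
                                  baseline = cfg$baseline_timepoint)
      km <- kmeans_trends(prof, k = min(cfg$k, nrow(prof)),
                          n_restarts = cfg$n_restarts,
                          seed = derive_seed(cfg$seed, "trends"))
      utils::write.table(
        data.frame(bin_id = names(km$cluster), cluster = km$cluster),
        file.path(out_dir, "clusters.csv"), sep = ",", row.names = FALSE,
        quote = FALSE)
      utils::write.table(
        data.frame(cluster = seq_len(nrow(km$centroids)), km$centroids,
                   check.names = FALSE),
        file.path(out_dir, "centroids.csv"), sep = ",", row.names = FALSE,
        quote = FALSE)
      km
    }, error = function(e) fail("trends", e))
    clusters <- results$trends$cluster
    manifest$counts$clusters <- length(unique(clusters))
  }

  if ("enrich" %in% stages && !is.null(clusters) && !is.null(records)) {
    results$enrichment <- tryCatch({
      ann_terms <- do.call(rbind, lapply(records[names(clusters)], function(r) {
        if (!length(r$lineage)) return(NULL)
        data.frame(feature_id = r$bin_id, term = r$lineage,
                   stringsAsFactors = FALSE)
      }))
      graph <- build_knowledge_graph(reference$compounds, reference$edges)
      feat_cmp <- do.call(rbind, lapply(records[names(clusters)], function(r) {
        ids <- unique(unlist(strsplit(r$candidates$compound_ids, ";")))
        if (!length(ids)) return(NULL)
        data.frame(feature_id = r$bin_id, compound_id = ids,
                   stringsAsFactors = FALSE)
      }))
      enr <- cluster_enrichment(clusters, ann_terms %||% data.frame(
        feature_id = character(), term = character()),
        feature_compounds = feat_cmp, graph = graph,
        n_null = cfg$n_null, damping = cfg$damping,
        seed = derive_seed(cfg$seed, "enrich"))
      if (!is.null(enr$structural)) {
        utils::write.table(enr$structural,
                           file.path(out_dir, "enrichment_structural.csv"),
                           sep = ",", row.names = FALSE, quote = FALSE)
      }
      if (!is.null(enr$functional)) {
        utils::write.table(enr$functional,
                           file.path(out_dir, "enrichment_functional.csv"),
                           sep = ",", row.names = FALSE, quote = FALSE)
      }
      enr
    }, error = function(e) fail("enrich", e))
  }

  manifest$counts <- manifest$counts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
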