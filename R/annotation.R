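# Accurate-mass annotation: match bin m/z against theoretical adduct ions
# of a formula database (primary source first, fallback only when the
# primary yields nothing), then derive a consensus chemical-taxonomy
# lineage over all matched compounds.

#' Assign candidate molecular formulas to an observed m/z
#'
#' Every (formula, adduct rule) pair whose theoretical m/z lies within
#' `tolerance_ppm` of the observed m/z becomes a candidate, subject to the
#' rule's polarity matching the bin's ionisation mode and its applicability
#' predicate holding for the formula. Compounds with `source == "primary"`
#' are searched first; `"fallback"` compounds are consulted only when the
#' primary source yields no candidate.
#'
#' @param mz Observed m/z (the bin's representative accurate mass).
#' @param mode Ionisation mode, `"positive"` or `"negative"`.
#' @param db Formula database data.frame (see [generate_reference()]):
#'   columns `compound_id`, `formula`, `mass`, `source`, `lineage`,
#'   optionally `pathway_ids`.
#' @param rules Adduct rule table, default [adduct_rules()].
#' @param tolerance_ppm Mass tolerance in ppm.
#' @param bin_id Optional bin identifier carried into the record.
#' @return An `annotation_record`: list with `bin_id`, `mz`, `mode`,
#'   `candidates` (data.frame: `formula`, `adduct`, `theoretical_mz`,
#'   `ppm_error`, `compound_ids`, `source`) and consensus fields (filled by
#'   [consensus_classification()] via [annotate_features()]).
#' @export
assign_formulas <- function(mz, mode, db, rules = adduct_rules(),
                            tolerance_ppm = 3, bin_id = NULL) {
  if (is.null(db) || !nrow(db)) stopf("formula database is empty")
  mode <- match.arg(mode, c("positive", "negative"))
  if (tolerance_ppm <= 0) stopf("tolerance_ppm must be positive")
  rules <- rules[rules$polarity == mode, , drop = FALSE]
  if (!nrow(rules)) stopf("no adduct rules for mode '%s'", mode)

  search <- function(dbs) {
    hits <- list()
    # one mass per distinct formula; compounds sharing it are grouped
    forms <- unique(dbs[, c("formula", "mass")])
    h_counts <- formula_h_counts(forms$formula)
    for (r in seq_len(nrow(rules))) {
      rule <- rules[r, ]
      ok <- h_counts >= rule$min_h
      if (!any(ok)) next
      theo <- (rule$n * forms$mass[ok] + rule$shift) / rule$z
      err <- ppm_error(mz, theo)
      within <- abs(err) <= tolerance_ppm
      if (!any(within)) next
      sel <- which(ok)[within]
      hits[[length(hits) + 1]] <- data.frame(
        formula = forms$formula[sel],
        adduct = rule$name,
        theoretical_mz = theo[within],
        ppm_error = err[within],
        compound_ids = vapply(forms$formula[sel], function(f) {
          paste(dbs$compound_id[dbs$formula == f], collapse = ";")
        }, character(1)),
        source = dbs$source[match(forms$formula[sel], dbs$formula)],
        stringsAsFactors = FALSE
      )
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }

  primary <- db[db$source == "primary", , drop = FALSE]
  fallback <- db[db$source != "primary", , drop = FALSE]
  cand <- if (nrow(primary)) search(primary) else NULL
  if (is.null(cand) && nrow(fallback)) cand <- search(fallback)
  if (is.null(cand)) {
    cand <- data.frame(formula = character(), adduct = character(),
                       theoretical_mz = numeric(), ppm_error = numeric(),
                       compound_ids = character(), source = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(cand) <- NULL
  structure(
    list(bin_id = bin_id, mz = mz, mode = mode, candidates = cand,
         lineage = character(0), depth = 0L, fractions = numeric(0),
         classified = FALSE),
    class = "annotation_record"
  )
}

#' Consensus chemical-taxonomy classification
#'
#' Walks the taxonomy from the most general level downward. At each level
#' the modal term is computed among the compounds still consistent with the
#' accepted lineage prefix; the level is accepted iff the modal term's
#' frequency reaches `threshold`. The walk stops at the first failure, and
#' a tie for the modal term stops at the previous level (conservative,
#' deterministic).
#'
#' @param lineages List of character vectors (one ordered lineage per
#'   matched compound, most general term first) or a character vector of
#'   `|`-joined lineage paths.
#' @param threshold Required consensus fraction.
#' @return List with `lineage` (accepted terms), `depth` and `fractions`
#'   (per accepted level).
#' @export
consensus_classification <- function(lineages, threshold = 0.66) {
  if (is.character(lineages)) lineages <- strsplit(lineages, "|", fixed = TRUE)
  lineages <- lineages[lengths(lineages) > 0]
  if (!length(lineages)) {
    return(list(lineage = character(0), depth = 0L, fractions = numeric(0)))
  }
  accepted <- character(0)
  fractions <- numeric(0)
  active <- seq_along(lineages)
  level <- 1L
  repeat {
    terms <- vapply(active, function(i) {
      lin <- lineages[[i]]
      if (length(lin) >= level) lin[level] else NA_character_
    }, character(1))
    terms <- terms[!is.na(terms)]
    if (!length(terms)) break
    tab <- sort(table(terms), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) break  # modal tie: stop
    frac <- tab[1] / length(active)
    if (frac < threshold) break
    modal <- names(tab)[1]
    accepted <- c(accepted, modal)
    fractions <- c(fractions, as.numeric(frac))
    active <- active[vapply(active, function(i) {
      lin <- lineages[[i]]
      length(lin) >= level && lin[level] == modal
    }, logical(1))]
    level <- level + 1L
  }
  list(lineage = accepted, depth = length(accepted), fractions = fractions)
}

# hydrogen counts per formula, memoised across calls within a session
formula_h_counts <- local({
  cache <- new.env(parent = emptyenv())
  function(formulas) {
    vapply(formulas, function(f) {
      got <- cache[[f]]
      if (is.null(got)) {
        cts <- parse_formula(f)
        got <- if ("H" %in% names(cts)) cts[["H"]] else 0L
        cache[[f]] <- got
      }
      got
    }, integer(1))
  }
})

# distinct compounds matched by a record, with their lineages
record_compound_lineages <- function(record, db) {
  ids <- unique(unlist(strsplit(record$candidates$compound_ids, ";")))
  if (!length(ids)) return(list())
  strsplit(db$lineage[match(ids, db$compound_id)], "|", fixed = TRUE)
}

#' Annotate all bins of a feature matrix
#'
#' Runs [assign_formulas()] on every bin's representative m/z and attaches
#' the consensus classification over all distinct matched compounds.
#'
#' @param fm A [feature_matrix()] (any stage) or a bins data.frame
#'   (`bin_id`, `mode`, `mz`).
#' @param db Formula database.
#' @param rules Adduct rules.
#' @param tolerance_ppm Mass tolerance in ppm.
#' @param consensus_threshold Consensus fraction for the taxonomy walk.
#' @return List of `annotation_record`s, one per bin, named by bin id.
#' @export
annotate_features <- function(fm, db, rules = adduct_rules(),
                              tolerance_ppm = 3, consensus_threshold = 0.66) {
  bins <- if (inherits(fm, "feature_matrix")) fm$bins else fm
  records <- lapply(seq_len(nrow(bins)), function(i) {
    rec <- assign_formulas(bins$mz[i], bins$mode[i], db, rules,
                           tolerance_ppm, bin_id = bins$bin_id[i])
    cons <- consensus_classification(record_compound_lineages(rec, db),
                                     consensus_threshold)
    rec$lineage <- cons$lineage
    rec$depth <- cons$depth
    rec$fractions <- cons$fractions
    rec$classified <- cons$depth > 0
    rec
  })
  names(records) <- bins$bin_id
  records
}

#' Annotation records as a flat table
#'
#' @param records List of `annotation_record`s from [annotate_features()].
#' @return data.frame with one row per bin: `bin_id`, `mz`, `mode`,
#'   `n_candidates`, `top_formula`, `top_adduct`, `consensus_lineage`
#'   (`|`-joined), `consensus_depth`.
#' @export
annotation_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      bin_id = r$bin_id %||% NA_character_, mz = r$mz, mode = r$mode,
      n_candidates = nrow(r$candidates),
      top_formula = if (nrow(r$candidates)) r$candidates$formula[1] else NA_character_,
      top_adduct = if (nrow(r$candidates)) r$candidates$adduct[1] else NA_character_,
      consensus_lineage = paste(r$lineage, collapse = "|"),
      consensus_depth = r$depth,
      stringsAsFactors = FALSE
    )
  }))
}

#' Structural composition summary
#'
#' Counts, per taxonomy term at each level, the number of bins whose
#' consensus lineage contains that term; bins with no consensus are counted
#' under an explicit `"unclassified"` bucket at level 1.
#'
#' @param records List of `annotation_record`s.
#' @return data.frame with columns `level`, `term`, `count`.
#' @export
composition_summary <- function(records) {
  rows <- list()
  n_unclassified <- 0L
  for (r in records) {
    if (!length(r$lineage)) {
      n_unclassified <- n_unclassified + 1L
      next
    }
    for (l in seq_along(r$lineage)) {
      key <- paste0(l, "\r", r$lineage[l])
      rows[[key]] <- (rows[[key]] %||% 0L) + 1L
    }
  }
  out <- data.frame(
    level = as.integer(sub("\r.*$", "", names(rows))),
    term = sub("^[0-9]+\r", "", names(rows)),
    count = unlist(rows, use.names = FALSE) %||% integer(0),
    stringsAsFactors = FALSE
  )
  if (n_unclassified > 0) {
    out <- rbind(out, data.frame(level = 1L, term = "unclassified",
                                 count = n_unclassified,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$level, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
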