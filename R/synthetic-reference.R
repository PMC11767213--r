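# Toy compound/taxonomy/pathway reference: a local stand-in for the
# compound-database and chemical-taxonomy lookups the annotation and
# enrichment stages need. Formulas are random CHNO(S,P) compositions with
# exact monoisotopic masses from the package's atomic-mass table; lineages
# are paths through a random taxonomy tree; pathway membership goes through
# intermediate reaction nodes (compound - reaction - pathway).

#' Generate a toy compound reference and knowledge graph
#'
#' @param n_compounds Number of compounds (distinct molecular formulas).
#' @param n_pathways Number of pathway nodes.
#' @param taxonomy_depth Depth of the taxonomy lineages (levels below the
#'   root kingdom term included; total lineage length = `taxonomy_depth`).
#' @param seed RNG seed.
#' @param source Source label(s) recycled over compounds (`"primary"` /
#'   `"fallback"`).
#' @return List with `compounds` (data.frame: `compound_id`, `formula`,
#'   `mass`, `source`, `lineage` as a `|`-joined path, `pathway_ids` as a
#'   `;`-joined list), `taxonomy` (data.frame of per-level terms), `edges`
#'   (data.frame `from`, `to`, `type`) and `rules` ([adduct_rules()]).
#' @export
generate_reference <- function(n_compounds = 40, n_pathways = 4,
                               taxonomy_depth = 5, seed = 1,
                               source = "primary") {
  if (n_compounds < 1 || n_pathways < 1 || taxonomy_depth < 1) {
    stopf("n_compounds, n_pathways and taxonomy_depth must be positive")
  }
  with_seed(derive_seed(seed, "reference"), {
    formulas <- character(0)
    guard <- 0
    while (length(formulas) < n_compounds) {
      guard <- guard + 1
      if (guard > 50 * n_compounds) {
        stopf("cannot generate %d distinct formulas; combinatorial capacity exceeded",
              n_compounds)
      }
      c_n <- sample(3:30, 1)
      n_n <- sample(0:4, 1)
      h_n <- sample(seq(max(2, c_n - 4), 2 * c_n + 2 + n_n), 1)
      o_n <- sample(0:14, 1)
      f <- paste0("C", c_n, "H", h_n,
                  if (n_n) paste0("N", n_n) else "",
                  if (o_n) paste0("O", o_n) else "")
      if (!f %in% formulas) formulas <- c(formulas, f)
    }
    mass <- vapply(formulas, monoisotopic_mass, numeric(1))

    # taxonomy: random tree, 2-3 children per term at each level
    level_names <- c("kingdom", "superclass", "class", "subclass",
                     "level5", "level6", "level7")[seq_len(taxonomy_depth)]
    n_terms <- pmin(2^(seq_len(taxonomy_depth) - 1), 8)
    terms <- lapply(seq_len(taxonomy_depth), function(l) {
      sprintf("%s_%d", level_names[l], seq_len(n_terms[l]))
    })
    parent <- lapply(seq_len(taxonomy_depth), function(l) {
      if (l == 1) return(integer(0))
      sort(rep_len(seq_len(n_terms[l - 1]), n_terms[l]))
    })
    lineage <- vapply(seq_len(n_compounds), function(i) {
      path <- integer(taxonomy_depth)
      path[taxonomy_depth] <- sample(n_terms[taxonomy_depth], 1)
      for (l in rev(seq_len(taxonomy_depth - 1))) {
        path[l] <- parent[[l + 1]][path[l + 1]]
      }
      paste(mapply(function(l, k) terms[[l]][k], seq_len(taxonomy_depth), path),
            collapse = "|")
    }, character(1))

    # pathways and reactions
    pathway_ids <- sprintf("path%03d", seq_len(n_pathways))
    n_reactions <- max(n_pathways, ceiling(n_compounds / 4))
    reaction_ids <- sprintf("rxn%03d", seq_len(n_reactions))
    rxn_pathway <- pathway_ids[rep_len(seq_len(n_pathways), n_reactions)]
    cmp_ids <- sprintf("cmp%03d", seq_len(n_compounds))
    # each compound participates in 1-2 reactions; every reaction gets >= 1
    cmp_rxn <- lapply(seq_len(n_compounds), function(i) {
      k <- if (i <= n_reactions) i else sample(n_reactions, sample(1:2, 1))
      unique(k)
    })
    edges <- rbind(
      do.call(rbind, lapply(seq_len(n_compounds), function(i) {
        data.frame(from = cmp_ids[i], to = reaction_ids[cmp_rxn[[i]]],
                   type = "participates", stringsAsFactors = FALSE)
      })),
      data.frame(from = reaction_ids, to = rxn_pathway, type = "member_of",
                 stringsAsFactors = FALSE)
    )
    cmp_pathways <- vapply(seq_len(n_compounds), function(i) {
      paste(sort(unique(rxn_pathway[cmp_rxn[[i]]])), collapse = ";")
    }, character(1))

    compounds <- data.frame(
      compound_id = cmp_ids,
      formula = formulas,
      mass = unname(mass),
      source = rep_len(source, n_compounds),
      lineage = lineage,
      pathway_ids = cmp_pathways,
      stringsAsFactors = FALSE
    )
    taxonomy <- data.frame(
      level = rep(level_names, n_terms),
      term = unlist(terms),
      parent = c(NA_character_,
                 unlist(mapply(function(l, p) terms[[l - 1]][p],
                               seq_len(taxonomy_depth)[-1], parent[-1],
                               SIMPLIFY = FALSE))),
      stringsAsFactors = FALSE
    )
    list(compounds = compounds, taxonomy = taxonomy, edges = edges,
         rules = adduct_rules())
  })
}

#' Write / read a compound reference as delimited text
#'
#' @param reference List as returned by [generate_reference()].
#' @param dir Directory to hold `compounds.csv`, `taxonomy.csv`, `edges.csv`.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(reference$compounds, file.path(dir, "compounds.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(reference$taxonomy, file.path(dir, "taxonomy.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(reference$edges, file.path(dir, "edges.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  compounds <- utils::read.table(file.path(dir, "compounds.csv"), sep = ",",
                                 header = TRUE, stringsAsFactors = FALSE)
  validate_formula_db(compounds)
  list(
    compounds = compounds,
    taxonomy = utils::read.table(file.path(dir, "taxonomy.csv"), sep = ",",
                                 header = TRUE, stringsAsFactors = FALSE),
    edges = utils::read.table(file.path(dir, "edges.csv"), sep = ",",
                              header = TRUE, stringsAsFactors = FALSE),
    rules = adduct_rules()
  )
}

# loaded formula databases must have masses consistent with their formulas
validate_formula_db <- function(db, tol = 1e-4) {
  need <- c("compound_id", "formula", "mass", "source", "lineage")
  if (!all(need %in% names(db))) {
    stopf("formula db must have columns %s", paste(need, collapse = ", "))
  }
  if (any(db$mass <= 0)) stopf("formula db masses must be positive")
  calc <- vapply(db$formula, monoisotopic_mass, numeric(1))
  bad <- abs(calc - db$mass) > tol
  if (any(bad)) {
    stopf("formula db mass inconsistent with formula for: %s",
          paste(db$compound_id[bad], collapse = ", "))
  }
  invisible(db)
}
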