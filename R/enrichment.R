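# Cluster enrichment: structural over-representation by one-sided Fisher's
# exact test with Benjamini-Hochberg adjustment, and diffusion (personalized
# PageRank) pathway enrichment on a compound-reaction-pathway knowledge
# graph with an empirical random-seed null.

#' Structural over-representation analysis (Fisher's exact test)
#'
#' For every annotation term present in the background, tests whether the
#' cluster contains more term-annotated features than expected under the
#' hypergeometric null (one-sided, enrichment direction), then adjusts
#' p-values across terms within the cluster.
#'
#' @param cluster_ids Feature ids in the cluster (subset of the background).
#' @param background_ids All feature ids forming the background set.
#' @param annotations data.frame with columns `feature_id`, `term` (one row
#'   per feature-term association, e.g. every term of a consensus lineage).
#' @param adjust Multiplicity adjustment, `"BH"` or `"bonferroni"`.
#' @return data.frame with one row per term: `term`, `in_cluster`,
#'   `cluster_size`, `in_background`, `background_size`, `p_value`,
#'   `adjusted_p`, sorted by p-value.
#' @export
fisher_ora <- function(cluster_ids, background_ids, annotations,
                       adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!all(cluster_ids %in% background_ids)) {
    stopf("cluster features must be a subset of the background")
  }
  if (!length(cluster_ids)) {
    warnf("empty cluster; no enrichment rows")
    return(data.frame(term = character(), in_cluster = integer(),
                      cluster_size = integer(), in_background = integer(),
                      background_size = integer(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  }
  ann <- annotations[annotations$feature_id %in% background_ids, , drop = FALSE]
  terms <- unique(ann$term)
  n_bg <- length(background_ids)
  n_cl <- length(cluster_ids)
  rows <- lapply(terms, function(tm) {
    feat <- unique(ann$feature_id[ann$term == tm])
    k_bg <- length(feat)
    k_cl <- sum(cluster_ids %in% feat)
    tab <- matrix(c(k_cl, n_cl - k_cl, k_bg - k_cl,
                    n_bg - n_cl - (k_bg - k_cl)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, in_cluster = k_cl, cluster_size = n_cl,
               in_background = k_bg, background_size = n_bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a compound-reaction-pathway knowledge graph
#'
#' Assembles an undirected tripartite igraph from a compound table and an
#' edge list; node types are inferred from the tables. Dangling edge
#' endpoints raise an error listing them.
#'
#' @param compounds Compound table (needs `compound_id`).
#' @param edges data.frame with `from`, `to` (ids of compounds, reactions or
#'   pathways).
#' @return An igraph with a `type` vertex attribute in
#'   `{"compound", "reaction", "pathway"}`.
#' @export
build_knowledge_graph <- function(compounds, edges) {
  ids <- unique(c(edges$from, edges$to))
  type <- rep("reaction", length(ids))
  type[ids %in% compounds$compound_id] <- "compound"
  type[grepl("^path", ids)] <- "pathway"
  # pathway ids may also be declared through the compound table
  declared <- unique(unlist(strsplit(compounds$pathway_ids %||% character(0), ";")))
  type[ids %in% declared] <- "pathway"
  if ("type" %in% names(edges)) {
    # compound-participation edges must reference declared compounds
    dangling <- setdiff(edges$from[edges$type == "participates"],
                        compounds$compound_id)
    if (length(dangling)) {
      stopf("dangling edge ids (undeclared compounds): %s",
            paste(dangling, collapse = ", "))
    }
  }
  g <- igraph::graph_from_data_frame(edges[order(edges$from, edges$to), c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = sort(ids)))
  igraph::V(g)$type <- type[match(igraph::V(g)$name, ids)]
  comp <- igraph::components(g)
  message(sprintf("knowledge graph: %d nodes, %d edges, %d connected component(s)",
                  igraph::vcount(g), igraph::ecount(g), comp$no))
  g
}

#' Personalized-PageRank pathway enrichment
#'
#' Scores every graph node by personalized PageRank with the restart mass
#' spread uniformly over the seed compounds, then assigns each non-seed
#' node an empirical p-score against a null of `n_null` equally sized
#' random compound seed sets:
#' `p = (1 + #\{null score >= observed score\}) / (1 + n_null)`.
#' Smaller p-scores indicate nodes more specifically connected to the seeds
#' than to random compounds.
#'
#' @param graph Knowledge graph from [build_knowledge_graph()].
#' @param seeds Seed compound node names (must exist in the graph).
#' @param damping PageRank damping factor in (0, 1).
#' @param n_null Null draws.
#' @param seed RNG seed.
#' @return data.frame with `node`, `type`, `score`, `p_score` for all
#'   non-seed nodes, pathways first, sorted by p-score then score.
#' @export
pagerank_enrichment <- function(graph, seeds, damping = 0.85, n_null = 1000,
                                seed = 1) {
  if (damping <= 0 || damping >= 1) stopf("damping must be in (0, 1)")
  nodes <- igraph::V(graph)$name
  seeds <- unique(seeds)
  if (!length(seeds) || !all(seeds %in% nodes)) {
    stopf("seed compounds missing from the graph: %s",
          paste(setdiff(seeds, nodes), collapse = ", "))
  }
  compounds <- nodes[igraph::V(graph)$type == "compound"]
  score_for <- function(seed_set) {
    pers <- stats::setNames(numeric(length(nodes)), nodes)
    pers[seed_set] <- 1 / length(seed_set)
    igraph::page_rank(graph, damping = damping, personalized = pers)$vector
  }
  observed <- score_for(seeds)
  null_draws <- with_seed(derive_seed(seed, "pagerank_null"), {
    replicate(n_null, score_for(sample(compounds, length(seeds))))
  })
  exceed <- rowSums(null_draws >= observed)
  p_score <- (1 + exceed) / (1 + n_null)
  keep <- !nodes %in% seeds
  out <- data.frame(
    node = nodes[keep],
    type = igraph::V(graph)$type[keep],
    score = unname(observed[keep]),
    p_score = unname(p_score[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$type != "pathway", out$p_score, -out$score), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster-wise enrichment report
#'
#' Runs structural ORA and PageRank pathway enrichment for each trend
#' cluster.
#'
#' @param clusters Named cluster assignment (feature id -> cluster).
#' @param annotations Structural annotations (`feature_id`, `term`).
#' @param feature_compounds Optional data.frame (`feature_id`,
#'   `compound_id`) linking features to graph compounds for the functional
#'   side; `NULL` skips PageRank.
#' @param graph Knowledge graph (required when `feature_compounds` given).
#' @param n_null,damping,seed Passed to [pagerank_enrichment()].
#' @return List with `structural` (data.frame with `cluster` column) and
#'   `functional` (data.frame or `NULL`).
#' @export
cluster_enrichment <- function(clusters, annotations,
                               feature_compounds = NULL, graph = NULL,
                               n_null = 1000, damping = 0.85, seed = 1) {
  background <- names(clusters)
  structural <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    ids <- names(clusters)[clusters == cl]
    res <- fisher_ora(ids, background, annotations)
    if (nrow(res)) cbind(cluster = cl, res) else NULL
  }))
  functional <- NULL
  if (!is.null(feature_compounds) && !is.null(graph)) {
    functional <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
      ids <- names(clusters)[clusters == cl]
      cmp <- unique(feature_compounds$compound_id[
        feature_compounds$feature_id %in% ids])
      cmp <- intersect(cmp, igraph::V(graph)$name)
      if (!length(cmp)) return(NULL)
      res <- pagerank_enrichment(graph, cmp, damping = damping,
                                 n_null = n_null,
                                 seed = derive_seed(seed, paste0("cl", cl)))
      res <- res[res$type == "pathway", , drop = FALSE]
      if (nrow(res)) cbind(cluster = cl, res) else NULL
    }))
  }
  list(structural = structural, functional = functional)
}
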