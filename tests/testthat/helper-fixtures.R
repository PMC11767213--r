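# Shared fixture builders; everything is generated in code at test time.

# minimal formula database with known masses
tiny_db <- function() {
  forms <- c("C6H12O6", "C12H22O11", "C9H11NO2", "C5H5N5", "C10H16N5O13P3")
  data.frame(
    compound_id = sprintf("c%d", seq_along(forms)),
    formula = forms,
    mass = vapply(forms, monoisotopic_mass, numeric(1)),
    source = "primary",
    lineage = c("kA|sA|cA|uA", "kA|sA|cA|uB", "kA|sB|cC|uC",
                "kA|sB|cD|uD", "kA|sA|cA|uA"),
    pathway_ids = c("path001", "path001", "path002", "path002", "path001"),
    stringsAsFactors = FALSE
  )
}

# one-sample scan set built from explicit peaks
peaks_scan_set <- function(scan, mode, mz, intensity, sample_id = "S1",
                           mz_range = c(55, 1200)) {
  scan_set(sample_id,
           data.frame(scan = scan, mode = mode, mz = mz, intensity = intensity,
                      stringsAsFactors = FALSE),
           mz_range = mz_range)
}

# small two-class dataset generator used by several RF tests
two_class_data <- function(n_per_class = 20, n_features = 100,
                           n_disc = 0, effect = 0, noise_sd = 0.3, seed = 1) {
  spec <- synthetic_spec(
    classes = c("g3", "g4"), n_per_class = n_per_class,
    n_features = n_features, n_discriminating = n_disc,
    effect_size = effect, noise_sd = noise_sd, qc_n = 0, zero_rate = 0,
    seed = seed
  )
  ds <- generate_feature_matrix(spec)
  bio <- ds$samples[ds$samples$role == "sample", ]
  list(x = log2(as.matrix(ds$matrix)[bio$sample_id, , drop = FALSE]),
       y = bio$class, samples = ds$samples, truth = ds$truth)
}

# random connected undirected tripartite-ish graph for PageRank oracles
random_connected_graph <- function(n_nodes, seed) {
  set.seed(seed)
  # random spanning tree plus a few extra edges => connected, no isolates
  parent <- c(NA, vapply(2:n_nodes, function(i) sample(i - 1, 1), numeric(1)))
  edges <- data.frame(from = paste0("v", parent[-1]),
                      to = paste0("v", 2:n_nodes))
  extra <- max(2, n_nodes %/% 3)
  more <- t(replicate(extra, sample(n_nodes, 2)))
  edges <- rbind(edges, data.frame(from = paste0("v", more[, 1]),
                                   to = paste0("v", more[, 2])))
  edges <- edges[edges$from != edges$to, ]
  igraph::simplify(igraph::graph_from_data_frame(edges, directed = FALSE))
}

# reference personalized-PageRank by dense power iteration
power_iteration_pagerank <- function(graph, pers, damping,
                                     tol = 1e-15, max_iter = 10000) {
  a <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  deg <- rowSums(a)
  p <- a / deg  # row-stochastic; graphs used here have no isolated nodes
  v <- pers / sum(pers)
  r <- v
  for (i in seq_len(max_iter)) {
    r_new <- damping * as.vector(t(p) %*% r) + (1 - damping) * v
    if (max(abs(r_new - r)) < tol) return(stats::setNames(r_new, rownames(a)))
    r <- r_new
  }
  stats::setNames(r, rownames(a))
}

# hypergeometric enrichment tail by explicit pmf summation
hypergeom_tail <- function(k_cl, n_cl, k_bg, n_bg) {
  xs <- k_cl:min(n_cl, k_bg)
  sum(stats::dhyper(xs, k_bg, n_bg - k_bg, n_cl))
}
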