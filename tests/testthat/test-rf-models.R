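test_that("margin statistic follows the vote-difference definition", {
  votes <- rbind(c(1, 0), c(0.5, 0.5), c(0.4, 0.6))
  colnames(votes) <- c("A", "B")
  y <- c("A", "A", "A")
  expect_equal(margin_statistic(votes, y, per_sample = TRUE),
               c(1, 0, -0.2))
  expect_equal(margin_statistic(votes, y), mean(c(1, 0, -0.2)))
  # unanimous correct votes -> 1
  v2 <- rbind(c(1, 0), c(0, 1))
  colnames(v2) <- c("A", "B")
  expect_equal(margin_statistic(v2, c("A", "B")), 1)
})

test_that("planted class structure yields a large margin; null does not", {
  d <- two_class_data(n_per_class = 20, n_features = 100, n_disc = 5,
                      effect = 1.2, noise_sd = 0.3, seed = 31)
  fit <- fit_rf_classifier(d$x, d$y, n_trees = 500, seed = 1)
  expect_gt(fit$margin, 0.5)
  expect_true(all(abs(rowSums(fit$votes) - 1) < 1e-12))
  expect_true(all(fit$per_sample_margin >= -1 & fit$per_sample_margin <= 1))
  # shuffled labels: margin near zero
  y_null <- with_seed(7, sample(d$y))
  fit0 <- fit_rf_classifier(d$x, y_null, n_trees = 500, seed = 1)
  expect_lt(abs(fit0$margin), 0.1)
  expect_error(fit_rf_classifier(d$x, rep("A", nrow(d$x))), "2 classes")
})

test_that("proximity is symmetric, unit-diagonal, and highest for a duplicate", {
  d <- two_class_data(n_per_class = 10, n_features = 60, n_disc = 4,
                      effect = 1, seed = 33)
  x2 <- rbind(d$x, DUP = d$x[1, ])
  y2 <- c(d$y, d$y[1])
  fit <- fit_rf_classifier(x2, y2, n_trees = 1000, seed = 2)
  p <- fit$proximity
  expect_true(isSymmetric(unname(p)))
  expect_true(all(diag(p) == 1))
  expect_true(all(p >= 0 & p <= 1))
  dup_row <- p["DUP", setdiff(rownames(p), "DUP")]
  expect_equal(names(which.max(dup_row)), rownames(d$x)[1])
})

test_that("permutation p follows the add-one rule and is seed-reproducible", {
  d <- two_class_data(n_per_class = 10, n_features = 50, n_disc = 5,
                      effect = 1.5, seed = 35)
  pt <- permutation_test(d$x, d$y, "margin", n_perm = 19, n_trees = 100,
                         seed = 4)
  expect_equal(pt$p, (1 + sum(pt$null >= pt$observed)) / 20)
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  # strong planted effect beats every null draw
  expect_equal(pt$p, 1 / 20)
  pt2 <- permutation_test(d$x, d$y, "margin", n_perm = 19, n_trees = 100,
                          seed = 4)
  expect_identical(pt, pt2)
})

test_that("proximity converts to distance as 1 - proximity", {
  p <- matrix(c(1, 0.344, 0.344, 1), 2, 2)
  d <- proximity_to_distance(p)
  expect_equal(d[1, 2], 0.656)
  expect_equal(diag(d), c(0, 0))
  expect_error(proximity_to_distance(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("classical MDS reproduces simple geometries and the eigen oracle", {
  # two points at distance d -> coordinates +/- d/2 on the first axis
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  m2 <- classical_mds(d2, dims = 1)
  expect_equal(sort(m2$points[, 1]), c(-1.5, 1.5))
  # three points pairwise distance 1 -> equilateral triangle with side 1
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  m3 <- classical_mds(d3, dims = 2)
  expect_equal(as.numeric(stats::dist(m3$points)), rep(1, 3),
               tolerance = 1e-12)
  # random instance vs the base cmdscale eigendecomposition route
  set.seed(41)
  pts <- matrix(rnorm(16), 8, 2)
  dd <- as.matrix(stats::dist(pts))
  mine <- classical_mds(dd, dims = 2)
  ref <- stats::cmdscale(dd, k = 2)
  expect_equal(unname(as.matrix(stats::dist(mine$points))),
               unname(as.matrix(stats::dist(ref))), tolerance = 1e-10)
  expect_error(classical_mds(dd, dims = 8), "dims")
})

test_that("confidence ellipses are centred, equivariant and sized by chi-square", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(cos(theta), sin(theta))
  e <- confidence_ellipse(circ, 0.95)
  expect_equal(unname(e$centre), c(0, 0), tolerance = 1e-12)
  expect_equal(e$radius, sqrt(stats::qchisq(0.95, 2)))
  # doubling the coordinates doubles the ellipse axes (cov scales by 4)
  e2 <- confidence_ellipse(2 * circ, 0.95)
  expect_equal(e2$cov, 4 * e$cov)
  expect_error(confidence_ellipse(circ[1:2, ]), "at least 3")
})

test_that("within-class distance summaries enumerate all pairs", {
  d <- matrix(0.3, 5, 5); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  cls <- c("A", "A", "A", "B", "B")
  res <- intraclass_distance_summary(d, cls)
  expect_equal(res$summary$n_pairs, c(3L, 1L))  # C(3,2), C(2,2)
  expect_equal(res$summary$median, c(0.3, 0.3))
  # singleton class flagged with empty multiset
  res1 <- intraclass_distance_summary(d, c("A", "A", "A", "A", "C"))
  expect_equal(res1$summary$n_pairs[res1$summary$class == "C"], 0L)
  expect_true(is.na(res1$summary$median[res1$summary$class == "C"]))
  # permutation invariance of medians
  perm <- c(3, 1, 5, 2, 4)
  res_p <- intraclass_distance_summary(d[perm, perm], cls[perm])
  expect_equal(res_p$summary$median[order(res_p$summary$class)],
               res$summary$median[order(res$summary$class)])
})

test_that("pairwise margin dendrogram merges indistinguishable classes first", {
  # A and B share a distribution; C is shifted away
  set.seed(43)
  n <- 12; p <- 40
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = 2), n, p))
  rownames(x) <- sprintf("s%02d", seq_len(3 * n))
  y <- rep(c("A", "B", "C"), each = n)
  res <- pairwise_margin_dendrogram(x, y, n_trees = 300, seed = 5)
  expect_lt(res$margins["A", "B"], res$margins["A", "C"])
  expect_lt(res$margins["A", "B"], res$margins["B", "C"])
  merged_first <- res$hclust$labels[-res$hclust$merge[1, ]]
  expect_setequal(merged_first, c("A", "B"))
})

test_that("regression recovers a response encoded by one feature", {
  set.seed(47)
  n <- 150; p <- 30
  t <- runif(n, 0, 15)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("f%03d", 1:p)))
  x[, 1] <- t + rnorm(n, 0, 0.05)
  fit <- fit_rf_regressor(x, t, n_trees = 500, seed = 6)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(names(which.max(fit$importance)), "f001")
  # pure noise: OOB R^2 at or below zero on average
  r2s <- vapply(1:5, function(i) {
    set.seed(i)
    xn <- matrix(rnorm(30 * 40), 30, 40)
    fit_rf_regressor(xn, rnorm(30), n_trees = 200, seed = i)$r_squared
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
  expect_error(fit_rf_regressor(x, rep(1, n)), "distinct")
})

test_that("importance-permutation selection picks out planted features", {
  set.seed(49)
  n <- 32; p <- 80
  t <- rep(c(0, 3, 9, 15), each = n / 4)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:p)))
  planted <- sprintf("f%03d", 1:8)
  for (j in 1:8) x[, j] <- x[, j] + 0.3 * t * c(1, -1)[1 + j %% 2]
  fit <- fit_rf_regressor(x, t, n_trees = 300, seed = 7,
                          n_perm_importance = 60)
  expect_true(all(fit$importance_p > 0 & fit$importance_p <= 1))
  expect_gte(mean(fit$explanatory %in% planted), 0.8)
  expect_gte(sum(planted %in% fit$explanatory), 6)
})
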