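test_that("formula assignment finds planted adducts within tolerance", {
  db <- tiny_db()
  rec <- assign_formulas(179.0561, "negative", db)
  expect_true(any(rec$candidates$formula == "C6H12O6" &
                    rec$candidates$adduct == "[M-H]-"))
  expect_true(all(abs(rec$candidates$ppm_error) <= 3))
  # far from every candidate
  rec2 <- assign_formulas(179.10, "negative", db)
  expect_equal(nrow(rec2$candidates), 0)
  expect_error(assign_formulas(100, "negative", db[0, ]), "empty")
})

test_that("fallback source is consulted only when the primary has no hit", {
  db <- tiny_db()
  db$source <- c("fallback", rep("primary", 4))
  # glucose [M-H]- only exists in the fallback record
  rec <- assign_formulas(179.0561, "negative", db)
  expect_true(all(rec$candidates$source == "fallback"))
  # when a primary hit exists, fallback is not searched
  db2 <- tiny_db()
  db2 <- rbind(db2, within(db2[1, ], {
    compound_id <- "dup"; source <- "fallback"
  }))
  rec2 <- assign_formulas(179.0561, "negative", db2)
  expect_true(all(rec2$candidates$source == "primary"))
})

test_that("assignment equals exhaustive enumeration over (compound, rule) pairs", {
  ref <- generate_reference(n_compounds = 40, n_pathways = 3,
                            taxonomy_depth = 4, seed = 14)
  db <- ref$compounds
  rules <- adduct_rules()
  set.seed(15)
  test_mz <- c(
    runif(20, 55, 1200),
    # and some m/z placed exactly on candidate ions
    vapply(1:20, function(i) {
      cmp <- db[sample(nrow(db), 1), ]
      repeat {
        rule <- rules[sample(nrow(rules), 1), ]
        h <- parse_formula(cmp$formula)[["H"]]
        if (!is.na(h) && h >= rule$min_h) break
      }
      theoretical_mz(cmp$mass, rule) * (1 + runif(1, -2e-6, 2e-6))
    }, numeric(1))
  )
  for (mz in test_mz) {
    for (mode in c("positive", "negative")) {
      got <- assign_formulas(mz, mode, db, rules, tolerance_ppm = 3)$candidates
      # oracle: enumerate all pairs
      expected <- list()
      for (ci in seq_len(nrow(db))) {
        for (ri in seq_len(nrow(rules))) {
          rule <- rules[ri, ]
          if (rule$polarity != mode) next
          h <- parse_formula(db$formula[ci])[["H"]]
          if (is.na(h)) h <- 0
          if (h < rule$min_h) next
          theo <- (rule$n * db$mass[ci] + rule$shift) / rule$z
          if (abs(1e6 * (mz - theo) / theo) <= 3) {
            expected[[length(expected) + 1]] <-
              paste(db$formula[ci], rule$name)
          }
        }
      }
      expect_setequal(paste(got$formula, got$adduct),
                      unique(unlist(expected)) %||% character(0))
    }
  }
})

test_that("tightening the tolerance never adds candidates", {
  ref <- generate_reference(30, 3, 4, seed = 16)
  set.seed(17)
  for (mz in runif(25, 55, 1200)) {
    prev <- Inf
    for (tol in c(10, 5, 3, 1)) {
      n <- nrow(assign_formulas(mz, "positive", ref$compounds,
                                tolerance_ppm = tol)$candidates)
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("consensus accepts 2-of-3 at 0.66 and stops at divergence", {
  # identical above, 2 share subclass X
  cc <- consensus_classification(c("k|s|X", "k|s|X", "k|s|Y"), 0.66)
  expect_equal(cc$lineage, c("k", "s", "X"))
  expect_equal(cc$fractions[3], 2 / 3, tolerance = 1e-12)
  # 1-of-2 (0.5) rejected at the divergent level
  cc2 <- consensus_classification(c("k|A", "k|B"), 0.66)
  expect_equal(cc2$lineage, "k")
  # single compound: full lineage, fraction 1 everywhere
  cc3 <- consensus_classification("k|s|c|u", 0.66)
  expect_equal(cc3$depth, 4L)
  expect_equal(cc3$fractions, rep(1, 4))
  # no compounds: unclassified
  cc4 <- consensus_classification(character(0), 0.66)
  expect_equal(cc4$depth, 0L)
})

test_that("raising the consensus threshold never deepens a lineage", {
  set.seed(18)
  terms <- list(c("k1", "k2"), c("s1", "s2", "s3"), c("c1", "c2", "c3", "c4"),
                c("u1", "u2", "u3", "u4", "u5"))
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    lineages <- replicate(n, paste(
      vapply(terms, function(t) sample(t, 1), character(1)),
      collapse = "|"))
    depths <- vapply(c(0.5, 0.66, 0.8, 0.95), function(thr) {
      consensus_classification(lineages, thr)$depth
    }, integer(1))
    expect_true(all(diff(depths) <= 0))
  }
})

test_that("composition summary counts respect the lineage hierarchy", {
  db <- tiny_db()
  bins <- data.frame(
    bin_id = c("n179.05", "n341.10", "n400.00"),
    mode = "negative",
    mz = c(179.0561, 341.108953, 400.123),
    stringsAsFactors = FALSE
  )
  recs <- annotate_features(bins, db)
  cs <- composition_summary(recs)
  expect_equal(cs$count[cs$term == "kA"], 2)
  expect_equal(cs$count[cs$term == "unclassified"], 1)
  # a parent term's count is at least any child's count
  expect_true(all(cs$count[cs$level == 1 & cs$term != "unclassified"] >=
                    max(cs$count[cs$level == 2])))
})
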