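# Random-forest regression of fingerprint features on a numeric response
# (sampling hour): out-of-bag R-squared, %IncMSE importances and selection
# of explanatory features by importance-permutation p-values.

#' Fit a random-forest regressor and select explanatory features
#'
#' The out-of-bag R-squared is `1 - MSE_oob / var(t)`. Per-feature
#' importance is the percent increase in out-of-bag mean squared error when
#' the feature is permuted (%IncMSE). When `n_perm_importance > 0`, a null
#' importance distribution is built by refitting the forest with the
#' response permuted; each feature's p-value compares its observed %IncMSE
#' with its own null draws under the add-one rule, and features with
#' `p < alpha` (no multiplicity adjustment) form the explanatory set.
#'
#' @param x Feature matrix (samples x features).
#' @param t Numeric response (e.g. hours since first sampling); needs at
#'   least 3 distinct values.
#' @param n_trees Number of trees.
#' @param seed RNG seed.
#' @param n_perm_importance Response-permutation refits for the importance
#'   null (0 skips feature selection).
#' @param alpha Selection threshold on the importance p-value.
#' @return An `rf_reg_result`: list with `r_squared`, `importance`
#'   (%IncMSE per feature), `importance_p`, `explanatory` (feature ids),
#'   `predicted` (OOB), `n_trees`, `seed`, `alpha`.
#' @export
fit_rf_regressor <- function(x, t, n_trees = 1000, seed = 1,
                             n_perm_importance = 0, alpha = 0.05) {
  t <- as.numeric(t)
  if (length(unique(t)) < 3) {
    stopf("regression needs at least 3 distinct response values")
  }
  if (nrow(x) != length(t)) stopf("x and t disagree on the number of samples")
  fit_once <- function(resp, s) {
    # a few distinct response values (e.g. 4 sampling hours) is by design
    withCallingHandlers(
      with_seed(s, randomForest::randomForest(x, resp, ntree = n_trees,
                                              importance = TRUE)),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  rf <- fit_once(t, derive_seed(seed, "reg_observed"))
  mse_oob <- mean((rf$predicted - t)^2)
  r2 <- 1 - mse_oob / mean((t - mean(t))^2)
  imp <- rf$importance[, "%IncMSE"]
  names(imp) <- colnames(x)

  imp_p <- NULL
  explanatory <- character(0)
  if (n_perm_importance > 0) {
    null_imp <- with_seed(derive_seed(seed, "reg_null"), {
      vapply(seq_len(n_perm_importance), function(b) {
        tt <- t[sample.int(length(t))]
        rfb <- fit_once(tt, derive_seed(seed, paste0("reg_perm", b)))
        rfb$importance[, "%IncMSE"]
      }, numeric(ncol(x)))
    })
    # per-feature null: add-one empirical tail
    imp_p <- (1 + rowSums(null_imp >= imp)) / (1 + n_perm_importance)
    names(imp_p) <- colnames(x)
    explanatory <- colnames(x)[imp_p < alpha]
  }
  structure(
    list(r_squared = r2, importance = imp, importance_p = imp_p,
         explanatory = explanatory, predicted = rf$predicted,
         n_trees = n_trees, seed = seed, alpha = alpha,
         n_perm_importance = n_perm_importance),
    class = "rf_reg_result"
  )
}

#' @export
print.rf_reg_result <- function(x, ...) {
  cat(sprintf("rf_reg_result: OOB R^2 = %.3f, %d explanatory feature(s) at p < %g\n",
              x$r_squared, length(x$explanatory), x$alpha))
  invisible(x)
}
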