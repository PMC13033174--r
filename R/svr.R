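#' Nested cross-validation configuration for linear SVR
#'
#' @param outer_folds,inner_folds fold counts (>= 2).
#' @param repeats number of repeated outer splits.
#' @param C_grid positive cost grid searched in the inner loop.
#' @param epsilon epsilon-insensitive margin on z-scaled targets.
#' @param n_perm permutations for [svr_permutation_p()].
#' @param perm_repeats repeats used inside each permutation refit (a
#'   reduced-cost approximation of the full pipeline; recorded in the
#'   result).
#' @param seed integer seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10, inner_folds = 5, repeats = 10,
                      C_grid = 2^seq(-5, 5, by = 2), epsilon = 0.1,
                      n_perm = 1000, perm_repeats = 1, seed = 1) {
  if (outer_folds < 2 || inner_folds < 2) stop("fold counts must be >= 2")
  if (!length(C_grid) || any(C_grid <= 0)) stop("`C_grid` must be positive and non-empty")
  if (epsilon < 0) stop("`epsilon` must be non-negative")
  if (repeats < 1) stop("`repeats` must be >= 1")
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 repeats = repeats, C_grid = C_grid, epsilon = epsilon,
                 n_perm = n_perm, perm_repeats = perm_repeats, seed = seed),
            class = "cv_config")
}

# z-scale with training statistics; returns function to apply to new data
train_scaler <- function(X) {
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(apply = function(M) sweep(sweep(M, 2, mu), 2, sd, "/"),
       mu = mu, sd = sd)
}

# linear SVR weight vector in (scaled) feature space
svr_weights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

fit_linear_svr <- function(X, y, C, epsilon) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "linear",
             cost = C, epsilon = epsilon, scale = FALSE)
}

# rank-based AUC of scores against binary labels (positive = level2)
rank_auc <- function(scores, labels) {
  pos <- labels == levels(factor(labels))[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nested cross-validated linear support-vector regression
#'
#' Repeated nested cross-validation: each repeat draws an outer fold
#' assignment; within each outer training set an inner cross-validation
#' selects the cost `C` maximizing the mean inner held-out Pearson
#' correlation; the selected model is refit on the outer training set
#' and predicts the held-out outer fold. Feature and target scaling are
#' computed on training folds only. Held-out predictions are averaged
#' across repeats per subject and summarized by Pearson r, a Fisher-z
#' 95 percent CI and (when `labels` given) the ROC AUC of the
#' predictions against the group labels.
#'
#' @param X feature matrix (subjects x features, finite).
#' @param y numeric target.
#' @param config a [cv_config()].
#' @param labels optional binary group labels for the AUC.
#' @param keep_weights store per-fold weight vectors (needed by
#'   [cvr_importance()]); default TRUE.
#' @return object of class `prediction_result`.
#' @export
nested_cv_svr <- function(X, y, config = cv_config(), labels = NULL,
                          keep_weights = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("`X` and `y` must share the subject axis")
  if (any(!is.finite(X))) stop("features must be finite")
  if (stats::sd(y) == 0) stop("constant target `y`")
  if (n < 4 * config$outer_folds)
    stop(sprintf("n = %d too small for %d outer folds (need >= %d)",
                 n, config$outer_folds, 4 * config$outer_folds))
  set.seed(config$seed)
  pred_sum <- numeric(n); pred_cnt <- numeric(n)
  weights <- list(); fold_assignments <- list()
  models_summary <- list()
  for (rep_i in seq_len(config$repeats)) {
    fold <- sample(rep_len(seq_len(config$outer_folds), n))
    fold_assignments[[rep_i]] <- fold
    wmat <- matrix(NA_real_, config$outer_folds, ncol(X))
    chosen <- numeric(config$outer_folds)
    for (k in seq_len(config$outer_folds)) {
      tr <- fold != k
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      sc <- train_scaler(Xtr); Xtr_s <- sc$apply(Xtr)
      ysc <- c(mean(ytr), stats::sd(ytr))
      ytr_s <- (ytr - ysc[1]) / ysc[2]
      bestC <- config$C_grid[1]
      if (length(config$C_grid) > 1) {
        ifold <- sample(rep_len(seq_len(config$inner_folds), sum(tr)))
        perf <- vapply(config$C_grid, function(C) {
          cc <- vapply(seq_len(config$inner_folds), function(j) {
            itr <- ifold != j
            if (stats::sd(ytr_s[itr]) == 0) return(0)
            m <- fit_linear_svr(Xtr_s[itr, , drop = FALSE], ytr_s[itr],
                                C, config$epsilon)
            ph <- stats::predict(m, Xtr_s[!itr, , drop = FALSE])
            if (stats::sd(ph) == 0 || stats::sd(ytr_s[!itr]) == 0) 0
            else stats::cor(ph, ytr_s[!itr])
          }, numeric(1))
          mean(cc)
        }, numeric(1))
        bestC <- config$C_grid[which.max(perf)]
      }
      m <- fit_linear_svr(Xtr_s, ytr_s, bestC, config$epsilon)
      ph <- stats::predict(m, sc$apply(X[!tr, , drop = FALSE]))
      pred_sum[!tr] <- pred_sum[!tr] + (ph * ysc[2] + ysc[1])
      pred_cnt[!tr] <- pred_cnt[!tr] + 1
      chosen[k] <- bestC
      if (keep_weights) wmat[k, ] <- svr_weights(m)
    }
    if (keep_weights) weights[[rep_i]] <- wmat
    models_summary[[rep_i]] <- chosen
  }
  predictions <- pred_sum / pred_cnt
  r <- stats::cor(predictions, y)
  res <- structure(list(
    predictions = predictions, observed = y,
    r = r, ci95 = fisher_z_ci(r, n),
    auc = if (is.null(labels)) NA_real_ else rank_auc(predictions, labels),
    p_perm = NA_real_,
    fold_assignments = fold_assignments,
    models_summary = models_summary,
    weights = if (keep_weights) weights else NULL,
    feature_names = colnames(X) %||% sprintf("f%04d", seq_len(ncol(X))),
    config = config), class = "prediction_result")
  res
}

#' Permutation p-value for the nested SVR correlation
#'
#' The target is permuted `config$n_perm` times and the nested pipeline
#' re-run on each permutation with `config$perm_repeats` repeats (a
#' reduced-cost approximation recorded in the result);
#' `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)`.
#'
#' @param X,y as in [nested_cv_svr()].
#' @param config a [cv_config()]; `n_perm` must be >= 19 for a usable
#'   p resolution.
#' @param r_obs optional precomputed observed r (skips one full fit).
#' @return list with `p`, `r_obs` and the permutation null `r_perm`.
#' @export
svr_permutation_p <- function(X, y, config = cv_config(), r_obs = NULL) {
  if (config$n_perm < 19)
    stop("`n_perm` must be >= 19 (p-value resolution)")
  if (is.null(r_obs))
    r_obs <- nested_cv_svr(X, y, config, keep_weights = FALSE)$r
  pcfg <- config
  pcfg$repeats <- config$perm_repeats
  set.seed(config$seed + 77L)
  perm_seeds <- sample.int(.Machine$integer.max %/% 2L, config$n_perm)
  r_perm <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(perm_seeds[b])
    yp <- sample(y)
    cfg_b <- pcfg; cfg_b$seed <- perm_seeds[b]
    nested_cv_svr(X, yp, cfg_b, keep_weights = FALSE)$r
  }, numeric(1))
  list(p = (1 + sum(r_perm >= r_obs)) / (config$n_perm + 1),
       r_obs = r_obs, r_perm = r_perm,
       perm_repeats = pcfg$repeats)
}

#' Cross-validation-ratio feature importance
#'
#' Per repeat, the cross-validation ratio (CVR) of a feature is the
#' mean of its weights across outer folds divided by their standard
#' error; the overall mean (CVR-OM) averages the per-repeat CVRs.
#' Features whose fold weights have zero standard error are reported
#' with a capped sentinel value (`cap`, sign-matched) and flagged.
#'
#' @param result a `prediction_result` with stored weights.
#' @param cap sentinel magnitude for zero-SE features.
#' @return data.frame: `feature`, `cvr_om`, `rank` (by decreasing
#'   |CVR-OM|), `zero_se` flag.
#' @export
cvr_importance <- function(result, cap = 1e6) {
  if (is.null(result$weights))
    stop("result was fitted with keep_weights = FALSE; no stored weights")
  per_rep <- lapply(result$weights, function(wmat) {
    mu <- colMeans(wmat)
    se <- apply(wmat, 2, stats::sd) / sqrt(nrow(wmat))
    zero <- se == 0
    cvr <- ifelse(zero, sign(mu) * cap, mu / se)
    cvr[zero & mu == 0] <- 0
    list(cvr = cvr, zero = zero)
  })
  cvr_om <- rowMeans(vapply(per_rep, `[[`, numeric(length(result$feature_names)), "cvr"))
  zero_any <- Reduce(`|`, lapply(per_rep, `[[`, "zero"))
  out <- data.frame(feature = result$feature_names, cvr_om = cvr_om,
                    zero_se = zero_any, stringsAsFactors = FALSE)
  out$rank <- rank(-abs(out$cvr_om), ties.method = "first")
  out[order(out$rank), c("feature", "cvr_om", "rank", "zero_se")]
}

#' Null distribution from models on random feature subsets
#'
#' Fits the nested SVR on `n_models` random `k`-column subsets of a
#' feature superset and returns the distribution of held-out r, plus
#' the percentile of a supplied observed r within that null.
#'
#' @param X_all feature superset (more than `k` columns).
#' @param y target.
#' @param k subset size.
#' @param n_models number of random models (the conventional baseline
#'   uses 100).
#' @param config a [cv_config()].
#' @param observed_r optional observed r to locate in the null.
#' @param seed integer seed for subset draws.
#' @return list with `r_null` (length `n_models`) and `percentile`
#'   (NULL if `observed_r` missing).
#' @export
random_feature_baseline <- function(X_all, y, k, n_models = 100,
                                    config = cv_config(), observed_r = NULL,
                                    seed = 1) {
  X_all <- as.matrix(X_all)
  if (k >= ncol(X_all)) stop("`k` must be smaller than the number of columns")
  set.seed(seed)
  subsets <- replicate(n_models, sample.int(ncol(X_all), k), simplify = FALSE)
  r_null <- vapply(seq_len(n_models), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    nested_cv_svr(X_all[, subsets[[i]], drop = FALSE], y, cfg,
                  keep_weights = FALSE)$r
  }, numeric(1))
  list(r_null = r_null,
       percentile = if (is.null(observed_r)) NULL
                    else 100 * mean(r_null < observed_r))
}

#' Refit on all training data and apply to an external cohort
#'
#' The final model refits on the full training data with the cost
#' selected by a single inner cross-validation, then predicts the
#' external cohort; features are aligned by name and no retraining
#' happens on external data.
#'
#' @param X,y training data.
#' @param X_ext,y_ext external cohort (feature names must cover the
#'   training features).
#' @param config a [cv_config()].
#' @param labels_ext optional external group labels for the AUC.
#' @return list with `r`, `ci95`, `p_perm` (label-permutation p of the
#'   external correlation), `auc` and `predictions`.
#' @export
apply_external <- function(X, y, X_ext, y_ext, config = cv_config(),
                           labels_ext = NULL) {
  X <- as.matrix(X); X_ext <- as.matrix(X_ext)
  if (!is.null(colnames(X))) {
    missing <- setdiff(colnames(X), colnames(X_ext))
    if (length(missing))
      stop("external cohort lacks features: ",
           paste(utils::head(missing, 5), collapse = ", "))
    X_ext <- X_ext[, colnames(X), drop = FALSE]
  } else if (ncol(X_ext) != ncol(X)) {
    stop(sprintf("feature count mismatch: expected %d, got %d",
                 ncol(X), ncol(X_ext)))
  }
  set.seed(config$seed)
  sc <- train_scaler(X); Xs <- sc$apply(X)
  ysc <- c(mean(y), stats::sd(y)); ys <- (y - ysc[1]) / ysc[2]
  bestC <- config$C_grid[1]
  if (length(config$C_grid) > 1) {
    ifold <- sample(rep_len(seq_len(config$inner_folds), nrow(X)))
    perf <- vapply(config$C_grid, function(C) {
      mean(vapply(seq_len(config$inner_folds), function(j) {
        itr <- ifold != j
        m <- fit_linear_svr(Xs[itr, , drop = FALSE], ys[itr], C, config$epsilon)
        ph <- stats::predict(m, Xs[!itr, , drop = FALSE])
        if (stats::sd(ph) == 0) 0 else stats::cor(ph, ys[!itr])
      }, numeric(1)))
    }, numeric(1))
    bestC <- config$C_grid[which.max(perf)]
  }
  m <- fit_linear_svr(Xs, ys, bestC, config$epsilon)
  pred <- stats::predict(m, sc$apply(X_ext)) * ysc[2] + ysc[1]
  r <- stats::cor(pred, y_ext)
  set.seed(config$seed + 1L)
  r_perm <- vapply(seq_len(max(config$n_perm, 99)), function(b)
    stats::cor(pred, sample(y_ext)), numeric(1))
  list(r = r, ci95 = fisher_z_ci(r, length(y_ext)),
       p_perm = (1 + sum(r_perm >= r)) / (length(r_perm) + 1),
       auc = if (is.null(labels_ext)) NA_real_ else rank_auc(pred, labels_ext),
       predictions = pred, C = bestC)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("nested SVR: n = %d, r = %.3f [%.3f, %.3f]",
              length(x$observed), x$r, x$ci95[1], x$ci95[2]))
  if (!is.na(x$auc)) cat(sprintf(", AUC = %.3f", x$auc))
  if (!is.na(x$p_perm)) cat(sprintf(", p_perm = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}
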