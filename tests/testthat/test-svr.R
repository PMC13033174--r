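make_planted <- function(n = 60, p = 15, r_pop = 0.7, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%02d", 1:p)))
  signal <- X[, 1:3] %*% c(1, -1, 0.5)
  signal <- drop(scale(signal))
  y <- r_pop * signal + sqrt(1 - r_pop^2) * rnorm(n)
  list(X = X, y = drop(y))
}

test_that("nested SVR is deterministic under a fixed seed", {
  d <- make_planted()
  f1 <- nested_cv_svr(d$X, d$y, fast_cv(seed = 3))
  f2 <- nested_cv_svr(d$X, d$y, fast_cv(seed = 3))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$fold_assignments, f2$fold_assignments)
  f3 <- nested_cv_svr(d$X, d$y, fast_cv(seed = 4))
  expect_false(identical(f1$fold_assignments, f3$fold_assignments))
})

test_that("a planted linear signal is recovered at the expected strength", {
  rs <- vapply(1:5, function(s) {
    d <- make_planted(n = 80, seed = s)
    nested_cv_svr(d$X, d$y, fast_cv(seed = s))$r
  }, numeric(1))
  expect_gt(mean(rs), 0.5); expect_lt(mean(rs), 0.85)
})

test_that("null features give small held-out r and valid permutation p", {
  set.seed(6)
  d <- make_planted(n = 60, r_pop = 0)
  y_null <- rnorm(60)
  fit <- nested_cv_svr(d$X, y_null, fast_cv(seed = 5))
  expect_lt(abs(fit$r), 0.35)
  perm <- svr_permutation_p(d$X, y_null, fast_cv(seed = 5, n_perm = 19))
  expect_gt(perm$p, 0.05)
  expect_error(svr_permutation_p(d$X, y_null, fast_cv(n_perm = 10)),
               ">= 19")
})

test_that("input validation catches the documented degenerate cases", {
  d <- make_planted(n = 20)
  expect_error(nested_cv_svr(d$X, rep(1, 20), fast_cv()), "constant")
  expect_error(nested_cv_svr(d$X[1:8, ], d$y[1:8], fast_cv()), "too small")
  Xb <- d$X; Xb[1, 1] <- Inf
  expect_error(nested_cv_svr(Xb, d$y, fast_cv()), "finite")
})

test_that("CVR importance ranks planted features high and caps zero SE", {
  d <- make_planted(n = 100, seed = 9)
  fit <- nested_cv_svr(d$X, d$y,
                       cv_config(outer_folds = 5, inner_folds = 2,
                                 repeats = 2, C_grid = 1, n_perm = 19,
                                 seed = 2))
  imp <- cvr_importance(fit)
  expect_setequal(imp$feature, colnames(d$X))
  top3 <- imp$feature[1:3]
  expect_gte(length(intersect(top3, c("g01", "g02", "g03"))), 2)
  # zero-SE sentinel: identical weights across folds
  fake <- fit
  fake$weights <- list(matrix(rep(c(2, 0), each = 5), 5, 2))
  fake$feature_names <- c("a", "b")
  imp2 <- cvr_importance(fake)
  expect_true(imp2$zero_se[imp2$feature == "a"])
  expect_equal(abs(imp2$cvr_om[imp2$feature == "a"]), 1e6)
  expect_equal(imp2$cvr_om[imp2$feature == "b"], 0)
  fit2 <- nested_cv_svr(d$X, d$y, fast_cv(), keep_weights = FALSE)
  expect_error(cvr_importance(fit2), "keep_weights")
})

test_that("random-feature baseline returns the requested null and percentile", {
  d <- make_planted(n = 48, p = 12, seed = 10)
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
                   C_grid = 1, n_perm = 19, seed = 3)
  base <- random_feature_baseline(d$X, rnorm(48), k = 4, n_models = 25,
                                  config = cfg, observed_r = -0.9, seed = 4)
  expect_length(base$r_null, 25)
  expect_lt(base$percentile, 50)
  expect_lt(abs(median(base$r_null)), 0.4)
  expect_error(random_feature_baseline(d$X, d$y, k = 12, config = cfg),
               "smaller")
})

test_that("external application refits once and aligns features by name", {
  d <- make_planted(n = 60, seed = 11)
  ext <- make_planted(n = 50, seed = 12)
  out <- apply_external(d$X, d$y, ext$X, ext$y, fast_cv(seed = 6))
  expect_gt(out$r, 0.3)
  expect_lt(out$p_perm, 0.05)
  # training data as "external" reproduces the in-sample fit
  self <- apply_external(d$X, d$y, d$X, d$y, fast_cv(seed = 6))
  expect_gt(self$r, out$r)
  # shuffled labels give chance-level AUC on average
  set.seed(13)
  aucs <- replicate(30, {
    lab <- sample(rep(c("HC", "SCZ"), 25))
    rank_auc <- neurobridge:::rank_auc(ext$y, lab)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # feature mismatch is named
  expect_error(apply_external(d$X, d$y, ext$X[, 1:10], ext$y, fast_cv()),
               "lacks features")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(14)
  score <- rnorm(40)
  lab <- rep(c("HC", "SCZ"), 20)
  a1 <- neurobridge:::rank_auc(score, lab)
  a2 <- neurobridge:::rank_auc(exp(score) + 5, lab)
  expect_equal(a1, a2)
})

test_that("no subject is predicted by a model trained on itself", {
  d <- make_planted(n = 36, seed = 15)
  cfg <- fast_cv(seed = 7)
  fit <- nested_cv_svr(d$X, d$y, cfg)
  fold <- fit$fold_assignments[[1]]
  # prediction provenance: each subject held out exactly once per repeat
  expect_equal(sort(unique(fold)), 1:3)
  expect_true(all(tabulate(fold) >= 1))
})
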