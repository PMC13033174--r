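#' Soft-thresholding operator
#'
#' Maps each entry to `sign(w) * max(|w| - lam, 0)`, the proximal
#' operator of the L1 penalty used inside the sparse rank-1 updates.
#'
#' @param w numeric vector.
#' @param lam non-negative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(w, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0)
    stop("`lam` must be a single non-negative number")
  sign(w) * pmax(abs(w) - lam, 0)
}

# Soft-threshold w and L2-normalize so that the L1 norm of the result is
# <= budget c (penalized-matrix-decomposition style); c = 1 yields a
# single nonzero coordinate, c >= sqrt(length(w)) leaves w effectively
# unpenalized. The threshold solves ||s(w,lam)||_1 / ||s(w,lam)||_2 = c:
# with |w| sorted descending the ratio is a closed-form scalar function
# of lam on each segment between consecutive sorted magnitudes, so the
# active segment is located once and the root bisected with scalar
# arithmetic only (no per-step vector passes).
l1_unit <- function(w, c) {
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(w)
  u <- w / nw
  if (sum(abs(u)) <= c + 1e-12) return(u)
  a <- sort.int(abs(w), decreasing = TRUE, method = "quick")
  p <- length(a)
  A <- cumsum(a); Q <- cumsum(a^2)
  m_seq <- seq_len(p)
  lamb <- c(a[-1], 0)                       # lower edge of each segment
  den <- pmax(Q - 2 * lamb * A + m_seq * lamb^2, 1e-300)
  ratio_edge <- (A - m_seq * lamb) / sqrt(den)
  m <- which(ratio_edge >= c)[1]            # ratio grows as lam decreases
  lo <- lamb[m]; hi <- a[m]
  Am <- A[m]; Qm <- Q[m]
  # on the active segment the ratio equation is a quadratic in lam:
  # m (m - c^2) lam^2 - 2 Am (m - c^2) lam + (Am^2 - c^2 Qm) = 0
  mc <- m - c * c
  lam <- NA_real_
  if (abs(mc) > 1e-10) {
    disc <- (Am * mc)^2 - m * mc * (Am * Am - c * c * Qm)
    if (disc >= 0) {
      rts <- (Am * mc + c(-1, 1) * sqrt(disc)) / (m * mc)
      # valid branch has a positive numerator (lam <= Am / m); the other
      # root solves ratio = -c
      rts <- rts[rts >= lo - 1e-12 & rts <= hi + 1e-12 &
                 rts <= Am / m + 1e-12]
      if (length(rts)) lam <- min(max(min(rts), lo), hi)
    }
  }
  if (is.na(lam)) {                          # degenerate segment: bisect
    for (i in 1:50) {
      lam <- (lo + hi) / 2
      num <- Am - m * lam
      dd <- sqrt(max(Qm - 2 * lam * Am + m * lam^2, 1e-300))
      if (num / dd > c) lo <- lam else hi <- lam
    }
    lam <- hi
  }
  su <- soft_threshold(w, lam)
  # when the root sits on a segment edge, finite precision can leave a
  # ghost coordinate ~1e-16 of the leader; prune below root precision
  su[abs(su) < 1e-9 * max(abs(su))] <- 0
  ns <- sqrt(sum(su^2))
  if (ns == 0) {
    # exact ties at the maximum magnitude can make the budget
    # unattainable (the ratio jumps over c); keep the tied leaders,
    # the sparsest attainable support
    su <- ifelse(abs(w) >= a[1], w, 0)
    ns <- sqrt(sum(su^2))
  }
  su / ns
}

#' Sparse rank-1 decomposition of a cross-covariance matrix
#'
#' Alternating soft-thresholded power iterations extracting a sparse
#' singular-vector pair of `S`, with L1 budgets in the
#' penalized-matrix-decomposition convention: `c_u` (`c_v`) bounds the
#' L1 norm of the unit-L2 weight vector, so 1 gives a single nonzero
#' coordinate and `sqrt(nrow(S))` (`sqrt(ncol(S))`) removes the
#' penalty.
#'
#' @param S numeric matrix (rows index the X block, columns the Y block).
#' @param c_u,c_v L1 budgets, each >= 1.
#' @param tol convergence tolerance on successive weight changes.
#' @param max_iter maximum number of alternations.
#' @return list with unit vectors `u`, `v`, `singular_value`
#'   (`t(u) S v`, >= 0), `iterations` and `converged`.
#' @export
sparse_rank1 <- function(S, c_u, c_v, tol = 1e-8, max_iter = 100) {
  if (!is.matrix(S) || anyNA(S) || any(!is.finite(S)))
    stop("`S` must be a finite numeric matrix")
  if (all(S == 0)) stop("`S` is identically zero: no component to extract")
  if (c_u < 1 || c_v < 1) stop("L1 budgets must be >= 1")
  # initialize v from the dominant column of S
  j0 <- which.max(colSums(S^2))
  v <- rep(0, ncol(S)); v[j0] <- 1
  u <- rep(0, nrow(S))
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    u_new <- l1_unit(drop(S %*% v), c_u)
    v_new <- l1_unit(drop(crossprod(S, u_new)), c_v)
    if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new; converged <- TRUE; break
    }
    u <- u_new; v <- v_new
  }
  d <- drop(t(u) %*% S %*% v)
  if (d < 0) { u <- -u; d <- -d }
  list(u = u, v = v, singular_value = d, iterations = it, converged = converged)
}

# z-scale columns; errors on constant columns naming the offender
scale_block <- function(M, block) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  bad <- which(sd == 0 | !is.finite(sd))
  if (length(bad))
    stop(sprintf("constant column(s) in %s block: %s", block,
                 paste(utils::head(colnames(M)[bad] %||% bad, 5), collapse = ", ")))
  list(x = sweep(sweep(M, 2, mu), 2, sd, "/"), mean = mu, sd = sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation significance of a sparse rank-1 component
#'
#' Rows of `Y` are permuted (X fixed), the sparse rank-1 fit is re-run
#' on each permuted cross-covariance, and the p-value is
#' `(1 + #(sv_perm >= observed)) / (n_perm + 1)`.
#'
#' @param X,Y column-scaled blocks sharing the subject axis.
#' @param c_u,c_v L1 budgets passed to [sparse_rank1()].
#' @param observed_sv observed singular value to test.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return permutation p-value in (0, 1].
#' @export
spls_permutation_p <- function(X, Y, c_u, c_v, observed_sv, n_perm, seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  n <- nrow(X)
  set.seed(seed)
  hits <- 0
  for (b in seq_len(n_perm)) {
    Sp <- crossprod(X, Y[sample.int(n), , drop = FALSE]) / (n - 1)
    svp <- sparse_rank1(Sp, c_u, c_v)$singular_value
    if (svp >= observed_sv) hits <- hits + 1
  }
  (1 + hits) / (n_perm + 1)
}

#' Select L1 budgets by cross-validated score correlation
#'
#' Grid search over `(c_u, c_v)` scoring each pair by the mean held-out
#' covariance between the X-side and Y-side scores over `folds`
#' cross-validation folds, then applying a one-standard-error rule:
#' among all pairs whose mean score is within one standard error of
#' the best, the sparsest (smallest `c_u + c_v`) is returned.
#' Covariance (not correlation) is the selection signal: spreading
#' unit-norm weights onto signal-free columns dilutes the held-out
#' covariance, whereas the held-out correlation is nearly flat in the
#' budget, so covariance identifies the planted support.
#'
#' @param X,Y column-scaled blocks.
#' @param grid_u,grid_v candidate budgets; defaults are 8 values
#'   log-spaced over `[1, sqrt(p)]`.
#' @param folds number of folds.
#' @param seed integer seed for the fold split.
#' @return list with `c_u`, `c_v` and the CV score table.
#' @export
select_sparsity <- function(X, Y, grid_u = NULL, grid_v = NULL,
                            folds = 5, seed = 1) {
  n <- nrow(X)
  default_grid <- function(p) unique(pmax(1, exp(seq(0, log(sqrt(p)), length.out = 8))))
  grid_u <- grid_u %||% default_grid(ncol(X))
  grid_v <- grid_v %||% default_grid(ncol(Y))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  tab <- expand.grid(c_u = grid_u, c_v = grid_v)
  tab$score <- NA_real_; tab$se <- NA_real_
  folds_S <- lapply(seq_len(folds), function(k) {
    tr <- fold != k
    crossprod(X[tr, , drop = FALSE], Y[tr, , drop = FALSE]) / (sum(tr) - 1)
  })
  for (i in seq_len(nrow(tab))) {
    cc <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      Sk <- folds_S[[k]]
      # looser tolerance: CV only ranks budgets, the final fit is exact
      fit <- sparse_rank1(Sk, tab$c_u[i], tab$c_v[i], tol = 1e-5)
      sx <- X[!tr, , drop = FALSE] %*% fit$u
      sy <- Y[!tr, , drop = FALSE] %*% fit$v
      cc[k] <- mean(sx * sy) - mean(sx) * mean(sy)
    }
    tab$score[i] <- mean(cc)
    tab$se[i] <- stats::sd(cc) / sqrt(folds)
  }
  ibest <- which.max(tab$score)
  thr <- tab$score[ibest] - tab$se[ibest]
  cand <- tab[tab$score >= thr, ]
  cand <- cand[order(cand$c_u + cand$c_v, cand$c_v), ]
  list(c_u = cand$c_u[1], c_v = cand$c_v[1], cv_table = tab)
}

# Universal-threshold screening refinement of a budgeted sparse pair.
# With z-scaled blocks, the correlation of a signal-free column with
# the opposite-block score is approximately N(0, 1/n), so coordinates
# are kept when |cor| exceeds the universal threshold
# sqrt(2 log(dim) / n); the pair is then refit unpenalized (exact SVD)
# on the screened support and the screening iterated until the support
# is stable. Soft-thresholding alone retains a fringe of lucky-noise
# coordinates near the L1 knee; the screening pass removes exactly the
# coordinates compatible with the null scale.
screen_refit <- function(X, Y, u, v, max_pass = 4) {
  n <- nrow(X)
  S <- crossprod(X, Y) / (n - 1)
  tau_u <- sqrt(2 * log(ncol(X)) / n)
  tau_v <- sqrt(2 * log(ncol(Y)) / n)
  for (pass in seq_len(max_pass)) {
    sy <- drop(Y %*% v); sx <- drop(X %*% u)
    if (stats::sd(sy) == 0 || stats::sd(sx) == 0) return(NULL)
    cu <- drop(stats::cor(X, sy)); cv <- drop(stats::cor(Y, sx))
    keep_u <- which(abs(cu) > tau_u); keep_v <- which(abs(cv) > tau_v)
    if (!length(keep_u) || !length(keep_v)) return(NULL)
    sv <- svd(S[keep_u, keep_v, drop = FALSE], nu = 1, nv = 1)
    u_new <- numeric(ncol(X)); v_new <- numeric(ncol(Y))
    u_new[keep_u] <- sv$u[, 1]; v_new[keep_v] <- sv$v[, 1]
    if (identical(which(u_new != 0), which(u != 0)) &&
        identical(which(v_new != 0), which(v != 0))) {
      u <- u_new; v <- v_new
      break
    }
    u <- u_new; v <- v_new
  }
  d <- drop(t(u) %*% S %*% v)
  if (d < 0) { u <- -u; v <- -v; d <- -d }
  list(u = u, v = v, singular_value = d)
}

#' Fit a sparse partial least squares model
#'
#' Extracts sparse latent weight pairs from the cross-covariance of a
#' phenotype block `X` and a brain (GMV) block `Y`. Columns are
#' z-scaled (scaling stored for projection), components are extracted
#' in order from `S = t(X) Y / (n - 1)`, each followed by a permutation
#' test; extraction stops after the first component with
#' `p_perm > alpha`. Projection deflation (`X <- X - (Xu)u'`,
#' `Y <- Y - (Yv)v'`) is applied between components, which makes
#' successive training score vectors orthogonal.
#'
#' By default each component's support is refined by universal-threshold
#' screening (coordinates kept when their correlation with the
#' opposite-block score exceeds the null scale `sqrt(2 log(dim) / n)`)
#' and the weights refit unpenalized on the screened support; the
#' permutation test is always run on the budgeted soft-threshold fit so
#' its null and observed statistics are exchangeable.
#'
#' @param X phenotype matrix (subjects x features).
#' @param Y GMV matrix (subjects x voxels).
#' @param c_u,c_v L1 budgets; `NULL` selects them per component via
#'   [select_sparsity()].
#' @param n_components maximum number of components.
#' @param n_perm permutations per component (values below 100 are
#'   allowed but recorded as a warning in the model).
#' @param alpha significance level of the stopping rule.
#' @param refine apply the screening refinement pass.
#' @param seed integer seed.
#' @return an object of class `spls_model`.
#' @export
fit_spls <- function(X, Y, c_u = NULL, c_v = NULL, n_components = 2,
                     n_perm = 1000, alpha = 0.05, refine = TRUE,
                     seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("`X` and `Y` must share the subject axis")
  if (nrow(X) < 10) stop("need at least 10 subjects")
  warn <- character(0)
  if (n_perm < 100)
    warn <- c(warn, sprintf("n_perm = %d is below 100; permutation p-values are coarse", n_perm))
  sx <- scale_block(X, "phenotype"); sy <- scale_block(Y, "GMV")
  Xc <- sx$x; Yc <- sy$x
  n <- nrow(Xc)
  comps <- list()
  for (k in seq_len(n_components)) {
    S <- crossprod(Xc, Yc) / (n - 1)
    if (all(abs(S) < 1e-12)) break
    if (is.null(c_u) || is.null(c_v)) {
      sel <- select_sparsity(Xc, Yc, seed = seed + 1000L * k)
      cu_k <- c_u %||% sel$c_u; cv_k <- c_v %||% sel$c_v
    } else {
      cu_k <- c_u; cv_k <- c_v
    }
    fit <- sparse_rank1(S, cu_k, cv_k)
    p <- spls_permutation_p(Xc, Yc, cu_k, cv_k, fit$singular_value,
                            n_perm = n_perm, seed = seed + k)
    cleaned <- FALSE
    if (refine) {
      sr <- screen_refit(Xc, Yc, fit$u, fit$v)
      if (!is.null(sr)) {
        fit$u <- sr$u; fit$v <- sr$v
        fit$singular_value <- sr$singular_value
        cleaned <- TRUE
      }
    }
    comps[[k]] <- list(u = fit$u, v = fit$v,
                       singular_value = fit$singular_value,
                       p_perm = p, c_u = cu_k, c_v = cv_k,
                       converged = fit$converged, refined = cleaned)
    if (p > alpha) break
    tu <- Xc %*% fit$u; tv <- Yc %*% fit$v
    Xc <- Xc - tu %*% t(fit$u)
    Yc <- Yc - tv %*% t(fit$v)
  }
  structure(list(components = comps,
                 scaling = list(x_mean = sx$mean, x_sd = sx$sd,
                                y_mean = sy$mean, y_sd = sy$sd),
                 n_perm = n_perm, alpha = alpha, seed = seed,
                 warnings = warn),
            class = "spls_model")
}

#' Project new data onto a fitted SPLS component
#'
#' New blocks are scaled with the stored training scaling and scored
#' against the requested component's weight pair. Projecting the
#' training data reproduces the in-sample scores.
#'
#' @param model an `spls_model`.
#' @param X_new,Y_new blocks with the training feature counts.
#' @param component_index which component to score.
#' @return data.frame with `cognition_score`, `brain_score` and
#'   `component_index`.
#' @export
project_spls <- function(model, X_new, Y_new, component_index = 1) {
  stopifnot(inherits(model, "spls_model"))
  if (component_index > length(model$components))
    stop("model has no component ", component_index)
  cmp <- model$components[[component_index]]
  X_new <- as.matrix(X_new); Y_new <- as.matrix(Y_new)
  if (ncol(X_new) != length(model$scaling$x_mean))
    stop(sprintf("phenotype feature mismatch: expected %d, got %d",
                 length(model$scaling$x_mean), ncol(X_new)))
  if (ncol(Y_new) != length(model$scaling$y_mean))
    stop(sprintf("GMV feature mismatch: expected %d, got %d",
                 length(model$scaling$y_mean), ncol(Y_new)))
  Xs <- sweep(sweep(X_new, 2, model$scaling$x_mean), 2, model$scaling$x_sd, "/")
  Ys <- sweep(sweep(Y_new, 2, model$scaling$y_mean), 2, model$scaling$y_sd, "/")
  data.frame(cognition_score = drop(Xs %*% cmp$u),
             brain_score = drop(Ys %*% cmp$v),
             component_index = component_index)
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("SPLS model: %d component(s)\n", length(x$components)))
  for (k in seq_along(x$components)) {
    cmp <- x$components[[k]]
    cat(sprintf("  [%d] sv = %.4f, p_perm = %.4g, |u|_0 = %d, |v|_0 = %d\n",
                k, cmp$singular_value, cmp$p_perm,
                sum(cmp$u != 0), sum(cmp$v != 0)))
  }
  invisible(x)
}
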