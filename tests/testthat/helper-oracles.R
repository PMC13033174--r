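# brute-force oracles used across test files

# two-sided Mann-Whitney p by explicit enumeration over all splits,
# written independently of the package implementation: recomputes the
# rank sum for every split from the pooled sorted values
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  n1 <- length(x); N <- length(pooled)
  mu <- n1 * (length(y)) / 2
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(N, n1)
  stat <- apply(splits, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(stat - mu) >= abs(u_obs - mu) - 1e-12)
}

# step-up BH by the definition: q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(sapply(i:m, function(j) m * p[o[j]] / j), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# tiny cohort config used across files: fast but non-degenerate
tiny_cohort <- function(seed = 1, n_hc = 30, n_scz = 30, psd = FALSE) {
  generate_cohort(cohort_config(
    n_hc = n_hc, n_scz = n_scz, p_pheno = 12, q_voxels = 30,
    n_genes = 20,
    latent_specs = list(
      latent_spec(driver = "age", u_support = 1:3, v_support = 1:5,
                  score_correlation = 0.7, driver_strength = 0.8),
      latent_spec(driver = "diagnosis", u_support = 4:7, v_support = 6:12,
                  score_correlation = 0.57)),
    include_psd = psd, seed = seed))
}

fast_cv <- function(seed = 1, n_perm = 19) {
  cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
            C_grid = c(0.25, 4), epsilon = 0.1, n_perm = n_perm,
            seed = seed)
}
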