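test_that("identical configurations produce identical cohorts", {
  c1 <- tiny_cohort(seed = 77)
  c2 <- tiny_cohort(seed = 77)
  expect_identical(c1, c2)
  c3 <- tiny_cohort(seed = 78)
  expect_false(identical(c1$pheno, c3$pheno))
})

test_that("group sizes and label counts follow the configuration", {
  ch <- generate_cohort(cohort_config(n_hc = 21, n_scz = 21, p_pheno = 8,
                                      q_voxels = 20, n_genes = 10,
                                      latent_specs = list(
                                        latent_spec("diagnosis", 1:3, 1:4)),
                                      include_psd = FALSE, seed = 1))
  expect_length(ch$labels, 42)
  expect_equal(as.vector(table(ch$labels)), c(21L, 21L))
})

test_that("configuration validation names the offending field", {
  expect_error(cohort_config(n_hc = 1), "n_hc")
  expect_error(cohort_config(freq_grid = c(1, 0.5)), "freq_grid")
  expect_error(cohort_config(electrodes = c("F8", "F8")), "electrodes")
  expect_error(cohort_config(frac_informative = 1.5), "frac_informative")
  expect_error(cohort_config(latent_specs = list(
    latent_spec("age", 1:3, 1:4), latent_spec("diagnosis", 3:5, 6:8))),
    "disjoint")
  expect_error(latent_spec("age", integer(0), 1:3), "non-empty")
  expect_error(latent_spec("age", 1:3, 1:3, score_correlation = 1.2),
               "score_correlation")
  expect_error(synapse_gen_params(mean_hc = -1), "mean_hc")
  expect_error(synapse_gen_params(reduction_pct = 120), "reduction_pct")
})

test_that("synapse generator shapes and null case behave", {
  d <- generate_synapse_densities(
    synapse_gen_params(replicates_per_subject = 3), n_hc = 2, n_scz = 2,
    seed = 4)
  expect_equal(nrow(d$replicates), 12)
  expect_equal(nrow(d$subjects), 4)
  expect_true(all(d$replicates$syn1_density_per_um > 0))
  expect_equal(mean(d$subjects$rho[d$subjects$group == "HC"]), 1)
  # zero reduction: group means differ only by sampling noise
  set.seed(99)
  pv <- replicate(40, {
    dd <- generate_synapse_densities(
      synapse_gen_params(reduction_pct = 0), 25, 25,
      seed = sample.int(1e6, 1))
    t.test(mean_density ~ group, dd$subjects)$p.value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("large cohorts recover the configured density reduction", {
  d <- generate_synapse_densities(n_hc = 2000, n_scz = 2000, seed = 21)
  m <- tapply(d$subjects$mean_density, d$subjects$group, mean)
  red <- 100 * (m[["HC"]] - m[["SCZ"]]) / m[["HC"]]
  expect_lt(abs(red - 12.4), 0.5)
})

test_that("planted block-score correlation hits its target at scale", {
  cfg <- cohort_config(n_hc = 2500, n_scz = 2500, include_psd = FALSE,
                       seed = 31)
  ch <- generate_cohort(cfg)
  tr <- ch$truth$signatures[[2]]   # diagnosis-driven, target 0.57
  r <- cor(tr$score_pheno, tr$score_gmv)
  expect_gt(r, 0.54); expect_lt(r, 0.60)
  # and the age-driven signature tracks age, not diagnosis
  tr1 <- ch$truth$signatures[[1]]
  expect_gt(abs(cor(tr1$latent, ch$age)),
            abs(cor(tr1$latent, as.numeric(ch$labels == "SCZ"))))
})

test_that("negative support signs flip the planted loadings", {
  cfg <- cohort_config(
    n_hc = 300, n_scz = 300, p_pheno = 10, q_voxels = 12,
    latent_specs = list(latent_spec("diagnosis", u_support = 1:4,
                                    v_support = 1:4,
                                    u_signs = rep(-1, 4))),
    include_psd = FALSE, seed = 8)
  ch <- generate_cohort(cfg)
  tr <- ch$truth$signatures[[1]]
  loads <- cor(ch$pheno[, 1:4], tr$t_x)
  expect_true(all(loads < 0))
})

test_that("expression block has the right shape and informative set", {
  ch <- tiny_cohort(seed = 5)
  expect_equal(ncol(ch$expression), 20)
  ex <- generate_expression(rnorm(50), rep(c("HC", "SCZ"), 25),
                            n_genes = 310, frac_informative = 0,
                            seed = 2)
  expect_equal(ncol(ex$expression), 310)
  expect_length(ex$informative, 0)
  expect_error(generate_expression(rnorm(10), rep("HC", 10),
                                   frac_informative = 2), "frac_informative")
})

test_that("empirical PSD degenerates correctly at the coupling extremes", {
  syn <- generate_synapse_densities(n_hc = 3, n_scz = 3, seed = 6)
  coupling <- c(F8 = 1, C3 = 0)
  pm <- generate_empirical_psd(syn$subjects, electrode_coupling = coupling,
                               meas_noise_sd = 0, seed = 7)
  base <- cmc_default_params()
  for (i in 1:6) {
    direct <- transfer_psd(
      personalize_params(base, syn$subjects$rho[i], "EXC_ONLY"))
    expect_equal(pm$values[i, 1, ], unname(direct), tolerance = 1e-12)
  }
  # coupling 0: all subjects share the background exactly
  expect_equal(pm$values[1, 2, ], pm$values[6, 2, ], tolerance = 1e-12)
})

test_that("cohort round-trips through its directory serialization", {
  ch <- tiny_cohort(seed = 12, n_hc = 5, n_scz = 5, psd = TRUE)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pheno.tsv", "gmv.tsv", "expression.tsv", "synapse_density.tsv",
      "psd.tsv", "truth.json", "config.yaml")))))
  back <- read_cohort(dir)
  expect_equal(unname(back$pheno), unname(ch$pheno), tolerance = 1e-12)
  expect_equal(unname(back$gmv), unname(ch$gmv), tolerance = 1e-12)
  expect_equal(back$labels, ch$labels)
  expect_equal(back$psd$values, ch$psd$values, tolerance = 1e-12)
  expect_equal(back$synapse$subjects$rho, ch$synapse$subjects$rho,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
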