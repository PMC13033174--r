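test_that("packaged default parameters satisfy their contract", {
  p <- cmc_default_params()
  st <- cmc_stability(p)
  expect_true(st$stable)
  psd <- transfer_psd(p)
  fr <- seq(1, 70, by = 0.5)
  pk <- fr[which.max(psd)]
  expect_gte(pk, 8); expect_lte(pk, 13)
  # no competing peak away from the dominant one
  locmax <- which(diff(sign(diff(psd))) == -2) + 1
  big <- locmax[psd[locmax] > 0.6 * max(psd)]
  if (length(big)) expect_true(all(abs(fr[big] - pk) <= 3))
  # connection classes match the source population classes
  cn <- p$connections
  expect_true(all(cn$class[cn$source %in% c("ss", "sp", "dp")] == "excitatory"))
  expect_true(all(cn$class[cn$source == "ii"] == "inhibitory"))
})

test_that("parameter validation catches class violations", {
  p <- cmc_default_params()
  bad <- p$connections
  bad$class[bad$source == "ii"][1] <- "excitatory"
  expect_error(cmc_params(p$kappa, p$H, bad), "class")
  expect_error(cmc_params(c(ss = -1, sp = 1, ii = 1, dp = 1), p$H,
                          p$connections), "kappa")
})

test_that("fixed point is exact at zero gains and tight at defaults", {
  p <- cmc_default_params()
  p0 <- p; p0$connections$g[] <- 0
  expect_identical(unname(cmc_fixed_point(p0)), rep(0, 4))
  v <- cmc_fixed_point(p)
  W <- neurobridge:::cmc_weight_matrix(p)
  resid <- v - (p$H / p$kappa) * drop(W %*% (1 / (1 + exp(-p$r * v)) - 0.5))
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("gain stress either converges or raises the documented error", {
  p <- cmc_default_params()
  exc <- p$connections$class == "excitatory"
  p$connections$g[exc] <- p$connections$g[exc] * 2
  out <- tryCatch(transfer_psd(p), error = function(e) conditionMessage(e))
  expect_true(is.numeric(out) || grepl("stability error", out))
})

test_that("spectrum is linear in the innovation variance", {
  p <- cmc_default_params()
  base <- transfer_psd(p)
  p2 <- p
  p2$noise$a_white <- p$noise$a_white * 3.7
  p2$noise$a_pink <- p$noise$a_pink * 3.7
  expect_equal(transfer_psd(p2), base * 3.7, tolerance = 1e-12)
})

test_that("spectrum decays monotonically beyond the highest resonance", {
  p <- cmc_default_params()
  fr <- seq(1, 70, by = 0.5)
  psd <- transfer_psd(p, fr)
  locmax <- which(diff(sign(diff(psd))) == -2) + 1
  last <- if (length(locmax)) max(locmax) else 1
  tail_part <- psd[seq(last, length(psd))]
  expect_true(all(diff(tail_part) < 0))
})

test_that("personalization is multiplicative, regime-local and validated", {
  p <- cmc_default_params()
  expect_identical(personalize_params(p, 1, "ALL"), p)
  q <- personalize_params(p, 0.876, "EXC_ONLY")
  exc <- p$connections$class == "excitatory"
  expect_equal(q$connections$g[exc], p$connections$g[exc] * 0.876)
  expect_identical(q$connections$g[!exc], p$connections$g[!exc])
  expect_identical(q$kappa, p$kappa); expect_identical(q$H, p$H)
  ab <- personalize_params(personalize_params(p, 0.9, "ALL"), 0.8, "ALL")
  expect_equal(ab$connections$g, personalize_params(p, 0.72, "ALL")$connections$g)
  expect_error(personalize_params(p, -1), "positive")
  # named excitatory subset
  sub <- personalize_params(p, 0.5, c("ss->sp"))
  expect_equal(sub$connections$g[1], p$connections$g[1] * 0.5)
  expect_identical(sub$connections$g[-1], p$connections$g[-1])
  expect_error(personalize_params(p, 0.5, c("ii->ss")), "excitatory")
})

test_that("gamma and theta relative power respond monotonically to density", {
  p <- cmc_default_params()
  rhos <- seq(0.7, 1, by = 0.05)
  th <- ga <- numeric(length(rhos))
  for (i in seq_along(rhos)) {
    sim <- simulate_cohort_spectra(
      data.frame(subject_id = "s", group = "HC", rho = rhos[i]), "EXC_ONLY", p)
    bp <- sim$band_powers
    th[i] <- bp$rel_power[bp$band == "theta"]
    ga[i] <- sum(bp$rel_power[bp$band %in% c("gamma1", "gamma2")])
  }
  expect_true(all(diff(ga) >= 0))
  expect_true(all(diff(th) <= 0))
})

test_that("cohort simulation flags unstable subjects without aborting", {
  p <- cmc_default_params()
  d <- data.frame(subject_id = c("a", "b", "c"), group = "HC",
                  rho = c(1, 0.9, 60))
  sim <- simulate_cohort_spectra(d, "EXC_ONLY", p)
  if (length(sim$failed)) {
    expect_true("c" %in% sim$failed)
    expect_setdiff_ok <- setdiff(c("a", "b"), sim$spectra$subject_ids)
    expect_length(expect_setdiff_ok, 0)
  }
  base <- transfer_psd(p)
  same <- simulate_cohort_spectra(
    data.frame(subject_id = c("a", "b"), group = "HC", rho = c(1, 1)),
    "EXC_ONLY", p)
  expect_equal(same$spectra$values[1, 1, ], unname(base), tolerance = 1e-12)
  expect_equal(same$spectra$values[2, 1, ], unname(base), tolerance = 1e-12)
  expect_error(simulate_cohort_spectra(d[0, ], "EXC_ONLY", p), "empty")
})

test_that("compare_regimes validates inputs and reports one row per regime", {
  syn <- generate_synapse_densities(n_hc = 12, n_scz = 12, seed = 3)
  v <- compare_regimes(syn$subjects, regimes = c("EXC_ONLY", "INH_ONLY"))
  expect_equal(nrow(v), 2)
  expect_true(all(c("q_theta", "q_gamma1", "dir_gamma2") %in% names(v)))
  expect_error(compare_regimes(syn$subjects, regimes = "ALL"), "2 regimes")
  expect_error(compare_regimes(syn$subjects,
                               empirical_pattern = c(theta = 0, gamma1 = 0)),
               "degenerate")
  single <- syn$subjects[1, , drop = FALSE]
  expect_error(suppressWarnings(
    compare_regimes(single, regimes = c("ALL", "EXC_ONLY"))))
})

test_that("predicted-vs-empirical correlation is exact on identical inputs", {
  syn <- generate_synapse_densities(n_hc = 6, n_scz = 6, seed = 13)
  sim <- simulate_cohort_spectra(syn$subjects)
  emp <- sim$band_powers
  emp$electrode <- "F8"
  out <- predicted_vs_empirical(sim$band_powers, emp, band = "gamma1")
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_error(predicted_vs_empirical(sim$band_powers[1:4, ], emp),
               "overlap")
})

test_that("parameters serialize to YAML and back losslessly", {
  p <- cmc_default_params()
  f <- tempfile(fileext = ".yaml")
  write_cmc_params(p, f)
  q <- read_cmc_params(f)
  expect_equal(q$kappa, p$kappa, tolerance = 1e-12)
  expect_equal(q$connections$g, p$connections$g, tolerance = 1e-12)
  expect_equal(q$noise, p$noise)
  unlink(f)
})
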