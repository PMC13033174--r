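flat_psd <- function(height = 2, nsub = 1, electrodes = "Cz") {
  fr <- seq(1, 70, by = 0.5)
  vals <- array(height, dim = c(nsub, length(electrodes), length(fr)))
  psd_matrix(vals, fr, electrodes,
             labels = rep(c("HC", "SCZ"), length.out = nsub))
}

test_that("band powers of a flat spectrum are the band widths", {
  bp <- band_power(flat_psd(2))
  expect_equal(bp$abs_power[bp$band == "delta"], 6)        # 2 x 3 Hz
  expect_equal(bp$rel_power[bp$band == "delta"], 3 / 69)
  expect_equal(bp$rel_power[bp$band == "beta"], 18 / 69)
  expect_equal(sum(bp$abs_power), 2 * 69)
})

test_that("a spectrum supported only in 30-50 Hz is pure gamma1", {
  fr <- seq(1, 70, by = 0.5)
  v <- array(0, dim = c(1, 1, length(fr)))
  v[1, 1, fr >= 30 & fr <= 50] <- 1
  # zero the edges so no mass leaks into beta/gamma2 trapezoids
  v[1, 1, fr == 30] <- 0; v[1, 1, fr == 50] <- 0
  bp <- band_power(psd_matrix(v, fr, "Cz"))
  expect_equal(bp$rel_power[bp$band == "gamma1"], 1)
  expect_equal(sum(bp$rel_power[bp$band != "gamma1"]), 0)
})

test_that("relative powers sum to one and scale invariance holds", {
  set.seed(8)
  fr <- seq(1, 70, by = 0.5)
  vals <- array(rexp(5 * 3 * length(fr)), dim = c(5, 3, length(fr)))
  p1 <- psd_matrix(vals, fr, c("F8", "C3", "C4"))
  bp1 <- band_power(p1)
  sums <- tapply(bp1$rel_power, paste(bp1$subject_id, bp1$electrode), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  p2 <- psd_matrix(vals * 7.3, fr, c("F8", "C3", "C4"))
  bp2 <- band_power(p2)
  expect_equal(bp2$abs_power, bp1$abs_power * 7.3)
  expect_equal(bp2$rel_power, bp1$rel_power, tolerance = 1e-12)
})

test_that("welch PSD concentrates a 10 Hz sinusoid in alpha with Parseval", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  psd <- welch_psd(x, fs)
  bp <- band_power(psd)
  expect_gt(bp$rel_power[bp$band == "alpha"], 0.99)
  total <- sum(bp$abs_power)
  expect_lt(abs(total - 0.5) / 0.5, 0.05)   # sinusoid variance 1/2
})

test_that("welch PSD of white noise integrates to its variance", {
  set.seed(9)
  fs <- 400
  x <- rnorm(fs * 120, sd = 2)
  bp <- band_power(welch_psd(x, fs))
  # variance in 1-70 Hz out of the 0-200 Hz one-sided support
  expected <- 4 * (70 - 1) / (fs / 2)
  expect_lt(abs(sum(bp$abs_power) - expected) / expected, 0.05)
})

test_that("welch PSD handles degenerate inputs", {
  expect_equal(max(welch_psd(rep(0, 1000), 250)$values), 0)
  expect_error(welch_psd(rnorm(100), 100), "Nyquist|exceed")
  expect_error(welch_psd(rnorm(100), 250, window_s = 2), "shorter")
})

test_that("z-scoring against a reference behaves affinely", {
  set.seed(10)
  fr <- seq(1, 70, by = 0.5)
  vals <- array(rexp(20 * 2 * length(fr)), dim = c(20, 2, length(fr)))
  pm <- psd_matrix(vals, fr, c("F8", "C3"),
                   labels = rep(c("HC", "SCZ"), each = 10))
  bp <- band_power(pm)
  z <- zscore_band_features(bp)
  key <- paste(z$electrode, z$band)
  expect_true(all(abs(tapply(z$rel_power, key, mean)) < 1e-12))
  expect_true(all(abs(tapply(z$rel_power, key, sd) - 1) < 1e-12))
  expect_error(zscore_band_features(bp, reference = bp$subject_id[1]),
               "at least 2")
  # shifting one group by delta moves its z-mean by delta / sd_ref
  ref_ids <- unique(bp$subject_id)[1:10]
  shifted <- bp
  sel <- !(shifted$subject_id %in% ref_ids) & shifted$band == "alpha" &
    shifted$electrode == "F8"
  sd_ref <- sd(bp$rel_power[bp$subject_id %in% ref_ids & bp$band == "alpha" &
                              bp$electrode == "F8"])
  shifted$rel_power[sel] <- shifted$rel_power[sel] + 0.1
  z2 <- zscore_band_features(shifted, reference = ref_ids)
  z1 <- zscore_band_features(bp, reference = ref_ids)
  d <- mean(z2$rel_power[sel]) - mean(z1$rel_power[sel])
  expect_equal(d, 0.1 / sd_ref, tolerance = 1e-10)
})

test_that("group comparison reproduces the exact enumeration and FDR family", {
  fr <- seq(1, 70, by = 0.5)
  vals <- array(1, dim = c(6, 1, length(fr)))
  # plant a separated alpha difference between 3 vs 3 subjects
  for (i in 4:6) vals[i, 1, fr >= 8 & fr < 12] <- 1 + i
  pm <- psd_matrix(vals, fr, "F8", labels = rep(c("HC", "SCZ"), each = 3))
  st <- group_band_comparison(band_power(pm), measure = "abs_power")
  alpha_row <- st[st$band == "alpha", ]
  expect_equal(alpha_row$p, 0.1)      # 3 vs 3 fully separated, two-sided
  expect_equal(alpha_row$direction, 1)
  expect_equal(nrow(st), 6)
  expect_true(all(st$q >= st$p - 1e-12))
})

test_that("per-subject labels give the same answer as the group column", {
  syn <- generate_synapse_densities(n_hc = 10, n_scz = 10, seed = 9)
  bp <- band_power(generate_empirical_psd(syn$subjects, seed = 9))
  a <- group_band_comparison(bp)
  b <- group_band_comparison(bp, labels = syn$subjects$group)
  expect_equal(a, b)
  expect_error(group_band_comparison(bp, labels = rep("HC", 3)),
               "one entry per")
})

test_that("planted theta-up / gamma-down contrast is detected at scale", {
  set.seed(123)
  syn <- generate_synapse_densities(n_hc = 40, n_scz = 40, seed = 123)
  pm <- generate_empirical_psd(syn$subjects, meas_noise_sd = 0.15, seed = 5)
  st <- group_band_comparison(band_power(pm))
  theta_f8 <- st[st$band == "theta" & st$electrode == "F8", ]
  gamma1_f8 <- st[st$band == "gamma1" & st$electrode == "F8", ]
  expect_lt(theta_f8$q, 0.05); expect_equal(theta_f8$direction, 1)
  expect_lt(gamma1_f8$q, 0.05); expect_equal(gamma1_f8$direction, -1)
})
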