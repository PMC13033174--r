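#' Canonical microcircuit parameter set
#'
#' Builds the full parameterization of the 4-population canonical
#' microcircuit (spiny stellate `ss`, superficial pyramidal `sp`,
#' inhibitory interneuron `ii`, deep pyramidal `dp`): second-order
#' synaptic kernels with per-population rate constants `kappa` (1/s)
#' and maximum postsynaptic gains `H` (mV), a signed intrinsic
#' connection table, a centred sigmoid firing function with slope `r`
#' (1/mV), output weights (superficial-pyramidal dominant) and the
#' innovation spectrum `S_u(f) = a_white + a_pink / f` driving the
#' spiny stellate population.
#'
#' @param kappa named numeric vector of rate constants for
#'   `ss, sp, ii, dp` (1/s, all > 0).
#' @param H named numeric vector of synaptic gains (mV, all > 0).
#' @param connections data.frame with columns `source`, `target`,
#'   `g` (>= 0) and `class`; the class of every connection must equal
#'   the neurotransmitter class of its source population (`ss`, `sp`,
#'   `dp` excitatory; `ii` inhibitory).
#' @param r sigmoid slope (1/mV).
#' @param output_weights per-population contribution to the measured
#'   signal.
#' @param noise list with `a_white` and `a_pink` innovation-spectrum
#'   amplitudes.
#' @return object of class `cmc_params`.
#' @export
cmc_params <- function(kappa, H, connections, r = 0.56,
                       output_weights = c(ss = 0.1, sp = 1, ii = 0, dp = 0.2),
                       noise = list(a_white = 1, a_pink = 10)) {
  pops <- c("ss", "sp", "ii", "dp")
  kappa <- kappa[pops]; H <- H[pops]; output_weights <- output_weights[pops]
  if (anyNA(kappa) || any(kappa <= 0)) stop("`kappa` must be positive for all four populations")
  if (anyNA(H) || any(H <= 0)) stop("`H` must be positive for all four populations")
  if (r <= 0) stop("sigmoid slope `r` must be positive")
  req <- c("source", "target", "g", "class")
  if (!all(req %in% names(connections))) stop("connection table must have columns source, target, g, class")
  if (any(connections$g < 0)) stop("connection gains must be non-negative")
  exc_src <- c("ss", "sp", "dp")
  want <- ifelse(connections$source %in% exc_src, "excitatory", "inhibitory")
  if (!all(connections$class == want))
    stop("connection class must match the neurotransmitter class of its source population")
  if (!any(connections$class == "excitatory") || !any(connections$class == "inhibitory"))
    stop("need at least one excitatory and one inhibitory connection")
  structure(list(populations = pops, kappa = kappa, H = H,
                 connections = connections, r = r,
                 output_weights = output_weights, noise = noise),
            class = "cmc_params")
}

# signed weight matrix W[target, source]
cmc_weight_matrix <- function(params) {
  pops <- params$populations
  W <- matrix(0, 4, 4, dimnames = list(pops, pops))
  cn <- params$connections
  for (k in seq_len(nrow(cn))) {
    sgn <- if (cn$class[k] == "excitatory") 1 else -1
    W[cn$target[k], cn$source[k]] <- W[cn$target[k], cn$source[k]] + sgn * cn$g[k]
  }
  W
}

cmc_sigmoid <- function(v, r) 1 / (1 + exp(-r * v)) - 0.5

#' Default (calibrated) canonical microcircuit parameters
#'
#' The packaged baseline parameter set, found by
#' [calibrate_base_params()]: it is stable, its output spectrum has a
#' single dominant alpha-range peak, scaling all excitatory gains down
#' to the schizophrenia-typical relative synapse density shifts
#' relative power from the gamma bands into theta, the same scaling of
#' inhibitory gains alone does not, and the linearized spectrum is
#' faithfully reproduced by time-domain simulation at a 2 kHz step
#' (all band powers within 10 percent), so that stochastic simulations
#' of the nonlinear system can be compared against it directly.
#'
#' @return a `cmc_params` object.
#' @export
cmc_default_params <- function() {
  # values produced by calibrate_base_params(); see the methods vignette
  kappa <- c(ss = 2346.660335, sp = 80.555686, ii = 1020.538019,
             dp = 20.005834)
  g <- c(2688.038810, 17460.535905, 115.351047, 759.280589,
         367.774517, 4.812893, 6282.139134, 18.459893)
  conns <- data.frame(
    source = c("ss", "ss", "sp", "dp", "ii", "ii", "ii", "ii"),
    target = c("sp", "ii", "dp", "ii", "ss", "sp", "dp", "ii"),
    g = g,
    class = rep(c("excitatory", "inhibitory"), each = 4),
    stringsAsFactors = FALSE)
  cmc_params(kappa = kappa, H = c(ss = 1, sp = 1, ii = 1, dp = 1),
             connections = conns)
}

#' Equilibrium (fixed point) of the microcircuit
#'
#' Solves the steady state of the second-order convolution dynamics
#' `vdd = kappa H u(v) - 2 kappa vd - kappa^2 v` with the centred
#' sigmoid firing function, i.e. `v = (H / kappa) W sigma(v)`, by
#' Newton iteration from zero. Because the sigmoid is centred
#' (`sigma(0) = 0`), `v = 0` is always an equilibrium; the Newton
#' solve guards against parameter sets that would drift elsewhere.
#'
#' @param params a `cmc_params` object.
#' @param tol residual tolerance (default 1e-10).
#' @param max_iter maximum Newton iterations.
#' @return named numeric vector of equilibrium voltages (mV).
#' @export
cmc_fixed_point <- function(params, tol = 1e-10, max_iter = 100) {
  W <- cmc_weight_matrix(params)
  A <- diag(params$H / params$kappa) %*% W  # v = A sigma(v)
  v <- rep(0, 4)
  for (it in seq_len(max_iter)) {
    Fv <- v - drop(A %*% cmc_sigmoid(v, params$r))
    if (max(abs(Fv)) < tol) {
      names(v) <- params$populations
      return(v)
    }
    Dsig <- params$r * exp(-params$r * v) / (1 + exp(-params$r * v))^2
    Jv <- diag(4) - A %*% diag(Dsig)
    step <- tryCatch(solve(Jv, Fv), error = function(e) NULL)
    if (is.null(step)) stop("stability error: singular Newton system at the fixed point")
    v <- v - step
  }
  stop("stability error: fixed-point iteration did not converge in ",
       max_iter, " iterations")
}

# Jacobian of the first-order (8-dim) system linearized at v_star
cmc_jacobian <- function(params, v_star = NULL) {
  v_star <- v_star %||% cmc_fixed_point(params)
  W <- cmc_weight_matrix(params)
  r <- params$r
  dsig <- r * exp(-r * v_star) / (1 + exp(-r * v_star))^2
  A21 <- diag(params$kappa * params$H) %*% W %*% diag(dsig) -
    diag(params$kappa^2)
  rbind(cbind(matrix(0, 4, 4), diag(4)),
        cbind(A21, diag(-2 * params$kappa)))
}

#' Stability check of the linearized microcircuit
#'
#' @param params a `cmc_params` object.
#' @return list with `stable` (logical), `max_re` (largest real part of
#'   the Jacobian eigenvalues) and `eigenvalues`.
#' @export
cmc_stability <- function(params) {
  J <- cmc_jacobian(params)
  ev <- eigen(J, only.values = TRUE)$values
  list(stable = max(Re(ev)) < 0, max_re = max(Re(ev)), eigenvalues = ev)
}

#' Analytic EEG power spectrum of the microcircuit
#'
#' Linearizes the circuit at its fixed point and evaluates
#' `PSD(f) = |L (2 pi i f I - J)^{-1} B|^2 S_u(f)` on the requested
#' grid, where `L` holds the output weights, `B` injects the
#' innovation at the spiny stellate population and
#' `S_u(f) = a_white + a_pink / f`.
#'
#' @param params a `cmc_params` object.
#' @param freqs frequency grid in Hz (default 1-70 at 0.5).
#' @return numeric vector of spectral density values (> 0).
#' @export
transfer_psd <- function(params, freqs = seq(1, 70, by = 0.5)) {
  v_star <- cmc_fixed_point(params)
  J <- cmc_jacobian(params, v_star)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop(sprintf("stability error: max real eigenvalue %.4g >= 0", max(Re(ev))))
  B <- c(rep(0, 4), params$kappa[1] * params$H[1], 0, 0, 0)
  L <- c(params$output_weights, rep(0, 4))
  a_w <- params$noise$a_white; a_p <- params$noise$a_pink
  vapply(freqs, function(f) {
    h <- L %*% solve(diag(8) * (2i * pi * f) - J, B)
    Mod(drop(h))^2 * (a_w + a_p / f)
  }, numeric(1))
}

#' Personalize microcircuit gains by relative synapse density
#'
#' Multiplies the connection gains selected by `regime` by the
#' subject's relative synapse density `rho` (HC mean = 1); all other
#' fields are untouched. Personalization is multiplicative:
#' `personalize(personalize(p, a), b) == personalize(p, a * b)`.
#'
#' @param params a `cmc_params` object.
#' @param rho relative density, > 0.
#' @param regime `"ALL"`, `"EXC_ONLY"`, `"INH_ONLY"`, or a character
#'   vector of connection names `"source->target"` (a strict,
#'   non-empty subset of the excitatory connections).
#' @return a modified `cmc_params` object.
#' @export
personalize_params <- function(params, rho, regime = "EXC_ONLY") {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0)
    stop("`rho` must be a single positive number")
  cn <- params$connections
  if (length(regime) == 1 && regime %in% c("ALL", "EXC_ONLY", "INH_ONLY")) {
    sel <- switch(regime,
                  ALL = rep(TRUE, nrow(cn)),
                  EXC_ONLY = cn$class == "excitatory",
                  INH_ONLY = cn$class == "inhibitory")
  } else {
    keys <- paste0(cn$source, "->", cn$target)
    exc_keys <- keys[cn$class == "excitatory"]
    if (!length(regime) || !all(regime %in% exc_keys))
      stop("EXC_SUBSET regime must name excitatory connections (source->target)")
    if (length(unique(regime)) >= length(exc_keys))
      stop("EXC_SUBSET must be a strict subset of the excitatory connections")
    sel <- keys %in% regime
  }
  params$connections$g[sel] <- cn$g[sel] * rho
  params
}

#' Simulate spectra for a cohort of relative densities
#'
#' Per subject: personalize the baseline parameters with the subject's
#' relative density under `regime`, evaluate the analytic spectrum and
#' summarize band powers. Subjects whose personalized circuit is
#' unstable are flagged and skipped rather than aborting the cohort.
#'
#' @param densities data.frame with `subject_id`, `group` and `rho`.
#' @param regime personalization regime (see [personalize_params()]).
#' @param base baseline `cmc_params`.
#' @param freqs frequency grid.
#' @return list with `spectra` (`psd_matrix` with one pseudo-electrode
#'   `"sim"`, failed subjects dropped), `band_powers` (long table) and
#'   `failed` (subject ids with stability failures).
#' @export
simulate_cohort_spectra <- function(densities, regime = "EXC_ONLY",
                                    base = cmc_default_params(),
                                    freqs = seq(1, 70, by = 0.5)) {
  if (!nrow(densities)) stop("empty density table")
  if (any(densities$rho <= 0)) stop("all relative densities must be positive")
  n <- nrow(densities)
  vals <- matrix(NA_real_, n, length(freqs))
  ok <- logical(n)
  for (i in seq_len(n)) {
    p_i <- personalize_params(base, densities$rho[i], regime)
    psd <- tryCatch(transfer_psd(p_i, freqs), error = function(e) NULL)
    if (!is.null(psd)) { vals[i, ] <- psd; ok[i] <- TRUE }
  }
  if (!any(ok)) stop("every subject's personalized circuit was unstable")
  pm <- psd_matrix(array(vals[ok, , drop = FALSE],
                         dim = c(sum(ok), 1, length(freqs))),
                   freqs = freqs, electrodes = "sim",
                   subject_ids = densities$subject_id[ok],
                   labels = densities$group[ok])
  list(spectra = pm, band_powers = band_power(pm),
       failed = densities$subject_id[!ok])
}

#' Regime-specificity comparison
#'
#' For each regime, simulates the cohort, runs the groupwise
#' band-power comparison and reports whether the empirical sign
#' pattern (by default theta up, gamma1 and gamma2 down in SCZ) is
#' reproduced with q < alpha for every patterned band.
#'
#' @param densities data.frame with `subject_id`, `group`, `rho`.
#' @param base baseline `cmc_params`.
#' @param regimes list/vector of regimes to test (>= 2).
#' @param empirical_pattern named signs per band; zero-valued bands are
#'   ignored. An all-zero pattern is rejected as degenerate.
#' @param alpha FDR threshold.
#' @param group_order direction convention, default SCZ minus HC.
#' @return data.frame: one row per regime with `consistent` verdict and
#'   per-band q/direction columns.
#' @export
compare_regimes <- function(densities, base = cmc_default_params(),
                            regimes = c("ALL", "EXC_ONLY", "INH_ONLY"),
                            empirical_pattern = c(theta = 1, gamma1 = -1, gamma2 = -1),
                            alpha = 0.05, group_order = c("SCZ", "HC")) {
  if (length(regimes) < 2) stop("need at least 2 regimes to compare")
  if (all(empirical_pattern == 0)) stop("degenerate empirical pattern: all signs zero")
  pat <- empirical_pattern[empirical_pattern != 0]
  rows <- lapply(regimes, function(rg) {
    sim <- simulate_cohort_spectra(densities, regime = rg, base = base)
    st <- group_band_comparison(sim$band_powers, group_order = group_order)
    hit <- vapply(names(pat), function(b) {
      row <- st[st$band == b, ]
      nrow(row) == 1 && row$q < alpha && row$direction == sign(pat[[b]])
    }, logical(1))
    out <- data.frame(regime = if (length(rg) > 1) paste(rg, collapse = "+") else rg,
                      consistent = all(hit), stringsAsFactors = FALSE)
    for (b in names(pat)) {
      out[[paste0("q_", b)]] <- st$q[st$band == b]
      out[[paste0("dir_", b)]] <- st$direction[st$band == b]
    }
    out
  })
  do.call(rbind, rows)
}

#' Correlate simulated and empirical band power per electrode
#'
#' Pearson correlation, per electrode, between per-subject simulated
#' band power (one microcircuit source) and empirical band power,
#' matched by subject id, with BH q-values across electrodes.
#'
#' @param simulated band-power table from [simulate_cohort_spectra()]
#'   (its `band_powers` element) or any table with `subject_id`,
#'   `band`, `abs_power`.
#' @param empirical band-power table from [band_power()] with an
#'   `electrode` column.
#' @param band band name to correlate (default `"gamma1"`).
#' @param measure `"abs_power"` or `"rel_power"`.
#' @return data.frame: `electrode`, `r`, `p`, `q`, `n`.
#' @export
predicted_vs_empirical <- function(simulated, empirical, band = "gamma1",
                                   measure = "abs_power") {
  sim <- simulated[simulated$band == band, c("subject_id", measure)]
  names(sim)[2] <- "sim_power"
  electrodes <- unique(empirical$electrode)
  rows <- lapply(electrodes, function(e) {
    emp <- empirical[empirical$band == band & empirical$electrode == e,
                     c("subject_id", measure)]
    m <- merge(sim, emp, by = "subject_id")
    if (nrow(m) < 5) stop("subject overlap below 5 for electrode ", e)
    ct <- stats::cor.test(m$sim_power, m[[measure]])
    data.frame(electrode = e, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out[, c("electrode", "r", "p", "q", "n")]
}

#' Euler-Maruyama simulation of the nonlinear microcircuit
#'
#' Integrates the full nonlinear second-order dynamics driven by an
#' innovation realized in the frequency domain with the model's
#' spectrum `S_u(f) = a_white + a_pink / f`, using an explicit Euler
#' step. This is the time-domain counterpart of [transfer_psd()] and
#' serves as its independent validation route.
#'
#' @param params a `cmc_params` object.
#' @param duration_s simulated length in seconds.
#' @param fs sampling rate in Hz (step is `1/fs`).
#' @param n_rep number of independent realizations (columns).
#' @param seed integer seed.
#' @return matrix of output samples, `duration_s * fs` rows x `n_rep`
#'   columns.
#' @export
simulate_cmc_timeseries <- function(params, duration_s = 200, fs = 2000,
                                    n_rep = 1, seed = 1) {
  st <- cmc_stability(params)
  if (!st$stable)
    stop(sprintf("stability error: max real eigenvalue %.4g >= 0", st$max_re))
  n <- round(duration_s * fs)
  if (n %% 2 == 1) n <- n + 1
  dt <- 1 / fs
  set.seed(seed)
  U <- vapply(seq_len(n_rep), function(i)
    synth_innovation(n, fs, params$noise$a_white, params$noise$a_pink),
    numeric(n))
  W <- cmc_weight_matrix(params)
  kH <- params$kappa * params$H
  twok <- 2 * params$kappa; k2 <- params$kappa^2
  L <- params$output_weights
  v <- matrix(0, 4, n_rep); w <- matrix(0, 4, n_rep)
  Y <- matrix(0, n, n_rep)
  r <- params$r
  for (tt in seq_len(n)) {
    inp <- W %*% (1 / (1 + exp(-r * v)) - 0.5)
    inp[1, ] <- inp[1, ] + U[tt, ]
    acc <- kH * inp - twok * w - k2 * v
    v <- v + dt * w
    w <- w + dt * acc
    Y[tt, ] <- crossprod(v, L)
  }
  Y
}

# frequency-domain synthesis of a real series with one-sided PSD
# a_w + a_p/f (DC excluded); length n must be even
synth_innovation <- function(n, fs, a_w, a_p) {
  m <- n / 2
  fk <- (1:m) * fs / n
  S2 <- (a_w + a_p / fk) / 2           # two-sided density
  amp <- sqrt(n * fs * S2 / 2)
  Z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * amp
  Z[m] <- complex(real = stats::rnorm(1) * sqrt(n * fs * S2[m]), imaginary = 0)
  X <- c(0 + 0i, Z, Conj(rev(Z[seq_len(m - 1)])))
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Calibrate the baseline microcircuit parameters
#'
#' Randomized search (structured seeds plus annealed local moves) over
#' gains and rate constants accepting a parameter set if and only if
#' it is (a) stable with margin, (b) alpha-peaked with no competing
#' peak, (c) excitatory-only down-scaling to the
#' schizophrenia-typical relative density raises theta and lowers
#' gamma relative power monotonically, (d) inhibitory-only scaling
#' fails that pattern, and (e) the explicit-Euler discretization at
#' `1/fs_check` reproduces all analytic band powers within
#' `euler_tol`, so the linearized spectrum is checkable by time-domain
#' simulation. The packaged default [cmc_default_params()] is a frozen
#' result of this procedure.
#'
#' @param n_restarts number of annealed restarts.
#' @param n_iter iterations per restart.
#' @param rho_ref reference relative density for constraints (c)-(d).
#' @param euler_tol band-power tolerance of constraint (e).
#' @param fs_check sampling rate of the discretization check.
#' @param seed integer seed; the search is reproducible.
#' @return a `cmc_params` object satisfying all constraints.
#' @export
calibrate_base_params <- function(n_restarts = 10, n_iter = 1500,
                                  rho_ref = 0.876, euler_tol = 0.10,
                                  fs_check = 2000, seed = 1) {
  set.seed(seed)
  template <- cmc_default_params()
  best <- NULL; best_pen <- Inf
  for (rs in seq_len(n_restarts)) {
    k_fast1 <- stats::runif(1, 250, 450); k_fast2 <- stats::runif(1, 250, 450)
    kappa <- c(ss = k_fast1, sp = stats::runif(1, 40, 120),
               ii = k_fast2, dp = stats::runif(1, 25, 70))
    om_f <- 2 * pi * stats::runif(1, 35, 55)
    gf <- sqrt((om_f / 0.707)^4 / (kappa[1] * kappa[3])) / (template$r / 4)
    om_s <- 2 * pi * stats::runif(1, 9, 11)
    gs <- sqrt((om_s / 0.707)^4 / (kappa[4] * kappa[3])) / (template$r / 4)
    g <- c(stats::runif(1, 100, 800), gf * stats::runif(1, 0.7, 1.4),
           stats::runif(1, 100, 800), gs * stats::runif(1, 0.7, 1.4),
           gf * stats::runif(1, 0.7, 1.4), stats::runif(1, 100, 800),
           gs * stats::runif(1, 0.7, 1.4), stats::runif(1, 30, 300))
    cur <- calib_penalty(kappa, g, template, rho_ref, euler_tol, fs_check)
    Temp <- 1
    for (it in seq_len(n_iter)) {
      Temp <- max(0.02, Temp * 0.9985)
      step <- 0.10 * Temp + 0.02
      kap2 <- kappa * exp(stats::rnorm(4, 0, step * 0.5))
      g2 <- g * exp(stats::rnorm(8, 0, step))
      cand <- calib_penalty(kap2, g2, template, rho_ref, euler_tol, fs_check)
      if (cand < cur || stats::runif(1) < exp((cur - cand) / (Temp * 0.3))) {
        kappa <- kap2; g <- g2; cur <- cand
      }
    }
    if (cur < best_pen) { best_pen <- cur; best <- list(kappa = kappa, g = g) }
    if (best_pen == 0) break
  }
  if (best_pen > 0)
    stop(sprintf("calibration failure: best residual penalty %.4g; ",
                 best_pen), "increase n_restarts/n_iter")
  out <- template
  out$kappa <- stats::setNames(best$kappa, template$populations)
  out$connections$g <- best$g
  out
}

# continuous constraint-violation penalty used by calibrate_base_params;
# zero iff all calibration constraints hold
calib_penalty <- function(kappa, g, template, rho_ref, euler_tol, fs_check) {
  p <- template
  p$kappa <- stats::setNames(kappa, p$populations)
  p$connections$g <- g
  st <- tryCatch(cmc_stability(p), error = function(e) NULL)
  if (is.null(st) || !st$stable) return(1e3)
  pen <- max(0, st$max_re + 0.5) * 10
  freqs <- seq(1, 70, by = 0.5)
  base <- transfer_psd(p, freqs)
  pk <- freqs[which.max(base)]
  pen <- pen + max(0, 8.5 - pk) * 2 + max(0, pk - 12.5) * 2
  locmax <- which(diff(sign(diff(base))) == -2) + 1
  big <- locmax[base[locmax] > 0.6 * max(base)]
  if (length(big)) pen <- pen + max(0, max(abs(freqs[big] - pk)) - 3)
  # discretization fidelity of the Euler map at fs_check
  J <- cmc_jacobian(p)
  dt <- 1 / fs_check
  Ad <- diag(8) + J * dt
  B <- c(rep(0, 4), p$kappa[1] * p$H[1], 0, 0, 0)
  L <- c(p$output_weights, rep(0, 4))
  ep <- vapply(freqs, function(f) {
    z <- exp(2i * pi * f * dt)
    Mod(drop(L %*% solve(diag(8) * z - Ad, B * dt)))^2 *
      (p$noise$a_white + p$noise$a_pink / f)
  }, numeric(1))
  bnd <- eeg_bands()
  bint <- function(psd) vapply(seq_len(nrow(bnd)), function(b) {
    sel <- freqs >= bnd$lo[b] & freqs <= bnd$hi[b]
    pracma::trapz(freqs[sel], psd[sel])
  }, numeric(1))
  a0 <- bint(base); e0 <- bint(ep)
  pen <- pen + max(0, max(abs(e0 / a0 - 1)) - euler_tol * 0.9) * 30
  rel0 <- a0 / sum(a0)  # delta theta alpha beta gamma1 gamma2
  pen <- pen + max(0, 0.03 - rel0[1]) * 30 + max(0, 0.08 - rel0[2]) * 30 +
    max(0, rel0[2] - 0.30) * 30 + max(0, 0.20 - rel0[3]) * 30 +
    max(0, 0.015 - rel0[5]) * 60 + max(0, rel0[5] - 0.15) * 30 +
    max(0, rel0[6] - 0.05) * 30
  rhos <- seq(0.70, 1, by = 0.05)
  th <- ga <- numeric(length(rhos))
  for (i in seq_along(rhos)) {
    pi_ <- personalize_params(p, rhos[i], "EXC_ONLY")
    sti <- cmc_stability(pi_)
    if (!sti$stable) return(pen + 50)
    a <- bint(transfer_psd(pi_, freqs)); rel <- a / sum(a)
    th[i] <- rel[2]; ga[i] <- rel[5] + rel[6]
  }
  pen <- pen + sum(pmax(0, -diff(ga))) * 300 + sum(pmax(0, diff(th))) * 300
  aE <- bint(transfer_psd(personalize_params(p, rho_ref, "EXC_ONLY"), freqs))
  relE <- aE / sum(aE)
  pen <- pen + max(0, rel0[2] - relE[2] + 0.002) * 200 +
    max(0, (relE[5] + relE[6]) - (rel0[5] + rel0[6]) + 0.002) * 200
  pI <- personalize_params(p, rho_ref, "INH_ONLY")
  stI <- cmc_stability(pI)
  if (!stI$stable) return(pen + 50)
  aI <- bint(transfer_psd(pI, freqs)); relI <- aI / sum(aI)
  if (relI[2] > rel0[2] && (relI[5] + relI[6]) < (rel0[5] + rel0[6]))
    pen <- pen + 5
  pen
}

#' Serialize / read microcircuit parameters as YAML
#'
#' @param params a `cmc_params` object.
#' @param path file path.
#' @return `read_cmc_params` returns a `cmc_params` object.
#' @export
write_cmc_params <- function(params, path) {
  yaml::write_yaml(list(
    kappa = as.list(params$kappa), H = as.list(params$H),
    r = params$r,
    output_weights = as.list(params$output_weights),
    noise = params$noise,
    connections = lapply(seq_len(nrow(params$connections)), function(i)
      as.list(params$connections[i, ]))), path)
  invisible(path)
}

#' @rdname write_cmc_params
#' @export
read_cmc_params <- function(path) {
  y <- yaml::read_yaml(path)
  conns <- do.call(rbind, lapply(y$connections, function(cc)
    data.frame(source = cc$source, target = cc$target, g = cc$g,
               class = cc$class, stringsAsFactors = FALSE)))
  cmc_params(kappa = unlist(y$kappa), H = unlist(y$H), connections = conns,
             r = y$r, output_weights = unlist(y$output_weights),
             noise = y$noise)
}
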