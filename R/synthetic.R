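#' Specification of one planted latent cross-block signature
#'
#' Describes a sparse latent signature linking the phenotype and GMV
#' blocks: which columns carry it (with signs), what drives the shared
#' latent factor (`age` or `diagnosis`), the target correlation of the
#' two observable block scores, and the per-column residual scale.
#'
#' The generator compensates the planted latent correlation upward by
#' the analytic attenuation factor `sqrt((1 + noise_sd^2 / k_u) *
#' (1 + noise_sd^2 / k_v))` so that the correlation of the observable
#' block scores (mean of the signed supporting columns) lands on
#' `score_correlation`.
#'
#' @param driver `"age"` or `"diagnosis"`.
#' @param u_support integer indices into the phenotype block.
#' @param v_support integer indices into the GMV block.
#' @param u_signs,v_signs signs (+1/-1) per support column; default +1.
#' @param score_correlation target block-score correlation, in (0, 1).
#' @param noise_sd residual scale per supporting column.
#' @param driver_strength correlation-like loading of the driver on the
#'   shared factor, in (0, 1).
#' @return object of class `latent_spec`.
#' @export
latent_spec <- function(driver = c("diagnosis", "age"),
                        u_support, v_support,
                        u_signs = NULL, v_signs = NULL,
                        score_correlation = 0.57, noise_sd = 0.5,
                        driver_strength = 0.6) {
  driver <- match.arg(driver)
  if (!length(u_support) || !length(v_support))
    stop("latent_spec: supports must be non-empty")
  if (score_correlation <= 0 || score_correlation >= 1)
    stop("latent_spec: score_correlation must be in (0, 1)")
  if (noise_sd <= 0) stop("latent_spec: noise_sd must be positive")
  u_signs <- u_signs %||% rep(1, length(u_support))
  v_signs <- v_signs %||% rep(1, length(v_support))
  if (length(u_signs) != length(u_support) || length(v_signs) != length(v_support))
    stop("latent_spec: signs must match support lengths")
  if (!all(abs(u_signs) == 1) || !all(abs(v_signs) == 1))
    stop("latent_spec: signs must be +1 or -1")
  structure(list(driver = driver, u_support = as.integer(u_support),
                 v_support = as.integer(v_support),
                 u_signs = u_signs, v_signs = v_signs,
                 score_correlation = score_correlation,
                 noise_sd = noise_sd, driver_strength = driver_strength),
            class = "latent_spec")
}

#' Synapse-density generation parameters
#'
#' Subject-level SYN1 puncta densities are log-normal (guaranteeing
#' positivity) with the group reduction applied to the arithmetic mean;
#' replicate wells are log-normal around the subject mean.
#'
#' @param mean_hc healthy-control mean density (SYN1 puncta per um of
#'   neurite), > 0.
#' @param reduction_pct percent reduction of the SCZ group mean,
#'   in `[0, 100)`; the default reflects the schizophrenia-typical
#'   reduction of excitatory synapse density.
#' @param cv_within coefficient of variation of subject means within a
#'   group.
#' @param cv_replicate coefficient of variation of replicate wells
#'   around their subject mean.
#' @param replicates_per_subject number of wells per subject.
#' @return object of class `synapse_gen_params`.
#' @export
synapse_gen_params <- function(mean_hc = 0.45, reduction_pct = 12.4,
                               cv_within = 0.12, cv_replicate = 0.15,
                               replicates_per_subject = 3) {
  if (mean_hc <= 0) stop("synapse_gen_params: mean_hc must be positive")
  if (reduction_pct < 0 || reduction_pct >= 100)
    stop("synapse_gen_params: reduction_pct must be in [0, 100)")
  if (cv_within <= 0) stop("synapse_gen_params: cv_within must be positive")
  if (cv_replicate <= 0) stop("synapse_gen_params: cv_replicate must be positive")
  if (replicates_per_subject < 1)
    stop("synapse_gen_params: replicates_per_subject must be >= 1")
  structure(list(mean_hc = mean_hc, reduction_pct = reduction_pct,
                 cv_within = cv_within, cv_replicate = cv_replicate,
                 replicates_per_subject = as.integer(replicates_per_subject)),
            class = "synapse_gen_params")
}

#' Cohort generation configuration
#'
#' @param n_hc,n_scz group sizes (>= 2 each).
#' @param p_pheno number of cognition/clinical features.
#' @param q_voxels number of GMV features.
#' @param n_genes number of expression features (default 310).
#' @param electrodes electrode labels (unique; 10-20 subset including
#'   F8, C3 and C4 by default).
#' @param freq_grid strictly increasing Hz grid within `[1, 70]`.
#' @param latent_specs list of [latent_spec()]s with disjoint supports
#'   per block; the defaults plant an age-driven signature and a
#'   diagnosis-driven neurocognition signature.
#' @param synapse_params a [synapse_gen_params()].
#' @param frac_informative fraction of expression features carrying
#'   signal for the cognition score.
#' @param effect_sd effect size scale of informative genes.
#' @param electrode_coupling named coupling weights in `[0, 1]` mixing
#'   each electrode's "empirical" PSD between the subject's simulated
#'   spectrum and a shared background; F8-dominant by default.
#' @param meas_noise_sd log-normal measurement noise SD of the
#'   empirical PSD.
#' @param include_psd generate the per-electrode PSD block (can be
#'   switched off for large purely-statistical cohorts).
#' @param seed integer seed; the entire cohort is a deterministic
#'   function of the configuration.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 73, n_scz = 58, p_pheno = 30, q_voxels = 200,
                          n_genes = 310,
                          electrodes = c("F3", "F4", "F7", "F8", "C3",
                                         "C4", "P3", "P4", "O1", "O2"),
                          freq_grid = seq(1, 70, by = 0.5),
                          latent_specs = default_latent_specs(p_pheno, q_voxels),
                          synapse_params = synapse_gen_params(),
                          frac_informative = 0.3, effect_sd = 0.5,
                          electrode_coupling = default_electrode_coupling(electrodes),
                          meas_noise_sd = 0.25,
                          include_psd = TRUE, seed = 1) {
  chk_count <- function(x, nm) if (!is.numeric(x) || length(x) != 1 || x < 2)
    stop(sprintf("cohort_config: `%s` must be a count >= 2", nm))
  chk_count(n_hc, "n_hc"); chk_count(n_scz, "n_scz")
  chk_count(p_pheno, "p_pheno"); chk_count(q_voxels, "q_voxels")
  chk_count(n_genes, "n_genes")
  if (anyDuplicated(electrodes)) stop("cohort_config: `electrodes` must be unique")
  if (is.unsorted(freq_grid, strictly = TRUE) || min(freq_grid) < 1 ||
      max(freq_grid) > 70)
    stop("cohort_config: `freq_grid` must be strictly increasing within [1, 70] Hz")
  if (frac_informative < 0 || frac_informative > 1)
    stop("cohort_config: `frac_informative` must be in [0, 1]")
  for (sp in latent_specs) {
    if (!inherits(sp, "latent_spec")) stop("cohort_config: latent_specs must be latent_spec objects")
    if (max(sp$u_support) > p_pheno) stop("cohort_config: u_support exceeds p_pheno")
    if (max(sp$v_support) > q_voxels) stop("cohort_config: v_support exceeds q_voxels")
  }
  if (length(latent_specs) > 1) {
    us <- unlist(lapply(latent_specs, `[[`, "u_support"))
    vs <- unlist(lapply(latent_specs, `[[`, "v_support"))
    if (anyDuplicated(us) || anyDuplicated(vs))
      stop("cohort_config: latent_specs supports must be disjoint across specs")
  }
  if (!all(names(electrode_coupling) %in% electrodes) ||
      !all(electrodes %in% names(electrode_coupling)))
    stop("cohort_config: `electrode_coupling` must name every electrode")
  if (any(electrode_coupling < 0 | electrode_coupling > 1))
    stop("cohort_config: coupling weights must be in [0, 1]")
  structure(list(n_hc = as.integer(n_hc), n_scz = as.integer(n_scz),
                 p_pheno = as.integer(p_pheno), q_voxels = as.integer(q_voxels),
                 n_genes = as.integer(n_genes), electrodes = electrodes,
                 freq_grid = freq_grid, latent_specs = latent_specs,
                 synapse_params = synapse_params,
                 frac_informative = frac_informative, effect_sd = effect_sd,
                 electrode_coupling = electrode_coupling,
                 meas_noise_sd = meas_noise_sd,
                 include_psd = isTRUE(include_psd), seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_latent_specs <- function(p_pheno = 30, q_voxels = 200) {
  list(
    latent_spec(driver = "age", u_support = 1:8, v_support = 1:15,
                u_signs = c(-1, -1, -1, -1, 1, 1, 1, 1),
                score_correlation = 0.78, noise_sd = 0.5,
                driver_strength = 0.8),
    latent_spec(driver = "diagnosis", u_support = 9:18, v_support = 16:35,
                u_signs = rep(c(-1, 1), each = 5),
                v_signs = rep(c(-1, 1), each = 10),
                score_correlation = 0.57, noise_sd = 0.5,
                driver_strength = 0.6))
}

#' @rdname cohort_config
#' @export
default_electrode_coupling <- function(electrodes) {
  w <- stats::setNames(rep(0.15, length(electrodes)), electrodes)
  if ("C3" %in% electrodes) w[["C3"]] <- 0.45
  if ("C4" %in% electrodes) w[["C4"]] <- 0.45
  if ("F8" %in% electrodes) w[["F8"]] <- 0.80
  w
}

#' Generate subject- and replicate-level synapse densities
#'
#' Subject means are log-normal around the group arithmetic mean
#' (`mean_hc` for HC, `mean_hc * (1 - reduction_pct/100)` for SCZ) with
#' coefficient of variation `cv_within`; replicate wells are log-normal
#' around each subject mean with `cv_replicate`. Log-normality makes
#' every value strictly positive.
#'
#' @param params a [synapse_gen_params()].
#' @param n_hc,n_scz group sizes.
#' @param seed integer seed.
#' @return list with `subjects` (subject_id, group, mean_density, rho)
#'   and `replicates` (subject_id, group, replicate,
#'   syn1_density_per_um); `rho` is the subject mean divided by the HC
#'   group mean of this generated cohort.
#' @export
generate_synapse_densities <- function(params = synapse_gen_params(),
                                       n_hc, n_scz, seed = 1) {
  stopifnot(inherits(params, "synapse_gen_params"))
  if (params$mean_hc <= 0) stop("mean_hc must be positive")
  set.seed(seed)
  n <- n_hc + n_scz
  group <- c(rep("HC", n_hc), rep("SCZ", n_scz))
  gmean <- ifelse(group == "HC", params$mean_hc,
                  params$mean_hc * (1 - params$reduction_pct / 100))
  sdlog <- sqrt(log(1 + params$cv_within^2))
  mu <- log(gmean) - sdlog^2 / 2
  subj_mean <- stats::rlnorm(n, meanlog = mu, sdlog = sdlog)
  subject_id <- sprintf("S%04d", seq_len(n))
  rho <- subj_mean / mean(subj_mean[group == "HC"])
  reps <- params$replicates_per_subject
  sdlog_r <- sqrt(log(1 + params$cv_replicate^2))
  repl <- data.frame(
    subject_id = rep(subject_id, each = reps),
    group = rep(group, each = reps),
    replicate = rep(seq_len(reps), times = n),
    syn1_density_per_um = stats::rlnorm(
      n * reps, meanlog = rep(log(subj_mean) - sdlog_r^2 / 2, each = reps),
      sdlog = sdlog_r),
    stringsAsFactors = FALSE)
  list(subjects = data.frame(subject_id = subject_id, group = group,
                             mean_density = subj_mean, rho = rho,
                             stringsAsFactors = FALSE),
       replicates = repl)
}

#' Generate phenotype and GMV blocks with planted latent signatures
#'
#' For each [latent_spec()], a shared latent factor is built from its
#' driver (scaled age, or the diagnosis indicator mixed with noise at
#' `driver_strength`), split into a phenotype-side and a GMV-side
#' latent score with the attenuation-compensated correlation, and
#' loaded with the stated signs onto the supporting columns plus
#' `noise_sd`-scaled residuals. All remaining columns are iid standard
#' normal, and every column is z-scaled at generation.
#'
#' @param config a [cohort_config()].
#' @param labels group label per subject.
#' @param age age per subject (years).
#' @param seed integer seed.
#' @return list with `pheno`, `gmv` (matrices) and `truth` (per spec:
#'   supports, signs, latent scores, observable block scores and the
#'   compensated latent correlation).
#' @export
generate_phenotype_gmv <- function(config, labels, age, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  pheno <- matrix(stats::rnorm(n * config$p_pheno), n, config$p_pheno)
  gmv <- matrix(stats::rnorm(n * config$q_voxels), n, config$q_voxels)
  truth <- list()
  for (si in seq_along(config$latent_specs)) {
    sp <- config$latent_specs[[si]]
    drv <- if (sp$driver == "age") drop(scale(age))
           else drop(scale(as.numeric(labels == "SCZ")))
    b <- sp$driver_strength
    f <- b * drv + sqrt(1 - b^2) * stats::rnorm(n)
    ku <- length(sp$u_support); kv <- length(sp$v_support)
    c0 <- sp$score_correlation *
      sqrt((1 + sp$noise_sd^2 / ku) * (1 + sp$noise_sd^2 / kv))
    if (c0 >= 0.999)
      stop("latent_spec: score_correlation unreachable at this noise_sd/support size")
    a <- sqrt(c0)
    t_x <- a * f + sqrt(1 - c0) * stats::rnorm(n)
    t_y <- a * f + sqrt(1 - c0) * stats::rnorm(n)
    for (j in seq_along(sp$u_support))
      pheno[, sp$u_support[j]] <- sp$u_signs[j] * t_x +
        sp$noise_sd * stats::rnorm(n)
    for (j in seq_along(sp$v_support))
      gmv[, sp$v_support[j]] <- sp$v_signs[j] * t_y +
        sp$noise_sd * stats::rnorm(n)
    truth[[si]] <- list(driver = sp$driver,
                        u_support = sp$u_support, u_signs = sp$u_signs,
                        v_support = sp$v_support, v_signs = sp$v_signs,
                        latent = f, t_x = t_x, t_y = t_y,
                        latent_correlation = c0,
                        target_score_correlation = sp$score_correlation)
  }
  pheno <- scale(pheno); gmv <- scale(gmv)
  # drop scale()'s center/scale attributes so cohort matrices are plain
  # matrices that survive serialization round-trips unchanged
  attr(pheno, "scaled:center") <- NULL; attr(pheno, "scaled:scale") <- NULL
  attr(gmv, "scaled:center") <- NULL; attr(gmv, "scaled:scale") <- NULL
  colnames(pheno) <- sprintf("pheno%03d", seq_len(ncol(pheno)))
  colnames(gmv) <- sprintf("voxel%04d", seq_len(ncol(gmv)))
  for (si in seq_along(truth)) {
    sp <- config$latent_specs[[si]]
    truth[[si]]$score_pheno <- drop(pheno[, sp$u_support, drop = FALSE] %*%
                                      sp$u_signs) / length(sp$u_support)
    truth[[si]]$score_gmv <- drop(gmv[, sp$v_support, drop = FALSE] %*%
                                    sp$v_signs) / length(sp$v_support)
  }
  list(pheno = pheno, gmv = gmv, truth = truth)
}

#' Generate an expression block carrying signal for the cognition score
#'
#' Informative genes are noisy linear readouts of the planted cognition
#' score (the diagnosis-driven signature's phenotype-side score) plus a
#' diagnosis offset; the remaining genes are iid noise. Columns carry
#' gene identifiers.
#'
#' @param cognition_score per-subject planted cognition score.
#' @param labels group label per subject.
#' @param n_genes number of genes (default 310).
#' @param frac_informative fraction of informative genes in `[0, 1]`.
#' @param effect_sd scale of the informative effects.
#' @param seed integer seed.
#' @return list with `expression` (matrix) and `informative` (column
#'   indices).
#' @export
generate_expression <- function(cognition_score, labels, n_genes = 310,
                                frac_informative = 0.3, effect_sd = 0.5,
                                seed = 1) {
  if (frac_informative < 0 || frac_informative > 1)
    stop("`frac_informative` must be in [0, 1]")
  set.seed(seed)
  n <- length(cognition_score)
  k <- round(frac_informative * n_genes)
  expr <- matrix(stats::rnorm(n * n_genes), n, n_genes)
  dz <- as.numeric(labels == "SCZ")
  cs <- drop(scale(cognition_score))
  if (k > 0) {
    betas <- stats::rnorm(k, 0, effect_sd)
    offs <- stats::rnorm(k, 0, effect_sd / 2)
    for (j in seq_len(k))
      expr[, j] <- betas[j] * cs + offs[j] * dz + stats::rnorm(n)
  }
  colnames(expr) <- sprintf("GENE%04d", seq_len(n_genes))
  list(expression = expr, informative = seq_len(k))
}

#' Generate per-electrode "empirical" PSDs from relative densities
#'
#' Each subject's empirical spectrum at an electrode mixes the
#' subject's personalized forward spectrum (excitatory-only regime)
#' with a shared 1/f-plus-alpha-bump background by the electrode's
#' coupling weight, then applies mean-one log-normal measurement
#' noise. With coupling 1 and zero noise the electrode reproduces the
#' forward spectrum exactly; with coupling 0 it carries no
#' subject-specific synaptic information.
#'
#' @param densities subject table with `subject_id`, `group`, `rho`.
#' @param base_params baseline `cmc_params`.
#' @param electrode_coupling named numeric coupling weights in `[0, 1]`.
#' @param meas_noise_sd log-normal noise SD (0 disables noise).
#' @param freqs frequency grid.
#' @param seed integer seed.
#' @return a `psd_matrix`.
#' @export
generate_empirical_psd <- function(densities,
                                   base_params = cmc_default_params(),
                                   electrode_coupling = default_electrode_coupling(
                                     c("F3", "F4", "F7", "F8", "C3", "C4",
                                       "P3", "P4", "O1", "O2")),
                                   meas_noise_sd = 0.25,
                                   freqs = seq(1, 70, by = 0.5), seed = 1) {
  set.seed(seed)
  n <- nrow(densities)
  electrodes <- names(electrode_coupling)
  base_psd <- transfer_psd(base_params, freqs)  # errors if unstable
  bg <- background_spectrum(freqs)
  bg <- bg * pracma::trapz(freqs, base_psd) / pracma::trapz(freqs, bg)
  vals <- array(0, dim = c(n, length(electrodes), length(freqs)))
  for (i in seq_len(n)) {
    sim_i <- transfer_psd(
      personalize_params(base_params, densities$rho[i], "EXC_ONLY"), freqs)
    for (e in seq_along(electrodes)) {
      w <- electrode_coupling[[e]]
      noise <- if (meas_noise_sd > 0)
        exp(stats::rnorm(1, 0, meas_noise_sd) - meas_noise_sd^2 / 2) else 1
      vals[i, e, ] <- (w * sim_i + (1 - w) * bg) * noise
    }
  }
  psd_matrix(vals, freqs = freqs, electrodes = electrodes,
             subject_ids = densities$subject_id, labels = densities$group)
}

# resting-EEG-like background: 1/f plus an alpha bump at 10 Hz
background_spectrum <- function(freqs) {
  1 / freqs^1.3 + 0.8 * exp(-(freqs - 10)^2 / (2 * 2^2))
}

#' Generate a complete synthetic multimodal cohort
#'
#' Orchestrates all block generators under sub-seeds derived from
#' `config$seed`, so the whole cohort is a deterministic function of
#' its configuration. Ground truth sufficient to score recovery of
#' every planted effect is stored alongside the data.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort` with elements `labels`,
#'   `age`, `pheno`, `gmv`, `synapse`, `expression`, `psd` (or `NULL`),
#'   `truth` and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  n <- config$n_hc + config$n_scz
  labels <- c(rep("HC", config$n_hc), rep("SCZ", config$n_scz))
  subject_id <- sprintf("S%04d", seq_len(n))
  set.seed(seed)
  age <- stats::runif(n, 18, 65)
  pg <- generate_phenotype_gmv(config, labels, age, seed = seed + 1L)
  syn <- generate_synapse_densities(config$synapse_params, config$n_hc,
                                    config$n_scz, seed = seed + 2L)
  cog_idx <- which(vapply(config$latent_specs, `[[`, "", "driver") == "diagnosis")
  cognition <- if (length(cog_idx)) pg$truth[[cog_idx[1]]]$score_pheno
               else stats::rnorm(n)
  ex <- generate_expression(cognition, labels, config$n_genes,
                            config$frac_informative, config$effect_sd,
                            seed = seed + 3L)
  psd <- NULL
  if (config$include_psd)
    psd <- generate_empirical_psd(syn$subjects,
                                  electrode_coupling = config$electrode_coupling,
                                  meas_noise_sd = config$meas_noise_sd,
                                  freqs = config$freq_grid, seed = seed + 4L)
  rownames(pg$pheno) <- rownames(pg$gmv) <- rownames(ex$expression) <- subject_id
  structure(list(subject_id = subject_id, labels = labels, age = age,
                 pheno = pg$pheno, gmv = pg$gmv, synapse = syn,
                 expression = ex$expression,
                 psd = psd,
                 truth = list(signatures = pg$truth,
                              informative_genes = ex$informative,
                              rho = syn$subjects$rho,
                              reduction_pct = config$synapse_params$reduction_pct),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d HC / %d SCZ)\n",
              length(x$labels), sum(x$labels == "HC"), sum(x$labels == "SCZ")))
  cat(sprintf("  pheno %d x %d, gmv %d x %d, expression %d x %d, psd: %s\n",
              nrow(x$pheno), ncol(x$pheno), nrow(x$gmv), ncol(x$gmv),
              nrow(x$expression), ncol(x$expression),
              if (is.null(x$psd)) "none" else
                paste(dim(x$psd$values), collapse = " x ")))
  invisible(x)
}

#' Write / read a cohort as a directory of plain-text files
#'
#' Writes `pheno.tsv`, `gmv.tsv`, `expression.tsv`,
#' `synapse_density.tsv` (long replicate table), `subjects.tsv`,
#' `psd.tsv` (long format), `truth.json` and `config.yaml`.
#' `read_cohort()` restores a `synthetic_cohort` losslessly up to
#' numeric text precision (values are written with full precision).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `read_cohort` returns a `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wm <- function(m, f) wtsv(data.frame(subject_id = cohort$subject_id,
                                       m, check.names = FALSE), f)
  wm(cohort$pheno, "pheno.tsv"); wm(cohort$gmv, "gmv.tsv")
  wm(cohort$expression, "expression.tsv")
  wtsv(cohort$synapse$replicates, "synapse_density.tsv")
  wtsv(data.frame(cohort$synapse$subjects, age = cohort$age,
                  label = cohort$labels), "subjects.tsv")
  if (!is.null(cohort$psd)) {
    p <- cohort$psd
    long <- data.frame(
      subject_id = rep(p$subject_ids, times = length(p$electrodes) * length(p$freqs)),
      electrode = rep(rep(p$electrodes, each = dim(p$values)[1]),
                      times = length(p$freqs)),
      freq = rep(p$freqs, each = dim(p$values)[1] * length(p$electrodes)),
      psd = as.vector(p$values))
    wtsv(long, "psd.tsv")
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  cfg$latent_specs <- lapply(cfg$latent_specs, unclass)
  cfg$synapse_params <- unclass(cfg$synapse_params)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rtsv <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                        header = TRUE, check.names = FALSE,
                                        stringsAsFactors = FALSE)
  subj <- rtsv("subjects.tsv")
  getm <- function(f) {
    d <- rtsv(f)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$subject_id
    m
  }
  psd <- NULL
  if (file.exists(file.path(dir, "psd.tsv"))) {
    long <- rtsv("psd.tsv")
    sids <- unique(long$subject_id); els <- unique(long$electrode)
    frs <- sort(unique(long$freq))
    vals <- array(long$psd[order(match(long$freq, frs),
                                 match(long$electrode, els),
                                 match(long$subject_id, sids))],
                  dim = c(length(sids), length(els), length(frs)))
    psd <- psd_matrix(vals, frs, els, sids, subj$label)
  }
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(subject_id = subj$subject_id, labels = subj$label,
                 age = subj$age,
                 pheno = getm("pheno.tsv"), gmv = getm("gmv.tsv"),
                 expression = getm("expression.tsv"),
                 synapse = list(subjects = subj[, c("subject_id", "group",
                                                    "mean_density", "rho")],
                                replicates = rtsv("synapse_density.tsv")),
                 psd = psd, truth = truth, config = cfgl),
            class = "synthetic_cohort")
}
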