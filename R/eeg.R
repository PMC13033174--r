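#' Canonical EEG frequency bands
#'
#' The six analysis bands: delta (1-4), theta (4-8), alpha (8-12),
#' beta (12-30), gamma1 (30-50) and gamma2 (50-70 Hz). Band intervals
#' are treated as half-open `[lo, hi)` so they tile `[1, 70)` exactly;
#' since band powers are trapezoidal integrals on the native grid and
#' the trapezoid rule is additive over shared edges, the six absolute
#' powers always sum to the total 1-70 Hz power.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2"),
             lo = c(1, 4, 8, 12, 30, 50),
             hi = c(4, 8, 12, 30, 50, 70),
             stringsAsFactors = FALSE)
}

#' Construct a PSD matrix container
#'
#' @param values subjects x electrodes x frequencies array of spectral
#'   density (signal-units^2/Hz), non-negative and finite.
#' @param freqs strictly increasing frequency grid in `[1, 70]` Hz.
#' @param electrodes electrode labels (unique).
#' @param subject_ids subject identifiers.
#' @param labels group label per subject (e.g. `"HC"`/`"SCZ"`), optional.
#' @return object of class `psd_matrix`.
#' @export
psd_matrix <- function(values, freqs, electrodes,
                       subject_ids = NULL, labels = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3)
    stop("`values` must be a subjects x electrodes x freqs array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("PSD values must be finite and non-negative")
  if (is.unsorted(freqs, strictly = TRUE) || min(freqs) < 1 || max(freqs) > 70)
    stop("`freqs` must be strictly increasing within [1, 70] Hz")
  if (anyDuplicated(electrodes)) stop("electrode labels must be unique")
  if (dim(values)[2] != length(electrodes) || dim(values)[3] != length(freqs))
    stop("dimensions of `values` do not match electrodes/freqs")
  subject_ids <- subject_ids %||% sprintf("S%03d", seq_len(dim(values)[1]))
  structure(list(values = values, freqs = freqs, electrodes = electrodes,
                 subject_ids = subject_ids, labels = labels),
            class = "psd_matrix")
}

#' Welch power spectral density of multichannel time series
#'
#' Hann-windowed averaged periodogram, one-sided density normalization
#' (`2 / (fs * sum(w^2))`), restricted to the 1-70 Hz analysis range.
#' With the default 2 s window the native resolution is 0.5 Hz.
#'
#' @param timeseries channels x samples matrix (a vector is treated as
#'   one channel).
#' @param fs sampling rate in Hz; must exceed 140 Hz so that 70 Hz is
#'   below Nyquist.
#' @param window_s window length in seconds (default 2).
#' @param overlap fractional overlap between windows (default 0.5).
#' @param electrodes optional channel labels.
#' @return a `psd_matrix` with one subject.
#' @export
welch_psd <- function(timeseries, fs, window_s = 2, overlap = 0.5,
                      electrodes = NULL) {
  if (is.vector(timeseries)) timeseries <- matrix(timeseries, nrow = 1)
  if (fs <= 140) stop("`fs` must exceed 140 Hz (Nyquist for 70 Hz)")
  nw <- round(window_s * fs)
  if (nw < 2) stop("window too short: `window_s * fs` must be >= 2 samples")
  if (ncol(timeseries) < nw)
    stop("recording shorter than one window")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, ncol(timeseries) - nw + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / (nw - 1)))
  u2 <- sum(w^2)
  fr <- (0:(nw - 1)) * fs / nw
  keep <- which(fr >= 1 & fr <= 70)
  nchan <- nrow(timeseries)
  out <- array(0, dim = c(1, nchan, length(keep)))
  for (ch in seq_len(nchan)) {
    acc <- numeric(nw)
    for (s0 in starts) {
      seg <- timeseries[ch, s0:(s0 + nw - 1)] * w
      acc <- acc + Mod(stats::fft(seg))^2
    }
    out[1, ch, ] <- (acc / length(starts) * 2 / (fs * u2))[keep]
  }
  psd_matrix(out, freqs = fr[keep],
             electrodes = electrodes %||% sprintf("ch%02d", seq_len(nchan)))
}

#' Absolute and relative band power
#'
#' Absolute power per band is the trapezoidal integral of the PSD over
#' the band on the native grid; relative power divides by the total
#' 1-70 Hz power. Because the trapezoid rule is additive across bands
#' that share grid-point edges, relative powers sum to one exactly.
#'
#' @param psd a `psd_matrix`.
#' @param bands band definition table as from [eeg_bands()].
#' @return data.frame (long format): `subject_id`, `group`,
#'   `electrode`, `band`, `abs_power`, `rel_power`.
#' @export
band_power <- function(psd, bands = eeg_bands()) {
  stopifnot(inherits(psd, "psd_matrix"))
  fr <- psd$freqs
  if (min(fr) > min(bands$lo) || max(fr) < max(bands$hi))
    stop("frequency grid does not cover the requested bands")
  nsub <- dim(psd$values)[1]; nel <- dim(psd$values)[2]
  rows <- vector("list", nsub * nel)
  idx <- 0
  for (i in seq_len(nsub)) {
    for (e in seq_len(nel)) {
      p <- psd$values[i, e, ]
      total <- pracma::trapz(fr, p)
      ab <- vapply(seq_len(nrow(bands)), function(b) {
        sel <- fr >= bands$lo[b] & fr <= bands$hi[b]
        pracma::trapz(fr[sel], p[sel])
      }, numeric(1))
      rel <- if (total > 0) ab / total else rep(0, length(ab))
      idx <- idx + 1
      rows[[idx]] <- data.frame(
        subject_id = psd$subject_ids[i],
        group = if (is.null(psd$labels)) NA_character_ else psd$labels[i],
        electrode = psd$electrodes[e],
        band = bands$name,
        abs_power = ab, rel_power = rel,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Z-score band-power features against a reference group
#'
#' Each band x electrode x measure feature is centred and scaled by
#' the mean and SD over the reference subjects.
#'
#' @param table band-power table from [band_power()].
#' @param reference subject ids forming the reference set; default all.
#' @param measure `"abs_power"`, `"rel_power"` or both (default).
#' @return the table with the chosen measures replaced by z-scores.
#' @export
zscore_band_features <- function(table, reference = NULL,
                                 measure = c("abs_power", "rel_power")) {
  measure <- match.arg(measure, several.ok = TRUE)
  reference <- reference %||% unique(table$subject_id)
  if (length(reference) < 2)
    stop("reference must contain at least 2 subjects")
  key <- interaction(table$electrode, table$band, drop = TRUE)
  out <- table
  for (m in measure) {
    for (k in levels(key)) {
      sel <- key == k
      ref <- sel & table$subject_id %in% reference
      mu <- mean(table[[m]][ref]); sdv <- stats::sd(table[[m]][ref])
      if (!is.finite(sdv) || sdv == 0)
        stop(sprintf("zero SD in reference for feature %s (%s)", k, m))
      out[[m]][sel] <- (table[[m]][sel] - mu) / sdv
    }
  }
  out
}

#' Groupwise band-power comparison with FDR correction
#'
#' Two-sided Mann-Whitney test per electrode x band feature
#' ([mann_whitney()]: exact enumeration for small groups, tie-corrected
#' normal approximation otherwise), with Benjamini-Hochberg q-values
#' computed across all features in the call. The reported direction is
#' the sign of the rank difference of the first group named in
#' `group_order` minus the second.
#'
#' @param table band-power table from [band_power()] (must carry a
#'   `group` column, or supply `labels`).
#' @param labels optional per-row group labels overriding
#'   `table$group`.
#' @param measure which power measure to test (default relative).
#' @param group_order character vector of length 2; the test direction
#'   is group_order[1] minus group_order[2]. Defaults to
#'   `c("SCZ", "HC")` when those labels are present.
#' @return data.frame: `electrode`, `band`, `U`, `p`, `q`, `direction`.
#' @export
group_band_comparison <- function(table, labels = NULL,
                                  measure = c("rel_power", "abs_power"),
                                  group_order = NULL) {
  measure <- match.arg(measure)
  grp <- if (is.null(labels)) {
    table$group
  } else if (length(labels) == nrow(table)) {
    labels
  } else {
    # per-subject labels: expand over the long table by subject order
    subs <- unique(table$subject_id)
    if (length(labels) != length(subs))
      stop(sprintf("`labels` must have one entry per row (%d) or per subject (%d)",
                   nrow(table), length(subs)))
    labels[match(table$subject_id, subs)]
  }
  if (is.null(grp) || anyNA(grp)) stop("group labels are required")
  lev <- unique(grp)
  if (length(lev) != 2) stop("exactly two groups are required")
  group_order <- group_order %||%
    (if (all(c("SCZ", "HC") %in% lev)) c("SCZ", "HC") else lev)
  g1 <- group_order[1]; g2 <- group_order[2]
  if (!all(c(g1, g2) %in% lev)) stop("`group_order` must match the labels")
  feats <- unique(table[, c("electrode", "band")])
  res <- lapply(seq_len(nrow(feats)), function(i) {
    sel <- table$electrode == feats$electrode[i] & table$band == feats$band[i]
    xv <- table[[measure]][sel & grp == g1]
    yv <- table[[measure]][sel & grp == g2]
    mw <- mann_whitney(xv, yv)
    data.frame(electrode = feats$electrode[i], band = feats$band[i],
               U = mw$statistic, p = mw$p, direction = mw$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- fdr_bh(out$p)
  out[, c("electrode", "band", "U", "p", "q", "direction")]
}
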