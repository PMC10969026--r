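# Hann-windowed averaged periodogram (Welch) of one real series
welch_psd <- function(x, fs, seg_len = 512, overlap = 0.5) {
  n <- length(x)
  if (seg_len > n) stop("series shorter than one segment", call. = FALSE)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1))) # Hann
  scale <- fs * sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything but DC (and Nyquist for even seg_len)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

#' Per-region power spectra
#'
#' Welch-style averaged-periodogram estimate of the power spectral density
#' of every region: the series is split into mean-centered Hann-windowed
#' segments with the given overlap and the segment periodograms are
#' averaged. Optionally each region's spectrum is max-normalized (display
#' parity with normalized-spectrum plots).
#'
#' @param series A [region_ts()] with at least 256 samples.
#' @param seg_len Segment length in samples (default 512).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param normalize Divide each region's PSD by its maximum.
#' @return Object of class `region_spectra`: `freq` (Hz), `psd`
#'   (N x n_freq, nonnegative), `labels`.
#' @export
power_spectrum <- function(series, seg_len = 512, overlap = 0.5,
                           normalize = FALSE) {
  x <- series$values
  if (ncol(x) < 256L) stop("need at least 256 samples", call. = FALSE)
  first <- welch_psd(x[1L, ], series$fs, seg_len, overlap)
  psd <- matrix(0, nrow(x), length(first$freq))
  psd[1L, ] <- first$psd
  if (nrow(x) > 1L) {
    for (i in 2:nrow(x)) {
      psd[i, ] <- welch_psd(x[i, ], series$fs, seg_len, overlap)$psd
    }
  }
  if (normalize) {
    mx <- apply(psd, 1L, max)
    psd <- psd / ifelse(mx > 0, mx, 1)
  }
  rownames(psd) <- series$labels
  structure(list(freq = first$freq, psd = psd, labels = series$labels),
            class = "region_spectra")
}

#' Dominant frequency per region
#'
#' Location of the maximum of each region's PSD within a search band; ties
#' are broken toward the lower frequency.
#'
#' @param spectrum A `region_spectra` from [power_spectrum()].
#' @param band Length-2 search band in Hz (default 0.5-45).
#' @return Named numeric vector of peak frequencies (Hz).
#' @export
dominant_frequency <- function(spectrum, band = c(0.5, 45)) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel)) stop("band outside the spectral grid", call. = FALSE)
  f <- spectrum$freq[sel]
  apply_peak <- function(p) {
    if (max(p) <= 0) {
      stop("flat zero spectrum: dominant frequency undefined", call. = FALSE)
    }
    f[which.max(p)] # which.max returns the first (lowest-frequency) maximum
  }
  stats::setNames(apply(spectrum$psd[, sel, drop = FALSE], 1L, apply_peak),
                  spectrum$labels)
}

#' Baseline potential per region
#'
#' The baseline is the temporal mean of the retained (post-transient)
#' output potential of each region, in mV.
#'
#' @param series A [region_ts()].
#' @return Named numeric vector (mV).
#' @export
baseline_potential <- function(series) {
  if (ncol(series$values) == 0L) stop("empty series", call. = FALSE)
  stats::setNames(rowMeans(series$values), series$labels)
}

#' Per-region feature table
#'
#' Baseline potential and dominant frequency for every region. When a list
#' of repetitions is given, baselines are averaged across repetitions and
#' the dominant frequency is taken from the repetition-averaged PSD.
#'
#' @param series A [region_ts()] or a list of them (repetitions).
#' @param band Dominant-frequency search band (Hz).
#' @param seg_len,overlap Spectral estimator settings, see
#'   [power_spectrum()].
#' @return `data.frame` with columns `region_index`, `label`,
#'   `baseline_mV`, `dominant_freq_Hz`.
#' @export
region_features <- function(series, band = c(0.5, 45), seg_len = 512,
                            overlap = 0.5) {
  reps <- if (inherits(series, "region_ts")) list(series) else series
  n <- nrow(reps[[1]]$values)
  base <- rowMeans(matrix(vapply(reps, baseline_potential, numeric(n)),
                          nrow = n))
  specs <- lapply(reps, power_spectrum, seg_len = seg_len, overlap = overlap)
  mean_spec <- specs[[1]]
  if (length(specs) > 1L) {
    mean_spec$psd <- Reduce(`+`, lapply(specs, `[[`, "psd")) / length(specs)
  }
  dom <- dominant_frequency(mean_spec, band)
  data.frame(region_index = seq_along(base),
             label = reps[[1]]$labels,
             baseline_mV = unname(base),
             dominant_freq_Hz = unname(dom))
}
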