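# FFT-based analytic signal (discrete Hilbert transform); x real, demeaned
analytic_signal <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1L] <- 1
  if (n %% 2L == 0L) {
    w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * w, inverse = TRUE) / n
}

# inclusive numeric grid robust to floating-point endpoint drift
inclusive_grid <- function(lo, hi, step) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (lo > hi) stop("grid lower bound exceeds upper bound", call. = FALSE)
  k <- floor((hi - lo) / step + 1e-9)
  lo + step * 0:k
}

#' Instantaneous phase via the Hilbert transform
#'
#' Extracts per-region instantaneous phases: each region's series is
#' mean-centered, optionally band-pass filtered (zero-phase, 4th-order
#' Butterworth applied forward and backward), converted to its analytic
#' signal, and the phase angle is returned. No unwrapping is applied (none
#' is needed for phase-locking values).
#'
#' @param series A [region_ts()].
#' @param band Optional length-2 frequency interval (Hz) strictly inside
#'   `(0, fs/2)`; `NULL` (default) applies no filtering.
#' @return Object of class `phase_mat`: list with `theta` (N x T radians)
#'   and `fs`.
#' @export
instantaneous_phase <- function(series, band = NULL) {
  x <- series$values
  if (ncol(x) < 16L) stop("need at least 16 samples", call. = FALSE)
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] <= 0 || band[2] >= series$fs / 2 ||
        band[1] >= band[2]) {
      stop("band must lie strictly inside (0, fs/2)", call. = FALSE)
    }
    bf <- signal::butter(4, band / (series$fs / 2), type = "pass")
  }
  theta <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ] - mean(x[i, ])
    if (!is.null(band)) xi <- signal::filtfilt(bf, xi)
    if (all(abs(xi) < .Machine$double.eps * 100)) {
      stop(sprintf("region %d: constant signal, phase undefined", i),
           call. = FALSE)
    }
    theta[i, ] <- Arg(analytic_signal(xi))
  }
  structure(list(theta = theta, fs = series$fs, labels = series$labels),
            class = "phase_mat")
}

#' Phase-locking value between two regions
#'
#' Modulus of the time-averaged unit phasor of the phase difference,
#' `|mean_t exp(i (theta_i(t) - theta_j(t)))|`. Equals 1 when the phase
#' difference is constant over the window and approaches 0 for uniformly
#' distributed phase differences.
#'
#' @param phases A `phase_mat` from [instantaneous_phase()], or a plain
#'   N x T matrix of phases in radians.
#' @param i,j Region indices.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phases, i, j) {
  theta <- if (inherits(phases, "phase_mat")) phases$theta else as.matrix(phases)
  if (i < 1 || j < 1 || i > nrow(theta) || j > nrow(theta)) {
    stop("region index out of bounds", call. = FALSE)
  }
  min(Mod(mean(exp(1i * (theta[i, ] - theta[j, ])))), 1)
}

#' Functional connectivity matrix container
#'
#' @param rho N x N symmetric matrix of PLV values in `[0, 1]`; the
#'   diagonal is fixed at 1 by convention.
#' @param labels Region labels.
#' @return Object of class `fc_mat`.
#' @export
fc_mat <- function(rho, labels = NULL) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("FC matrix must be square", call. = FALSE)
  if (max(abs(rho - t(rho))) > 1e-10) {
    stop("FC matrix must be symmetric", call. = FALSE)
  }
  if (any(rho < -1e-12) || any(rho > 1 + 1e-12)) {
    stop("PLV entries must lie in [0, 1]", call. = FALSE)
  }
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  if (is.null(labels)) labels <- default_labels(nrow(rho))
  dimnames(rho) <- list(labels, labels)
  structure(list(rho = rho, labels = labels), class = "fc_mat")
}

#' @export
print.fc_mat <- function(x, ...) {
  off <- x$rho[lower.tri(x$rho)]
  cat(sprintf("PLV functional connectivity: %d regions, mean off-diagonal %.4f\n",
              nrow(x$rho), mean(off)))
  invisible(x)
}

#' All-pairs PLV functional connectivity
#'
#' Computes the full phase-locking-value matrix of a set of regional time
#' series: phases by [instantaneous_phase()], then every pairwise PLV.
#' Computed in one pass as `|Z Z* / T|` with `Z = exp(i theta)`.
#'
#' @inheritParams instantaneous_phase
#' @return An [fc_mat()].
#' @export
fc_matrix <- function(series, band = NULL) {
  if (nrow(series$values) < 2L) stop("need at least 2 regions", call. = FALSE)
  ph <- instantaneous_phase(series, band)
  z <- exp(1i * ph$theta)
  rho <- Mod(z %*% Conj(t(z))) / ncol(ph$theta)
  rho <- pmin(rho, 1)
  fc_mat(rho, series$labels)
}

#' Element-wise average of FC matrices
#'
#' Arithmetic mean across a list of FC matrices (e.g. one per simulation
#' repetition or per subject); the diagonal is reset to 1.
#'
#' @param fcs Non-empty list of [fc_mat()] objects of equal size.
#' @return An [fc_mat()].
#' @export
average_fc <- function(fcs) {
  if (length(fcs) == 0L) stop("empty FC list", call. = FALSE)
  dims <- vapply(fcs, function(f) nrow(f$rho), integer(1))
  if (length(unique(dims)) != 1L) stop("FC shape mismatch", call. = FALSE)
  m <- Reduce(`+`, lapply(fcs, `[[`, "rho")) / length(fcs)
  fc_mat(m, fcs[[1]]$labels)
}

#' Similarity of two FC matrices
#'
#' Pearson correlation between the strictly-lower-triangle entries of the
#' simulated and reference FC matrices (diagonal excluded), the fitting
#' criterion for the global coupling coefficient.
#'
#' @param sim,ref [fc_mat()] objects of equal size (N >= 3).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
fc_similarity <- function(sim, ref) {
  if (nrow(sim$rho) != nrow(ref$rho)) stop("FC size mismatch", call. = FALSE)
  if (nrow(sim$rho) < 3L) stop("need at least 3 regions", call. = FALSE)
  a <- sim$rho[lower.tri(sim$rho)]
  b <- ref$rho[lower.tri(ref$rho)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a lower triangle: correlation undefined",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Sweep the global coupling coefficient
#'
#' For each coupling value `C` on the inclusive grid, simulates the network
#' (`n_reps` repetitions), computes the PLV FC matrix of every repetition,
#' averages them, and correlates the result with the reference FC via
#' [fc_similarity()]. Returns the full correlation-versus-coupling curve
#' and its argmax (ties broken toward the smallest `C`). Grid points where
#' the integration diverges are recorded as `NA` and do not abort the
#' sweep.
#'
#' @param connectome A [connectome()].
#' @param params A [wendling_params()].
#' @param config A [simulation_config()].
#' @param ref Reference [fc_mat()] to fit against.
#' @param c_min,c_max,c_step Inclusive sweep grid for the coupling
#'   coefficient.
#' @param band Optional band-pass (Hz) applied before phase extraction.
#' @return Object of class `coupling_sweep` with `c_values`, `pcc_values`,
#'   `best_c`, `best_pcc`.
#' @export
sweep_coupling <- function(connectome, params = wendling_params(),
                           config = simulation_config(), ref,
                           c_min = 0, c_max = 80, c_step = 0.1,
                           band = NULL) {
  grid <- inclusive_grid(c_min, c_max, c_step)
  pcc <- vapply(grid, function(cv) {
    tryCatch({
      sys <- coupled_system(params, connectome, c_global = cv)
      reps <- simulate_repetitions(sys, config)
      sim_fc <- average_fc(lapply(reps, fc_matrix, band = band))
      fc_similarity(sim_fc, ref)
    }, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(pcc))) {
    stop("coupling sweep failed at every grid point", call. = FALSE)
  }
  best <- which.max(pcc) # first maximum = smallest C on ties
  structure(list(c_values = grid, pcc_values = pcc,
                 best_c = grid[best], best_pcc = pcc[best]),
            class = "coupling_sweep")
}

#' @export
print.coupling_sweep <- function(x, ...) {
  cat(sprintf("Coupling sweep: %d grid points in [%g, %g]\n",
              length(x$c_values), min(x$c_values), max(x$c_values)))
  cat(sprintf("  best C = %g with PCC = %.4f\n", x$best_c, x$best_pcc))
  if (anyNA(x$pcc_values)) {
    cat(sprintf("  %d grid point(s) diverged (PCC unavailable)\n",
                sum(is.na(x$pcc_values))))
  }
  invisible(x)
}
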