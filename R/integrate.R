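#' Simulation configuration
#'
#' Settings for the fixed-step stochastic simulation: sampling rate `fs`
#' (Hz; the RK4 step is `1/fs`), total simulated `duration` (s), leading
#' `transient` (s) discarded from the output, number of repetitions with
#' different initial values, the master seed, and the amplitude
#' `init_scale` (mV) of the uniform random initial conditions.
#'
#' @param fs Sampling rate in Hz (default 1000; integration step `1/fs` s).
#' @param duration Total simulated time in seconds (default 2).
#' @param transient Leading time discarded, in seconds (default 1).
#' @param n_reps Number of repetitions with different initial values
#'   (default 20).
#' @param seed Master random seed (integer).
#' @param init_scale Initial state components are drawn uniformly from
#'   `[0, init_scale]` (default 0.1 mV).
#'
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(fs = 1000, duration = 2, transient = 1,
                              n_reps = 20, seed = 1, init_scale = 0.1) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (transient < 0 || transient >= duration) {
    stop("need 0 <= transient < duration", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(fs = fs, duration = duration, transient = transient,
                 n_reps = n_reps, seed = seed, init_scale = init_scale),
            class = "sim_config")
}

# deterministic substream seed for repetition `rep` (0-based)
substream_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + rep * 9973 + 1) %% 2147483647L
}

#' Regional time-series container
#'
#' Post-transient simulated pyramidal outputs for all regions at a fixed
#' sampling rate.
#'
#' @param values N x T numeric matrix of region outputs (mV).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first retained sample (s).
#' @param labels Region labels (length N).
#' @return Object of class `region_ts`.
#' @export
region_ts <- function(values, fs, t0 = 0, labels = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("region_ts values must be finite", call. = FALSE)
  }
  if (is.null(labels)) labels <- default_labels(nrow(values))
  rownames(values) <- labels
  structure(list(values = values, fs = fs, t0 = t0, labels = labels),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("Region time series: %d regions x %d samples @ %g Hz (t0 = %g s)\n",
              nrow(x$values), ncol(x$values), x$fs, x$t0))
  invisible(x)
}

#' Simulate the coupled whole-brain model
#'
#' Integrates the coupled system with classic fourth-order Runge-Kutta at
#' fixed step `h = 1/fs`. At every step one Gaussian external input sample
#' `p_i ~ N(mu, sigma2)` is drawn per region and held constant across the
#' four RK4 stages of that step. Initial state components are drawn
#' uniformly from `[0, init_scale]`. The first `transient * fs` samples are
#' discarded and the pyramidal output `y1 - y2 - y3` of the retained
#' trajectory is returned. Fully reproducible from `(seed, rep)`.
#'
#' @param system A [coupled_system()].
#' @param config A [simulation_config()].
#' @param rep Repetition index (0-based) selecting the random substream.
#' @param noise Optional N x n_steps matrix of external input samples,
#'   overriding the seeded Gaussian draw (used to match noise streams
#'   across runs).
#' @param init Optional N x 10 matrix of initial states, overriding the
#'   seeded uniform draw.
#' @return A [region_ts()] with `round((duration - transient) * fs)`
#'   samples per region.
#' @export
simulate_network <- function(system, config = simulation_config(),
                             rep = 0, noise = NULL, init = NULL) {
  n <- n_regions(system$connectome)
  h <- 1 / config$fs
  n_steps <- round(config$duration * config$fs)
  n_drop <- round(config$transient * config$fs)

  if (is.null(noise) || is.null(init)) {
    set.seed(substream_seed(config$seed, rep))
    if (is.null(init)) {
      init <- matrix(stats::runif(n * 10L, 0, config$init_scale), n, 10L)
    }
    if (is.null(noise)) {
      noise <- matrix(stats::rnorm(n * n_steps, mean = system$params$mu,
                                   sd = sqrt(system$params$sigma2)),
                      n, n_steps)
    }
  }
  stopifnot(nrow(noise) == n, ncol(noise) == n_steps,
            nrow(init) == n, ncol(init) == 10L)

  cs <- system$c_global * system$connectome$weights
  par <- unlist(system$params[c("A", "B", "G", "a", "b", "g",
                                paste0("C", 1:7), "v0", "e0", "r")])
  res <- .rk4_core(init, cs, par, noise, h)
  keep <- seq.int(n_drop + 1L, n_steps)
  region_ts(res$output[, keep, drop = FALSE], fs = config$fs,
            t0 = (n_drop + 1L) * h, labels = system$connectome$labels)
}

#' Repeat the simulation with different initial values
#'
#' Runs [simulate_network()] `n_reps` times; repetition `r` uses the random
#' substream derived from `(seed, r - 1)` for both its initial conditions
#' and its noise stream, so repetitions are independent and individually
#' reproducible.
#'
#' @inheritParams simulate_network
#' @return List of [region_ts()], length `config$n_reps`.
#' @export
simulate_repetitions <- function(system, config = simulation_config()) {
  lapply(seq_len(config$n_reps), function(r) {
    tryCatch(simulate_network(system, config, rep = r - 1L),
             error = function(e) {
               stop(sprintf("repetition %d: %s", r, conditionMessage(e)),
                    call. = FALSE)
             })
  })
}
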