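#' Standard Wendling neural-mass parameters
#'
#' Constructs the full parameter set of a Wendling four-population neural
#' mass (pyramidal cells, excitatory interneurons, slow GABA_B-like and fast
#' GABA_A-like inhibitory interneurons). Defaults are the standard values of
#' the model: synaptic gains `A`, `B`, `G` (mV), reciprocal time constants
#' `a`, `b`, `g` (1/s), synaptic contact counts `C1`..`C7` (dimensionless),
#' sigmoid parameters `v0` (mV), `e0` (1/s), `r` (1/mV), and the mean `mu`
#' and variance `sigma2` of the Gaussian external pulse-density input.
#'
#' @param A Average excitatory synaptic gain (mV).
#' @param B Average slow inhibitory synaptic gain (mV).
#' @param G Average fast inhibitory synaptic gain (mV).
#' @param a,b,g Reciprocal average time constants (1/s) of the excitatory,
#'   slow-inhibitory and fast-inhibitory post-synaptic kernels.
#' @param C1,C2,C3,C4,C5,C6,C7 Average synaptic contact counts of the
#'   excitatory (`C1`,`C2`), slow inhibitory (`C3`,`C4`) and fast inhibitory
#'   (`C5`,`C6`,`C7`) feedback loops.
#' @param v0 Half-activation potential of the sigmoid (mV).
#' @param e0 Half of the maximum firing rate (1/s).
#' @param r Sigmoid slope (1/mV).
#' @param mu Mean of the external input pulse density (1/s).
#' @param sigma2 Variance of the external input.
#'
#' @return An object of class `wendling_params` (a named list).
#' @examples
#' p <- wendling_params()
#' p$A  # 3.25 mV
#' @export
wendling_params <- function(A = 3.25, B = 22, G = 10,
                            a = 100, b = 50, g = 500,
                            C1 = 135, C2 = 108,
                            C3 = 33.75, C4 = 33.75,
                            C5 = 40.5, C6 = 13.5, C7 = 108,
                            v0 = 6, e0 = 2.5, r = 0.56,
                            mu = 90, sigma2 = 30) {
  p <- list(A = A, B = B, G = G, a = a, b = b, g = g,
            C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5, C6 = C6, C7 = C7,
            v0 = v0, e0 = e0, r = r, mu = mu, sigma2 = sigma2)
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("all Wendling parameters must be finite", call. = FALSE)
  }
  # sigma2 = 0 is the deterministic limit and is allowed; everything else
  # must be strictly positive for the model to make physical sense
  strict <- vals[setdiff(names(p), "sigma2")]
  if (any(strict <= 0) || sigma2 < 0) {
    stop("Wendling parameters must be strictly positive (sigma2 >= 0)",
         call. = FALSE)
  }
  structure(p, class = "wendling_params")
}

#' @export
print.wendling_params <- function(x, ...) {
  cat("Wendling neural-mass parameters\n")
  cat(sprintf("  gains (mV):          A = %g, B = %g, G = %g\n",
              x$A, x$B, x$G))
  cat(sprintf("  rate constants (1/s): a = %g, b = %g, g = %g\n",
              x$a, x$b, x$g))
  cat(sprintf("  contacts:            C1..C7 = %s\n",
              paste(unlist(x[paste0("C", 1:7)]), collapse = ", ")))
  cat(sprintf("  sigmoid:             v0 = %g mV, e0 = %g 1/s, r = %g 1/mV\n",
              x$v0, x$e0, x$r))
  cat(sprintf("  input:               mu = %g, sigma2 = %g\n",
              x$mu, x$sigma2))
  invisible(x)
}

is_wendling_params <- function(x) inherits(x, "wendling_params")
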