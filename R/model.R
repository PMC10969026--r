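#' Potential-to-firing-rate sigmoid
#'
#' The nonlinear conversion from mean membrane potential to population
#' firing rate, `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`. It saturates at
#' `2 e0`, equals `e0` at the half-activation potential `v0`, and its slope
#' at `v0` is controlled by `r`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param params A [wendling_params()] object.
#' @return Firing rate(s) in (0, 2 e0), 1/s.
#' @examples
#' sigmoid(6)            # e0 = 2.5 at the half-activation potential
#' sigmoid(c(-Inf, Inf)) # saturation limits 0 and 2 e0
#' @export
sigmoid <- function(v, params = wendling_params()) {
  if (any(is.na(v))) stop("sigmoid: v must not contain NA", call. = FALSE)
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

#' Pyramidal output of one region
#'
#' The model output of a region is the net post-synaptic potential of its
#' pyramidal population: the excitatory kernel output minus the slow and
#' fast inhibitory kernel outputs, `y1 - y2 - y3`.
#'
#' @param state_row Numeric vector of length 10: kernel outputs `y0..y4`
#'   followed by their derivatives `y5..y9`.
#' @return Membrane potential (mV).
#' @export
node_output <- function(state_row) {
  if (length(state_row) != 10L) {
    stop("node_output: state_row must have length 10", call. = FALSE)
  }
  state_row[2L] - state_row[3L] - state_row[4L]
}

# outputs for all regions at once; state is N x 10
network_output <- function(state) {
  state[, 2L] - state[, 3L] - state[, 4L]
}

#' Vector field of the coupled whole-brain model
#'
#' Evaluates the time derivative of the full network state. Each region is a
#' 10-state Wendling node; regions interact through one excitatory term on
#' the pyramidal input kernel, `c_global * sum_j w[i,j] * S(y_out_j)`, where
#' `y_out_j` is region j's pyramidal output. The external pulse density `p`
#' for the step is supplied by the caller (the integrator samples it), so
#' this evaluation is deterministic and side-effect free.
#'
#' @param state N x 10 numeric matrix (row = region, columns `y0..y9`).
#' @param system A [coupled_system()].
#' @param p External input pulse density per region (1/s), length N.
#' @return N x 10 matrix of derivatives.
#' @export
network_derivatives <- function(state, system, p) {
  state <- as.matrix(state)
  n <- n_regions(system$connectome)
  if (nrow(state) != n || ncol(state) != 10L) {
    stop("network_derivatives: state must be N x 10 with N matching the ",
         "connectome", call. = FALSE)
  }
  if (length(p) != n) {
    stop("network_derivatives: p must have one entry per region",
         call. = FALSE)
  }
  if (any(!is.finite(state))) {
    stop("network_derivatives: non-finite state", call. = FALSE)
  }
  pr <- system$params
  y0 <- state[, 1L]; y1 <- state[, 2L]; y2 <- state[, 3L]; y3 <- state[, 4L]
  y4 <- state[, 5L]; y5 <- state[, 6L]; y6 <- state[, 7L]; y7 <- state[, 8L]
  y8 <- state[, 9L]; y9 <- state[, 10L]

  coupling <- if (system$c_global > 0) {
    system$c_global *
      as.vector(system$connectome$weights %*% sigmoid(y1 - y2 - y3, pr))
  } else {
    numeric(n)
  }

  d <- matrix(0, n, 10L)
  d[, 1L] <- y5
  d[, 2L] <- y6
  d[, 3L] <- y7
  d[, 4L] <- y8
  d[, 5L] <- y9
  d[, 6L] <- pr$A * pr$a * sigmoid(y1 - y2 - y3, pr) -
    2 * pr$a * y5 - pr$a^2 * y0
  d[, 7L] <- pr$A * pr$a *
    (p + coupling + pr$C2 * sigmoid(pr$C1 * y0, pr)) -
    2 * pr$a * y6 - pr$a^2 * y1
  d[, 8L] <- pr$B * pr$b * pr$C4 * sigmoid(pr$C3 * y0, pr) -
    2 * pr$b * y7 - pr$b^2 * y2
  d[, 9L] <- pr$G * pr$g * pr$C7 * sigmoid(pr$C5 * y0 - y4, pr) -
    2 * pr$g * y8 - pr$g^2 * y3
  d[, 10L] <- pr$B * pr$b * pr$C6 * sigmoid(pr$C3 * y0, pr) -
    2 * pr$b * y9 - pr$b^2 * y4
  d
}
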