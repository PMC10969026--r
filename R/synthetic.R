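#' Synthetic structural connectome
#'
#' Generates a connectome with the statistical structure of group-averaged
#' max-normalized fiber-count matrices: symmetric, nonnegative, zero
#' diagonal, global maximum 1, and a hemispheric block structure in which
#' intra-hemispheric connections are on average stronger than
#' inter-hemispheric ones. Nonzero weights are drawn log-normally
#' (fiber-count distributions are heavy-tailed); `density` controls the
#' fraction of connected region pairs.
#'
#' @param n_regions Even number of regions (default 68, two hemispheres of
#'   34).
#' @param intra_meanlog,inter_meanlog Log-scale means of the weight
#'   magnitudes within and between hemispheres (intra must exceed inter by
#'   default: 0 vs -1).
#' @param sdlog Log-scale standard deviation of the weights (default 0.9).
#' @param density Fraction of region pairs with a nonzero connection, in
#'   (0, 1] (default 0.6).
#' @param seed Seed controlling the draw.
#' @return A [connectome()] with Desikan-Killiany labels when
#'   `n_regions = 68`.
#' @export
make_synthetic_sc <- function(n_regions = 68, intra_meanlog = 0,
                              inter_meanlog = -1, sdlog = 0.9,
                              density = 0.6, seed = 1) {
  if (n_regions %% 2L != 0L || n_regions < 4L) {
    stop("n_regions must be even and >= 4", call. = FALSE)
  }
  if (density <= 0 || density > 1) {
    stop("density must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  half <- n_regions %/% 2L
  hemi <- rep(c("L", "R"), each = half)
  w <- matrix(0, n_regions, n_regions)
  iu <- which(upper.tri(w), arr.ind = TRUE)
  same_hemi <- hemi[iu[, 1L]] == hemi[iu[, 2L]]
  present <- stats::runif(nrow(iu)) < density
  if (!any(present)) {
    stop("generated connectome is edgeless; increase density", call. = FALSE)
  }
  meanlog <- ifelse(same_hemi, intra_meanlog, inter_meanlog)
  vals <- ifelse(present,
                 stats::rlnorm(nrow(iu), meanlog = meanlog, sdlog = sdlog),
                 0)
  w[iu] <- vals
  w <- w + t(w)
  w <- w / max(w)
  connectome(w, hemisphere = hemi)
}

#' Model-generated reference FC matrix
#'
#' Runs the full simulate-to-PLV pipeline at a known coupling value
#' `c_star` and returns the repetition-averaged FC matrix. This serves as
#' a self-consistent ground truth for coupling-recovery experiments when
#' no empirical FC matrix is available.
#'
#' @param connectome A [connectome()].
#' @param params A [wendling_params()].
#' @param config A [simulation_config()] (its `seed` fixes the draw).
#' @param c_star Coupling coefficient used to generate the reference.
#' @param band Optional band-pass before phase extraction.
#' @return An [fc_mat()].
#' @export
make_reference_fc <- function(connectome, params = wendling_params(),
                              config = simulation_config(), c_star,
                              band = NULL) {
  sys <- coupled_system(params, connectome, c_global = c_star)
  reps <- simulate_repetitions(sys, config)
  average_fc(lapply(reps, fc_matrix, band = band))
}

#' Canonical test graphs
#'
#' Standard graph constructions used to exercise the graph measures:
#' complete, ring lattice (each node linked to its `k/2` nearest neighbors
#' per side), Watts-Strogatz small-world (ring lattice with rewiring
#' probability `p`), uniform random G(n, m), path, and star.
#'
#' @param kind One of `"complete"`, `"ring_lattice"`, `"watts_strogatz"`,
#'   `"random"`, `"path"`, `"star"`.
#' @param size Number of nodes (>= 3).
#' @param k Even neighborhood size for lattice/small-world kinds
#'   (default 6).
#' @param p Rewiring probability for `"watts_strogatz"` (default 0.1).
#' @param m Edge count for `"random"` (defaults to `size * k / 2`).
#' @param seed Seed for the random kinds.
#' @return An [adjacency()].
#' @export
make_canonical_graph <- function(kind = c("complete", "ring_lattice",
                                          "watts_strogatz", "random",
                                          "path", "star"),
                                 size, k = 6, p = 0.1, m = NULL,
                                 seed = 1) {
  kind <- match.arg(kind)
  if (size < 3) stop("size must be >= 3", call. = FALSE)
  set.seed(seed)
  g <- switch(kind,
    complete = igraph::make_full_graph(size),
    ring_lattice = igraph::sample_smallworld(1, size, k %/% 2L, p = 0),
    watts_strogatz = igraph::sample_smallworld(1, size, k %/% 2L, p = p),
    random = igraph::sample_gnm(size,
                                if (is.null(m)) size * k %/% 2L else m),
    path = igraph::make_ring(size, circular = FALSE),
    star = igraph::make_star(size, mode = "undirected")
  )
  adjacency(as.matrix(igraph::as_adjacency_matrix(g)),
            labels = sprintf("N%03d", seq_len(size)))
}
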