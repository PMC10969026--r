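#' Binary adjacency matrix container
#'
#' @param a N x N binary matrix (symmetric, zero diagonal).
#' @param threshold Threshold used to produce it (or `NA`).
#' @param labels Region labels.
#' @return Object of class `adjacency`.
#' @export
adjacency <- function(a, threshold = NA_real_, labels = NULL) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(a != t(a))) stop("adjacency must be symmetric", call. = FALSE)
  diag(a) <- 0
  storage.mode(a) <- "double"
  if (is.null(labels)) labels <- default_labels(nrow(a))
  dimnames(a) <- list(labels, labels)
  structure(list(a = a, threshold = threshold, labels = labels),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("Adjacency: %d nodes, %d edges (threshold %s)\n",
              nrow(x$a), sum(x$a) / 2,
              ifelse(is.na(x$threshold), "-", format(x$threshold))))
  invisible(x)
}

as_weight_matrix <- function(weights) {
  if (inherits(weights, "fc_mat")) weights$rho
  else if (inherits(weights, "connectome")) weights$weights
  else as.matrix(weights)
}

weight_labels <- function(weights, n) {
  if (inherits(weights, c("fc_mat", "connectome"))) weights$labels
  else if (!is.null(rownames(weights))) rownames(weights)
  else default_labels(n)
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj$a, mode = "undirected",
                                      diag = FALSE)
}

#' Absolute thresholding of a weight matrix
#'
#' Binarizes a (functional connectivity) weight matrix: off-diagonal
#' entries greater than or equal to the threshold become edges; the
#' diagonal is always zero regardless of the weight diagonal.
#'
#' @param weights An [fc_mat()], [connectome()] or plain symmetric matrix.
#' @param t Threshold (the `>=` rule is inclusive).
#' @return An [adjacency()].
#' @export
threshold_adjacency <- function(weights, t) {
  w <- as_weight_matrix(weights)
  if (!is.finite(t)) stop("threshold must be finite", call. = FALSE)
  a <- (w >= t) * 1
  diag(a) <- 0
  adjacency(a, threshold = t, labels = weight_labels(weights, nrow(w)))
}

#' Threshold grid
#'
#' Inclusive grid of thresholds; the defaults (0 to 0.5 in steps of 0.01)
#' produce 51 values.
#'
#' @param t_min,t_max,step Grid bounds and step (step > 0).
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(t_min = 0, t_max = 0.5, step = 0.01) {
  inclusive_grid(t_min, t_max, step)
}

#' Node strength
#'
#' Per-node sum of off-diagonal edge weights of the weighted matrix (not
#' the binarized graph); high-strength nodes are network hubs.
#'
#' @param weights An [fc_mat()], [connectome()] or plain symmetric matrix.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(weights) {
  w <- as_weight_matrix(weights)
  diag(w) <- 0
  stats::setNames(rowSums(w), weight_labels(weights, nrow(w)))
}

#' Node degrees and average degree
#'
#' @param adj An [adjacency()].
#' @return List with `degree` (per node) and `average`.
#' @export
degrees <- function(adj) {
  d <- rowSums(adj$a)
  list(degree = stats::setNames(d, adj$labels), average = mean(d))
}

# hop-count distance matrix (Inf for unreachable pairs)
hop_distances <- function(adj) {
  igraph::distances(as_igraph(adj))
}

#' Characteristic path length
#'
#' Average unweighted shortest-path hop count over ordered node pairs.
#' Unreachable pairs are excluded from the average and their count is
#' reported alongside (a convention needed only above the threshold where
#' the graph fragments).
#'
#' @param adj An [adjacency()] with at least one edge.
#' @return List with `L` and `unreachable_pairs` (count of ordered pairs).
#' @export
characteristic_path_length <- function(adj) {
  if (sum(adj$a) == 0) {
    stop("characteristic path length undefined for an edgeless graph",
         call. = FALSE)
  }
  d <- hop_distances(adj)
  off <- d[row(d) != col(d)]
  list(L = mean(off[is.finite(off)]),
       unreachable_pairs = sum(!is.finite(off)))
}

#' Clustering coefficients
#'
#' Per-node local clustering `2 e_i / (k_i (k_i - 1))` (the fraction of
#' realized edges among node i's neighbors; 0 for nodes of degree < 2) and
#' the global coefficient, their mean over all N nodes.
#'
#' @param adj An [adjacency()].
#' @return List with `per_node` and `global`.
#' @export
clustering_coefficients <- function(adj) {
  cc <- igraph::transitivity(as_igraph(adj), type = "local",
                             isolates = "zero")
  list(per_node = stats::setNames(cc, adj$labels), global = mean(cc))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered node pairs, with zero
#' contribution from unreachable pairs; 1 for a complete graph, 0 for an
#' edgeless one.
#'
#' @param adj An [adjacency()].
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  if (sum(adj$a) == 0) return(0)
  d <- hop_distances(adj)
  inv <- 1 / d[row(d) != col(d)] # 1/Inf = 0 for unreachable pairs
  mean(inv)
}

#' Number of connected (non-isolated) nodes
#'
#' @param adj An [adjacency()].
#' @return Count of nodes with degree >= 1.
#' @export
count_connected_nodes <- function(adj) {
  sum(rowSums(adj$a) >= 1)
}

#' Random reference networks
#'
#' Ensemble means of the clustering coefficient and characteristic path
#' length over uniform random graphs with the same numbers of nodes and
#' edges as `adj` (Erdos-Renyi G(n, m)); optionally degree-preserving
#' rewiring instead. Realizations that fragment are retained with the same
#' unreachable-pair convention as [characteristic_path_length()].
#'
#' @param adj An [adjacency()] with at least one edge.
#' @param n_realizations Number of random realizations (>= 1).
#' @param seed Seed for the ensemble.
#' @param method `"gnm"` (uniform with matched node and edge counts,
#'   default) or `"rewire"` (degree-preserving edge swaps).
#' @return List with `cc_random`, `l_random`, `n_realizations`.
#' @export
random_reference <- function(adj, n_realizations = 20, seed = 1,
                             method = c("gnm", "rewire")) {
  method <- match.arg(method)
  m <- sum(adj$a) / 2
  if (m == 0) stop("random reference needs at least one edge", call. = FALSE)
  if (n_realizations < 1) stop("n_realizations must be >= 1", call. = FALSE)
  n <- nrow(adj$a)
  set.seed(seed)
  cc <- numeric(n_realizations)
  l <- numeric(n_realizations)
  for (k in seq_len(n_realizations)) {
    g <- if (method == "gnm") {
      igraph::sample_gnm(n, m)
    } else {
      igraph::rewire(as_igraph(adj),
                     igraph::keeping_degseq(niter = 10 * m))
    }
    a <- adjacency(as.matrix(igraph::as_adjacency_matrix(g)),
                   labels = adj$labels)
    cc[k] <- clustering_coefficients(a)$global
    l[k] <- characteristic_path_length(a)$L
  }
  list(cc_random = mean(cc), l_random = mean(l),
       n_realizations = n_realizations)
}

#' Small-world index
#'
#' Computes `sigma = gamma / lambda` where `gamma = CC_real / CC_random`
#' and `lambda = L_real / L_random`, with the random terms taken as
#' ensemble means over matched random graphs ([random_reference()]).
#' `sigma > 1` indicates small-world organization.
#'
#' @inheritParams random_reference
#' @return Object of class `small_world` with `gamma`, `lambda`, `sigma`,
#'   `cc_real`, `l_real`, `cc_random`, `l_random`, `n_realizations`,
#'   `seed`.
#' @export
small_world_index <- function(adj, n_realizations = 20, seed = 1,
                              method = c("gnm", "rewire")) {
  cc_real <- clustering_coefficients(adj)$global
  l_real <- characteristic_path_length(adj)$L
  rnd <- random_reference(adj, n_realizations, seed, method)
  if (rnd$cc_random == 0) {
    stop("random-ensemble clustering is zero: small-world index undefined",
         call. = FALSE)
  }
  gamma <- cc_real / rnd$cc_random
  lambda <- l_real / rnd$l_random
  structure(list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 cc_real = cc_real, l_real = l_real,
                 cc_random = rnd$cc_random, l_random = rnd$l_random,
                 n_realizations = n_realizations, seed = seed),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("Small-world index: sigma = %.3f (gamma = %.3f, lambda = %.3f)\n",
              x$sigma, x$gamma, x$lambda))
  cat(sprintf("  CC %.4f vs random %.4f; L %.4f vs random %.4f (%d realizations)\n",
              x$cc_real, x$cc_random, x$l_real, x$l_random,
              x$n_realizations))
  invisible(x)
}

#' All graph metrics at one threshold
#'
#' Convenience wrapper collecting the standard measures of a thresholded
#' network: per-node degree and clustering, average degree, characteristic
#' path length, global clustering, global efficiency and the count of
#' non-isolated nodes; node strength is computed on the weighted matrix
#' when one is supplied.
#'
#' @param adj An [adjacency()].
#' @param weights Optional weighted matrix for node strength.
#' @return Object of class `graph_metrics`.
#' @export
graph_metrics <- function(adj, weights = NULL) {
  deg <- degrees(adj)
  cc <- clustering_coefficients(adj)
  has_edge <- sum(adj$a) > 0
  pl <- if (has_edge) characteristic_path_length(adj) else
    list(L = NA_real_, unreachable_pairs = nrow(adj$a) * (nrow(adj$a) - 1))
  structure(list(
    degree = deg$degree,
    average_degree = deg$average,
    strength = if (!is.null(weights)) node_strength(weights) else NULL,
    clustering = cc$per_node,
    global_clustering = cc$global,
    path_length = pl$L,
    unreachable_pairs = pl$unreachable_pairs,
    efficiency = global_efficiency(adj),
    n_connected_nodes = count_connected_nodes(adj),
    threshold = adj$threshold
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("Graph metrics (threshold %s):\n",
              ifelse(is.na(x$threshold), "-", format(x$threshold))))
  cat(sprintf("  D = %.3f, L = %s (unreachable %d), CC = %.3f, E = %.3f, connected nodes = %d\n",
              x$average_degree,
              ifelse(is.na(x$path_length), "NA", sprintf("%.3f", x$path_length)),
              x$unreachable_pairs, x$global_clustering, x$efficiency,
              x$n_connected_nodes))
  invisible(x)
}

#' Metrics across a threshold sweep
#'
#' Thresholds a weight matrix across a grid and tabulates the graph
#' measures at each threshold, optionally including the small-world terms
#' against matched random networks.
#'
#' @param weights An [fc_mat()], [connectome()] or plain symmetric matrix.
#' @param thresholds Threshold grid (default [threshold_grid()]).
#' @param small_world Include `gamma`, `lambda`, `sigma` columns.
#' @param n_realizations,seed Random-reference ensemble settings.
#' @return `data.frame` with one row per threshold: `threshold`,
#'   `n_edges`, `n_connected`, `D`, `L`, `unreachable_pairs`, `CC`, `E`
#'   and, when requested, `gamma`, `lambda`, `sigma` (`NA` where
#'   undefined).
#' @export
threshold_metrics <- function(weights, thresholds = threshold_grid(),
                              small_world = FALSE, n_realizations = 20,
                              seed = 1) {
  rows <- lapply(thresholds, function(t) {
    adj <- threshold_adjacency(weights, t)
    gm <- graph_metrics(adj)
    row <- data.frame(threshold = t, n_edges = sum(adj$a) / 2,
                      n_connected = gm$n_connected_nodes,
                      D = gm$average_degree, L = gm$path_length,
                      unreachable_pairs = gm$unreachable_pairs,
                      CC = gm$global_clustering, E = gm$efficiency)
    if (small_world) {
      sw <- tryCatch(small_world_index(adj, n_realizations, seed),
                     error = function(e) NULL)
      row$gamma <- if (is.null(sw)) NA_real_ else sw$gamma
      row$lambda <- if (is.null(sw)) NA_real_ else sw$lambda
      row$sigma <- if (is.null(sw)) NA_real_ else sw$sigma
    }
    row
  })
  do.call(rbind, rows)
}
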