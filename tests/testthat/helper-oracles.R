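# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (and igraph): plain loops, Floyd-Warshall,
# explicit complex sums.

# all-pairs shortest hop counts by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# degree, path length, clustering and efficiency by brute force
oracle_metrics <- function(a) {
  n <- nrow(a)
  deg <- rowSums(a)
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k >= 2) {
      e <- sum(a[nb, nb]) / 2
      cc[i] <- 2 * e / (k * (k - 1))
    }
  }
  list(D = mean(deg),
       L = if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_,
       unreachable = sum(!is.finite(off)),
       CC = mean(cc),
       E = mean(ifelse(is.finite(off), 1 / off, 0)))
}

# direct complex-sum phase-locking value
oracle_plv <- function(theta_i, theta_j) {
  s <- 0 + 0i
  for (t in seq_along(theta_i)) s <- s + exp(1i * (theta_i[t] - theta_j[t]))
  Mod(s) / length(theta_i)
}

# textbook Pearson correlation
oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# scalar (single-node) Wendling RK4 reference: plain loops, no matrices
oracle_single_node <- function(p, y0, noise, h) {
  S <- function(v) 2 * p$e0 / (1 + exp(p$r * (p$v0 - v)))
  f <- function(y, pt) {
    c(y[6], y[7], y[8], y[9], y[10],
      p$A * p$a * S(y[2] - y[3] - y[4]) - 2 * p$a * y[6] - p$a^2 * y[1],
      p$A * p$a * (pt + p$C2 * S(p$C1 * y[1])) - 2 * p$a * y[7] -
        p$a^2 * y[2],
      p$B * p$b * p$C4 * S(p$C3 * y[1]) - 2 * p$b * y[8] - p$b^2 * y[3],
      p$G * p$g * p$C7 * S(p$C5 * y[1] - y[5]) - 2 * p$g * y[9] -
        p$g^2 * y[4],
      p$B * p$b * p$C6 * S(p$C3 * y[1]) - 2 * p$b * y[10] - p$b^2 * y[5])
  }
  out <- numeric(length(noise))
  y <- y0
  for (s in seq_along(noise)) {
    k1 <- f(y, noise[s])
    k2 <- f(y + h / 2 * k1, noise[s])
    k3 <- f(y + h / 2 * k2, noise[s])
    k4 <- f(y + h * k3, noise[s])
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s] <- y[2] - y[3] - y[4]
  }
  out
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p_edge = 0.4) {
  a <- matrix(0, n, n)
  iu <- upper.tri(a)
  a[iu] <- as.numeric(stats::runif(sum(iu)) < p_edge)
  a + t(a)
}

# adjacency from an edge-set bitmask over the upper triangle (enumeration)
adjacency_from_mask <- function(n, mask) {
  a <- matrix(0, n, n)
  iu <- which(upper.tri(a))
  bits <- as.integer(intToBits(mask))[seq_along(iu)]
  a[iu[bits == 1L]] <- 1
  a + t(a)
}

is_connected_mat <- function(a) {
  n <- nrow(a)
  seen <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
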