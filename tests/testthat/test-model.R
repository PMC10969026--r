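test_that("sigmoid reproduces its defining values and limits", {
  p <- wendling_params()
  expect_identical(sigmoid(p$v0, p), p$e0)
  # closed form at v = 0: 2 e0 / (1 + exp(r v0))
  expect_equal(sigmoid(0, p), 5 / (1 + exp(0.56 * 6)), tolerance = 1e-12)
  expect_equal(sigmoid(1e6, p), 2 * p$e0, tolerance = 1e-12)
  expect_lt(sigmoid(-1e3, p), 1e-10)
  expect_error(sigmoid(NA_real_, p), "NA")
})

test_that("sigmoid is monotone, bounded, and point-symmetric about (v0, e0)", {
  p <- wendling_params()
  v <- seq(-40, 40, by = 0.25)
  s <- sigmoid(v, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 2 * p$e0))
  d <- seq(0, 30, by = 0.5)
  expect_equal(sigmoid(p$v0 + d, p) + sigmoid(p$v0 - d, p),
               rep(2 * p$e0, length(d)), tolerance = 1e-12)
})

test_that("default parameters carry the standard values and reject bad input", {
  p <- wendling_params()
  expect_equal(unlist(p[c("A", "B", "G", "a", "b", "g")]),
               c(A = 3.25, B = 22, G = 10, a = 100, b = 50, g = 500))
  expect_equal(unlist(p[paste0("C", 1:7)]),
               c(C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75, C5 = 40.5,
                 C6 = 13.5, C7 = 108))
  expect_equal(unlist(p[c("v0", "e0", "r", "mu", "sigma2")]),
               c(v0 = 6, e0 = 2.5, r = 0.56, mu = 90, sigma2 = 30))
  expect_error(wendling_params(A = -1), "positive")
  expect_error(wendling_params(a = 0), "positive")
})

test_that("node output is y1 - y2 - y3 and ignores the other components", {
  expect_equal(node_output(c(0, 10, 3, 2, rnorm(6))), 5)
  expect_equal(node_output(rep(0, 10)), 0)
  base <- c(1, 4, 1, 2, 0.3, 5, -2, 0, 1, 7)
  perturbed <- base
  perturbed[c(1, 5:10)] <- rnorm(7)
  expect_equal(node_output(perturbed), node_output(base))
  expect_error(node_output(1:9), "length 10")
})

test_that("derivatives at the origin match term-by-term hand evaluation", {
  p <- wendling_params()
  sc <- connectome(matrix(0, 2, 2))
  sys <- coupled_system(p, sc, c_global = 0)
  d <- network_derivatives(matrix(0, 2, 10), sys, p = c(0, 0))
  s0 <- 2 * p$e0 / (1 + exp(p$r * p$v0)) # S(0)
  expect_equal(d[, 1:5], matrix(0, 2, 5))
  expect_equal(d[1, 6], p$A * p$a * s0)
  expect_equal(d[1, 7], p$A * p$a * p$C2 * s0)
  expect_equal(d[1, 8], p$B * p$b * p$C4 * s0)
  expect_equal(d[1, 9], p$G * p$g * p$C7 * s0)
  expect_equal(d[1, 10], p$B * p$b * p$C6 * s0)
})

test_that("first five derivative lines copy the stored velocities", {
  sc <- connectome(matrix(0, 2, 2))
  sys <- coupled_system(wendling_params(), sc, c_global = 0)
  st <- matrix(rnorm(20), 2, 10)
  d <- network_derivatives(st, sys, p = c(0, 0))
  expect_equal(d[, 1:5], st[, 6:10])
})

test_that("with zero coupling regions are independent", {
  set.seed(3)
  w <- matrix(0.5, 2, 2); diag(w) <- 0
  sys <- coupled_system(wendling_params(), connectome(w), c_global = 0)
  st <- matrix(rnorm(20), 2, 10)
  d1 <- network_derivatives(st, sys, p = c(90, 90))
  st2 <- st
  st2[2, ] <- rnorm(10)
  d2 <- network_derivatives(st2, sys, p = c(90, 90))
  expect_identical(d1[1, ], d2[1, ])
})

test_that("the pyramidal input derivative is affine in the coupling coefficient", {
  set.seed(4)
  n <- 5
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  w <- w / max(w)
  sc <- connectome(w)
  p <- wendling_params()
  st <- matrix(rnorm(n * 10, sd = 2), n, 10)
  pv <- rep(90, n)
  d0 <- network_derivatives(st, coupled_system(p, sc, 0), pv)
  d1 <- network_derivatives(st, coupled_system(p, sc, 1), pv)
  d3 <- network_derivatives(st, coupled_system(p, sc, 3), pv)
  slope <- p$A * p$a *
    as.vector(w %*% sigmoid(st[, 2] - st[, 3] - st[, 4], p))
  expect_equal(d1[, 7] - d0[, 7], slope, tolerance = 1e-10)
  expect_equal(d3[, 7] - d0[, 7], 3 * slope, tolerance = 1e-10)
  # all other components are unaffected by coupling
  expect_equal(d1[, -7], d0[, -7])
})

test_that("derivatives are equivariant under joint region permutation", {
  set.seed(5)
  n <- 6
  w <- matrix(runif(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  w <- w / max(w)
  p <- wendling_params()
  st <- matrix(rnorm(n * 10), n, 10)
  pv <- runif(n, 80, 100)
  perm <- sample(n)
  d <- network_derivatives(st, coupled_system(p, connectome(w), 4), pv)
  d_perm <- network_derivatives(
    st[perm, ],
    coupled_system(p, connectome(w[perm, perm]), 4),
    pv[perm])
  expect_equal(d_perm, d[perm, ], tolerance = 1e-12)
})

test_that("shape mismatches and non-finite states are rejected", {
  sys <- coupled_system(wendling_params(), connectome(matrix(0, 2, 2)), 0)
  expect_error(network_derivatives(matrix(0, 3, 10), sys, c(0, 0, 0)),
               "state")
  expect_error(network_derivatives(matrix(0, 2, 10), sys, 0), "entry per")
  bad <- matrix(0, 2, 10); bad[1, 1] <- Inf
  expect_error(network_derivatives(bad, sys, c(0, 0)), "finite")
})

test_that("connectome construction enforces its invariants", {
  w <- matrix(c(0, 2, 2, 0), 2, 2)
  sc <- connectome(w, normalize = TRUE)
  expect_equal(max(sc$weights), 1)
  expect_equal(diag(sc$weights), c(0, 0), ignore_attr = TRUE)
  expect_error(connectome(matrix(1, 2, 3)), "square")
  expect_error(connectome(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(connectome(-w), "nonnegative")
  expect_error(connectome(w), "normalize")
  expect_length(dk_region_labels(), 68)
  expect_identical(dk_region_labels()[27], "LH.SF")
  expect_identical(dk_region_labels()[31], "LH.FP")
  expect_identical(dk_region_labels()[51], "RH.POP")
})
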