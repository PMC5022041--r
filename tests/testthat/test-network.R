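test_that("generators respect the requested density and symmetry", {
  er <- make_network("er", N = 60, c = 0.1, R0 = 0.2, directed = TRUE, seed = 1)
  expect_equal(sum(er$A > 0), round(0.1 * 60^2))
  expect_true(all(diag(er$A) == 0))
  for (m in c("er", "ba", "ws", "ring")) {
    net <- make_network(m, N = 80, c = 6 / 80, R0 = 0.2, seed = 2)
    expect_identical(net$A, t(net$A))
    expect_true(all(diag(net$A) == 0))
    # density within one node's worth of edges of the request
    expect_lt(abs(sum(net$A > 0) - 6 * 80), 2 * 80)
    # edge weight encodes R0/(N c) for the realized c
    w <- unique(net$A[net$A > 0])
    expect_length(w, 1)
    expect_equal(w * 80 * net$c, 0.2, tolerance = 1e-12)
  }
})

test_that("the ring lattice has identical degrees and the uniform critical point", {
  ring <- make_network("ring", N = 100, c = 6 / 100, R0 = 0.2)
  expect_true(all(rowSums(ring$A > 0) == 6))
  expect_equal(critical_R(ring), 1 - 1 / sqrt(2), tolerance = 1e-3)
})

test_that("er at full density saturates every off-diagonal pair", {
  er <- make_network("er", N = 12, c = 11 / 12, R0 = 0.3, directed = TRUE,
                     seed = 3)
  # c = 11/12 fills all ordered off-diagonal pairs at weight R0/(N c)
  full <- matrix(0.3 / (12 * 11 / 12), 12, 12); diag(full) <- 0
  expect_equal(er$A, full, tolerance = 1e-12)
  expect_error(make_network("er", N = 12, c = 1, R0 = 0.3, directed = TRUE),
               "unreachable")
})

test_that("the karate club fixture is the canonical 34-node graph", {
  k <- make_network("karate", R0 = 0.2)
  expect_equal(k$N, 34)
  expect_equal(sum(k$A > 0), 156)          # 78 undirected friendships
  expect_identical(k$A, t(k$A))
  deg <- rowSums(k$A > 0)
  expect_equal(sort(deg, decreasing = TRUE)[1:2], c(17, 16))  # the two hubs
})

test_that("extreme configurations match their hand-built block forms", {
  # kind i: isolated clique (diagonal included), c = M^2/N^2
  n1 <- make_extreme("i", N = 6, M = 3, R0 = 0.2)
  w <- 0.2 / (6 * (9 / 36))
  A1 <- matrix(0, 6, 6); A1[1:3, 1:3] <- w
  expect_equal(n1$A, A1)
  # kind i with M = N degenerates to the uniform network
  expect_equal(make_extreme("i", N = 5, M = 5, R0 = 0.3)$A,
               make_network("uniform", N = 5, R0 = 0.3)$A)
  # kind ii: clique plus reciprocal periphery, c = (2MN - M^2)/N^2
  n2 <- make_extreme("ii", N = 6, M = 2, R0 = 0.2)
  c2 <- (2 * 2 * 6 - 4) / 36
  w2 <- 0.2 / (6 * c2)
  A2 <- matrix(0, 6, 6)
  A2[1:2, ] <- w2; A2[, 1:2] <- w2
  expect_equal(n2$A, A2)
  # kind iii is nilpotent: A^2 = 0 and L = I + A exactly
  n3 <- make_extreme("iii", N = 8, M = 3, R0 = 0.4)
  expect_equal(n3$A %*% n3$A, matrix(0, 8, 8))
  expect_equal(leontief(n3), diag(8) + n3$A)
  # kind iv: strictly lower triangular hierarchy
  n4 <- make_extreme("iv", N = 5, R0 = 0.3)
  expect_true(all(n4$A[upper.tri(n4$A, diag = TRUE)] == 0))
  expect_true(all(n4$A[lower.tri(n4$A)] > 0))
  expect_error(make_extreme("i", N = 5, M = 9, R0 = 0.1), "out of range")
})

test_that("clustering coefficient matches brute-force triangle counting", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(cascade_network(tri * 0.1, 1)), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 0.1
  expect_equal(clustering_coefficient(cascade_network(star, 1)), 0)
  set.seed(13)
  for (rep in 1:4) {
    N <- sample(10:30, 1)
    B <- matrix(rbinom(N * N, 1, 0.2), N, N) * 0.1
    diag(B) <- 0
    net <- cascade_network(B, 1)
    expect_equal(clustering_coefficient(net), brute_clustering(B),
                 tolerance = 1e-12)
    # the dense per-step tracker used during rewiring agrees too
    expect_equal(cascadenet:::clustering_dense(B), brute_clustering(B),
                 tolerance = 1e-12)
  }
  # undirected ER: local clustering concentrates near the edge density
  er <- make_network("er", N = 100, c = 0.1, R0 = 0.2, seed = 14)
  expect_lt(abs(clustering_coefficient(er) - 0.1), 0.03)
})

test_that("degree-based mean-field critical point behaves as derived", {
  # degenerate degrees recover the uniform value
  expect_equal(scale_free_Rc_meanfield(rep(6, 50)), 1 - 1 / sqrt(2),
               tolerance = 1e-6)
  # scale-free degree sequences: R_c decreases with N
  set.seed(15)
  rcs <- vapply(c(250, 500, 1000, 2000), function(N) {
    g <- igraph::sample_pa(N, m = 3, directed = FALSE)
    scale_free_Rc_meanfield(igraph::degree(g))
  }, numeric(1))
  expect_true(all(diff(rcs) < 0))
  expect_error(scale_free_Rc_meanfield(c(2, 0, 3)), "positive")
})
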