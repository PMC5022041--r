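test_that("Leontief inverse: identity, geometric series and nilpotent cases", {
  expect_equal(leontief(matrix(0, 4, 4)), diag(4))
  # uniform alpha = R0/N including the diagonal: column sums 1/(1-R0)
  for (N in c(10, 100)) {
    R0 <- 0.4
    L <- leontief(matrix(R0 / N, N, N))
    expect_equal(colSums(L), rep(1 / (1 - R0), N), tolerance = 1e-10)
    expect_true(all(L >= 0))
    expect_equal(L %*% (diag(N) - matrix(R0 / N, N, N)), diag(N),
                 tolerance = 1e-10)
  }
  # 2-node chain: nilpotent, L = I + A
  A <- rbind(c(0, 0), c(0.7, 0))
  expect_equal(leontief(A), rbind(c(1, 0), c(0.7, 1)))
})

test_that("mean rates shift base rates through the network", {
  A <- matrix(0, 3, 3)
  expect_equal(mean_rates(cascade_network(A, c(1, 2, 3))), c(1, 2, 3))
  N <- 50; R0 <- 0.3
  uni <- make_network("uniform", N = N, R0 = R0, rho = 0.5)
  expect_equal(mean_rates(uni), rep(0.5 / (1 - R0), N), tolerance = 1e-10)
})

test_that("cascading statistic: Poisson baseline, uniform closed form, threshold", {
  expect_equal(cascading_C(cascade_network(matrix(0, 5, 5), 1))$C, 1)
  for (N in c(10, 100, 1000)) {
    for (R0 in c(0.1, 0.29, 0.5)) {
      net <- make_network("uniform", N = N, R0 = R0, rho = 0.5)
      expect_equal(cascading_C(net)$C, 1 / (1 - R0)^2, tolerance = 1e-9)
    }
    # without the diagonal the agreement is O(1/N)
    netd <- make_network("uniform", N = N, R0 = 0.3, diag = FALSE)
    expect_equal(cascading_C(netd)$C, 1 / 0.7^2, tolerance = 5 / N)
  }
  net <- make_network("uniform", N = 100, R0 = 1 - 1 / sqrt(2))
  expect_equal(cascading_C(net)$C, 2, tolerance = 1e-9)
  # verdict flips across the boundary
  expect_false(cascading_C(make_network("uniform", N = 100,
                                        R0 = 0.29))$nonstationary)
  expect_true(cascading_C(make_network("uniform", N = 100,
                                       R0 = 0.30))$nonstationary)
  expect_error(cascading_C(cascade_network(matrix(0, 3, 3), 0)), "zero")
})

test_that("C is invariant under node permutation and base-rate scaling", {
  set.seed(20)
  A <- random_subcritical(15, c = 0.2)
  rho <- runif(15, 0.1, 2)
  C1 <- cascading_C(cascade_network(A, rho))$C
  p <- sample(15)
  expect_equal(cascading_C(cascade_network(A[p, p], rho[p]))$C, C1,
               tolerance = 1e-10)
  expect_equal(cascading_C(cascade_network(A, 7.3 * rho))$C, C1,
               tolerance = 1e-10)
  expect_equal(C1, brute_C(A, rho), tolerance = 1e-12)
})

test_that("critical_R recovers the uniform-network transition point", {
  uni <- make_network("uniform", N = 150, R0 = 0.2, rho = 1)
  expect_equal(critical_R(uni), 1 - 1 / sqrt(2), tolerance = 2e-4)
  # builder-function interface
  rc <- critical_R(function(R0) make_network("uniform", N = 80, R0 = R0))
  expect_equal(rc, 1 - 1 / sqrt(2), tolerance = 2e-4)
  # a 2-node feed-forward chain never reaches C = 2 at weight R0 * base
  chain <- cascade_network(rbind(c(0, 0), c(0.1, 0)), 1, R0 = 0.1)
  expect_warning(rc2 <- critical_R(chain), "no SN transition")
  expect_true(is.na(rc2))
})

test_that("exchange score H: closed form at A = 0 and gradient ranking", {
  net <- cascade_network(matrix(0, 6, 6), rho = 0.8)
  H <- exchange_score_H(cascading_C(net), net)
  expect_equal(H, matrix(2 * 0.8, 6, 6))   # u = 1, C = 1, lambda = rho
  # permuting labels permutes H consistently
  set.seed(21)
  A <- random_subcritical(10, c = 0.25)
  rho <- runif(10, 0.5, 1.5)
  net <- cascade_network(A, rho)
  H1 <- exchange_score_H(cascading_C(net), net)
  p <- sample(10)
  netp <- cascade_network(A[p, p], rho[p])
  Hp <- exchange_score_H(cascading_C(netp), netp)
  expect_equal(Hp, H1[p, p], tolerance = 1e-10)
  # H ranks first-order dC/dalpha_ij: rank correlation > 0.9 on small dense nets
  cors <- vapply(1:10, function(s) {
    set.seed(s)
    N <- 8
    A <- matrix(runif(N * N, 0, 0.08), N, N); diag(A) <- 0
    rho <- rep(1, N)
    net <- cascade_network(A, rho)
    rep <- cascading_C(net)
    H <- exchange_score_H(rep, net)
    eps <- 1e-6
    fd <- matrix(NA_real_, N, N)
    for (i in 1:N) for (j in 1:N) if (i != j) {
      A2 <- A; A2[i, j] <- A2[i, j] + eps
      fd[i, j] <- (brute_C(A2, rho) - rep$C) / eps
    }
    off <- row(A) != col(A)
    cor(H[off], fd[off], method = "spearman")
  }, numeric(1))
  expect_gt(median(cors), 0.9)
})

test_that("exact exchange delta-C agrees with dense recomputation to 1e-10", {
  set.seed(22)
  N <- 20; cc <- 0.15; R0 <- 0.35
  w <- R0 / (N * cc)
  off <- which(diag(N) == 0)
  A <- matrix(0, N, N); A[sample(off, round(cc * N^2))] <- w
  rho <- runif(N, 0.5, 1.5)
  net <- cascade_network(A, rho, R0 = R0)
  C0 <- brute_C(A, rho)
  pres <- which(A > 0); absn <- setdiff(which(A == 0), seq(1, N^2, N + 1))
  for (k in 1:40) {
    eo <- sample(pres, 1); ei <- sample(absn, 1)
    out <- c((eo - 1) %% N + 1, (eo - 1) %/% N + 1)
    inn <- c((ei - 1) %% N + 1, (ei - 1) %/% N + 1)
    d <- exact_exchange_deltaC(net, out, inn, undirected = FALSE)
    A2 <- A; A2[eo] <- 0; A2[ei] <- w
    expect_equal(d, brute_C(A2, rho) - C0, tolerance = 1e-10)
  }
  # null exchange
  out <- c((pres[1] - 1) %% N + 1, (pres[1] - 1) %/% N + 1)
  expect_equal(exact_exchange_deltaC(net, out, out), 0)
  # constraint errors
  expect_error(exact_exchange_deltaC(net, out, c(3, 3)), "self-loop")
  expect_error(exact_exchange_deltaC(net, c(out[1], out[1]), out),
               "not a present connection")
})

test_that("undirected pair exchanges match dense recomputation", {
  set.seed(23)
  N <- 16
  B <- matrix(0, N, N)
  ut <- which(upper.tri(B))
  sel <- sample(ut, 30)
  B[sel] <- 1; B <- B + t(B)
  w <- 0.3 / mean(rowSums(B))
  A <- B * w
  net <- cascade_network(A, 1, directed = FALSE, R0 = 0.3)
  C0 <- brute_C(A, rep(1, N))
  pres <- ut[A[ut] > 0]; absn <- ut[A[ut] == 0]
  for (k in 1:15) {
    eo <- sample(pres, 1); ei <- sample(absn, 1)
    out <- c((eo - 1) %% N + 1, (eo - 1) %/% N + 1)
    inn <- c((ei - 1) %% N + 1, (ei - 1) %/% N + 1)
    d <- exact_exchange_deltaC(net, out, inn)   # undirected by default
    A2 <- A
    A2[out[1], out[2]] <- A2[out[2], out[1]] <- 0
    A2[inn[1], inn[2]] <- A2[inn[2], inn[1]] <- w
    expect_equal(d, brute_C(A2, rep(1, N)) - C0, tolerance = 1e-10)
  }
})

test_that("block-structure evaluation matches explicit extreme matrices", {
  for (kind in c("i", "ii", "iii")) {
    N <- 40
    M <- if (kind == "iii") 8 else 12
    R0 <- 0.25
    net <- make_extreme(kind, N = N, M = M, R0 = R0)
    C_explicit <- brute_C(net$A, net$rho)
    bl <- cascadenet:::extreme_blocks(kind, net$c, N, R0)
    expect_equal(cascadenet:::block_C(bl$W, bl$n), C_explicit,
                 tolerance = 1e-9)
  }
  # analytic extreme_Rc agrees with brute bisection on the explicit matrix
  rc_block <- extreme_Rc("i", c = 0.09, N = 100)
  net_fun <- function(R0) make_extreme("i", N = 100, M = 30, R0 = R0)
  expect_equal(rc_block, critical_R(net_fun), tolerance = 1e-3)
})
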