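# independent brute-force oracles used across the suite

# cascading statistic straight from the definition (dense solve), bypassing
# the package's state machinery
brute_C <- function(A, rho) {
  L <- solve(diag(nrow(A)) - A)
  u <- colSums(L)
  lam <- as.vector(L %*% rho)
  sum(u^2 * lam) / sum(lam)
}

# average local clustering by explicit triangle enumeration
brute_clustering <- function(B) {
  B <- ((B > 0) | (t(B) > 0)) * 1
  diag(B) <- 0
  N <- nrow(B)
  cl <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      links <- links + B[nb[a], nb[b]]
    cl[i] <- 2 * links / (k * (k - 1))
  }
  mean(cl)
}

# random sparse subcritical directed weight matrix
random_subcritical <- function(N, c = 0.15, wmax = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wmax)) wmax <- 0.8 / (N * c)
  A <- matrix(0, N, N)
  off <- which(diag(N) == 0)
  A[sample(off, round(c * N^2))] <- runif(round(c * N^2), 0, wmax)
  while (max(Mod(eigen(A, only.values = TRUE)$values)) >= 0.95) A <- A / 2
  A
}
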