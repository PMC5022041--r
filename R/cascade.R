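#' Leontief inverse of an interaction matrix
#'
#' \eqn{L = (I - A)^{-1} = I + A + A^2 + \dots} sums the direct and indirect
#' excitation along all paths of the network; it maps the base rates to the
#' stationary mean rates, \eqn{\langle\lambda\rangle = L\rho}.  Defined only
#' in the subcritical regime where the spectral radius of \eqn{A} is below
#' 1.
#'
#' @param net a [cascade_network()] or a non-negative square matrix.
#' @return The dense matrix \eqn{L}; all entries are non-negative.
#' @examples
#' leontief(matrix(0, 3, 3))                       # identity
#' leontief(rbind(c(0, 0), c(0.4, 0)))             # 2-node chain: I + A
#' @export
leontief <- function(net) {
  net <- as_cascade_network(net)
  sr <- spectral_radius(net$A)
  if (sr >= 1)
    stop(sprintf("supercritical interaction matrix: spectral radius %.6g >= 1", sr),
         call. = FALSE)
  solve(diag(net$N) - net$A)
}

spectral_radius <- function(A) {
  if (all(A == 0)) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Stationary mean rates of the multivariate Hawkes process
#'
#' \eqn{\langle\lambda\rangle = L\rho}: interactions shift every node's mean
#' rate above its base rate by the excitation received along all network
#' paths.
#'
#' @inheritParams leontief
#' @return Numeric vector of per-node mean rates.
#' @export
mean_rates <- function(net) {
  net <- as_cascade_network(net)
  as.vector(leontief(net) %*% net$rho)
}

#' Cascading statistic C and stationarity verdict
#'
#' The superposed event stream of the whole network is nonstationary --
#' exhibits detectable cascades -- iff the zero-frequency power of its rate
#' fluctuation exceeds the mean rate, which reduces to the scalar condition
#' \deqn{C = \frac{\sum_i u_i^2 \langle\lambda_i\rangle}
#'               {\sum_i \langle\lambda_i\rangle} > 2,}
#' where \eqn{u_i = \sum_k L_{ki}} are the column sums of the Leontief
#' inverse (the total event multiplication triggered by one event at node
#' \eqn{i}) and \eqn{\langle\lambda_i\rangle} the mean rates.  Without
#' interactions \eqn{C = 1} (Poisson superposition); on the fully connected
#' uniform network \eqn{C = 1/(1-R_0)^2}, crossing 2 exactly at
#' \eqn{R_0 = 1 - 1/\sqrt 2}.  `C` depends on the base rates only through
#' their ratios.
#'
#' @inheritParams leontief
#' @return An object of class `cascade_report`: list with `C`,
#'   `nonstationary` (`C > 2`), `lambda_mean`, `colsum_L` (\eqn{u}) and
#'   `Lambda` (diagonal matrix of mean rates).
#' @examples
#' net <- make_network("uniform", N = 100, R0 = 1 - 1 / sqrt(2), rho = 0.5)
#' cascading_C(net)     # C = 2: exactly at the SN boundary
#' @export
cascading_C <- function(net) {
  net <- as_cascade_network(net)
  if (all(net$rho == 0))
    stop("all base rates are zero: total rate vanishes, C undefined",
         call. = FALSE)
  L <- leontief(net)
  u <- colSums(L)
  lam <- as.vector(L %*% net$rho)
  C <- sum(u^2 * lam) / sum(lam)
  structure(list(C = C, nonstationary = C > 2, lambda_mean = lam,
                 colsum_L = u, Lambda = diag(lam, nrow = length(lam))),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("Cascading statistic C = %.6g -> %s (critical value 2)\n", x$C,
              if (x$nonstationary) "nonstationary (cascading)" else "stationary"))
  cat(sprintf("Mean rates: total %.6g, range [%.4g, %.4g]\n",
              sum(x$lambda_mean), min(x$lambda_mean), max(x$lambda_mean)))
  invisible(x)
}

# C and ingredients from (L-free) state pieces; internal fast path
C_from_state <- function(u, lam) sum(u^2 * lam) / sum(lam)

#' Critical reproduction ratio of a network
#'
#' Solves \eqn{C(R_0) = 2} for the reproduction ratio at which the network
#' crosses the stationary--nonstationary boundary.  The interaction weights
#' scale linearly with \eqn{R_0} (0--1 connectivity, weight
#' \eqn{R_0/(Nc)}), so the whole family is obtained by rescaling one
#' matrix.  Bisection is confined to the subcritical range (upper end just
#' below the spectral-radius bound, capped at `R0_max`), where \eqn{C} is
#' continuous and increasing; monotonicity is spot-checked on a coarse grid.
#' For symmetric networks with uniform base rates a one-off eigendecomposition
#' makes every \eqn{C(R_0)} evaluation \eqn{O(N^2)}.
#'
#' @param net a [cascade_network()] with a finite `R0` field, or a builder
#'   `function(R0)` returning a [cascade_network()].
#' @param tol bisection tolerance on \eqn{R_0} (default 1e-4).
#' @param R0_max upper end of the admissible range (default 0.999).
#' @return The critical ratio \eqn{R_c}, or `NA` (with a warning) when
#'   \eqn{C < 2} over the whole admissible range.
#' @examples
#' ring <- make_network("ring", N = 200, c = 6 / 200, R0 = 0.2)
#' critical_R(ring)        # 1 - 1/sqrt(2) = 0.29289...
#' @export
critical_R <- function(net, tol = 1e-4, R0_max = 0.999) {
  if (is.function(net)) {
    f <- function(R0) {
      n <- net(R0)
      if (spectral_radius(n$A) >= 1) return(Inf)
      cascading_C(n)$C - 2
    }
    return(bisect_C(f, tol, R0_max))
  }
  net <- as_cascade_network(net)
  if (!is.finite(net$R0) || net$R0 <= 0)
    stop("network lacks a positive 'R0' field; pass a builder function instead",
         call. = FALSE)
  B <- net$A / net$R0
  sym <- isTRUE(all.equal(B, t(B))) &&
    diff(range(net$rho)) < 1e-12 * max(net$rho, 1)
  if (sym) {
    e <- eigen(B, symmetric = TRUE)
    a <- as.vector(crossprod(e$vectors, rep(1, net$N)))
    f <- function(R0) {
      g <- 1 / (1 - R0 * e$values)
      if (any(g < 0)) return(Inf)
      u <- as.vector(e$vectors %*% (a * g))
      sum(u^3) / sum(u) - 2        # symmetric + uniform rho: lam = rho * u
    }
    hi_sr <- if (max(e$values) > 0) (1 - 1e-9) / max(e$values) else Inf
  } else {
    rho <- net$rho
    f <- function(R0) {
      M <- diag(net$N) - R0 * B
      L <- tryCatch(solve(M), error = function(e) NULL)
      if (is.null(L) || any(L < -1e-9)) return(Inf)
      C_from_state(colSums(L), as.vector(L %*% rho)) - 2
    }
    hi_sr <- {
      sr <- spectral_radius(B)
      if (sr > 0) (1 - 1e-9) / sr else Inf
    }
  }
  bisect_C(f, tol, min(R0_max, hi_sr))
}

# bisection on C(R0) - 2 over (0, hi]; f returns Inf past the subcritical edge
bisect_C <- function(f, tol, hi) {
  lo <- 1e-6
  fhi <- f(hi)
  while (!is.finite(fhi) && hi > tol) {    # back off from the singular edge
    hi <- hi * 0.999
    fhi <- f(hi)
  }
  if (!is.finite(fhi) || fhi < 0) {
    if (is.finite(fhi) && fhi < 0) {
      warning("C < 2 over the whole admissible range: no SN transition")
      return(NA_real_)
    }
    stop("could not locate the subcritical range", call. = FALSE)
  }
  # coarse monotonicity check
  grid <- seq(lo, hi, length.out = 8)
  vals <- vapply(grid, f, numeric(1))
  fin <- is.finite(vals)
  if (any(diff(vals[fin]) < -1e-8))
    warning("C(R0) is not monotone on the admissible range; root may not be unique")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (is.finite(fm) && fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Exchange score for connection reallocation
#'
#' First-order sensitivity score for moving connections: the change of the
#' cascading statistic when a connection into node \eqn{i} from node
#' \eqn{j} is created is approximately proportional to
#' \deqn{H_{ij} = \big( (\textstyle\sum_k L_{ki})^2 - C \big)\,\rho_j
#'       + 2 \big(\textstyle\sum_k L_{kj}\big) \langle\lambda_j\rangle,}
#' and an exchange that removes \eqn{\alpha_{ij}} while adding
#' \eqn{\alpha_{i'j'}} changes \eqn{C} at first order like
#' \eqn{H_{i'j'} - H_{ij}}.  [rewire_optimize()] uses `H` to rank candidate
#' exchanges; acceptance always uses the exact [exact_exchange_deltaC()].
#'
#' @param report a `cascade_report` from [cascading_C()].
#' @param net the network the report was computed on.
#' @return The \eqn{N \times N} matrix `H`.
#' @export
exchange_score_H <- function(report, net) {
  net <- as_cascade_network(net)
  u <- report$colsum_L; lam <- report$lambda_mean
  outer(u^2 - report$C, net$rho) +
    matrix(2 * u * lam, net$N, net$N, byrow = TRUE)
}

## ---- Sherman–Morrison machinery -------------------------------------------
## A chain of rank-1 weight changes A[a,b] += s is applied to the resolvent
## state (L, u = colSums(L), lam = L rho).  For M = I - A,
## (M - s e_a e_b')^{-1} = L + s L[,a] L[b,] / (1 - s L[b,a]),
## so each op only needs the current column a and row b of L; for a chain we
## carry those slices through the updates (O(K^2 N) per candidate).

# ops: list of c(a, b, s); returns list(u, lam, ok) without forming L'
sm_chain_state <- function(L, u, lam, ops) {
  K <- length(ops)
  a_idx <- vapply(ops, `[`, numeric(1), 1L)
  b_idx <- vapply(ops, `[`, numeric(1), 2L)
  Cols <- L[, a_idx, drop = FALSE]          # N x K: columns L[, a_t]
  Rows <- L[b_idx, , drop = FALSE]          # K x N: rows    L[b_t, ]
  for (t in seq_len(K)) {
    a <- a_idx[t]; b <- b_idx[t]; s <- ops[[t]][3]
    col_a <- Cols[, t]; row_b <- Rows[t, ]
    d <- 1 - s * row_b[a]
    if (!is.finite(d) || d <= 1e-12) return(list(ok = FALSE))
    f <- s / d
    u <- u + f * u[a] * row_b
    lam <- lam + f * col_a * lam[b]
    if (t < K) {
      later <- (t + 1L):K
      Cols[, later] <- Cols[, later, drop = FALSE] +
        f * col_a %o% row_b[a_idx[later]]
      # current L[b_l, a] is col_a evaluated at the later ops' rows
      Rows[later, ] <- Rows[later, , drop = FALSE] +
        f * col_a[b_idx[later]] %o% row_b
    }
  }
  if (any(lam < 0) || any(u < 0)) return(list(ok = FALSE))
  list(ok = TRUE, u = u, lam = lam)
}

# apply ops to the full L (used when a step is accepted)
sm_chain_apply <- function(L, ops) {
  for (op in ops) {
    a <- op[1]; b <- op[2]; s <- op[3]
    d <- 1 - s * L[b, a]
    if (!is.finite(d) || abs(d) <= 1e-12)
      stop("exchange drives the network through the critical surface",
           call. = FALSE)
    L <- L + (s / d) * (L[, a] %o% L[b, ])
  }
  L
}

exchange_ops <- function(w, out, inn, undirected) {
  ops <- list(c(out[1], out[2], -w), c(inn[1], inn[2], +w))
  if (undirected)
    ops <- c(ops, list(c(out[2], out[1], -w), c(inn[2], inn[1], +w)))
  ops
}

#' Exact change of C under a connection exchange
#'
#' Removes the existing connection `edge_out` and creates `edge_in` at the
#' same weight, returning the exact change of the cascading statistic.
#' Computed through rank-1 resolvent updates (Sherman--Morrison), which
#' agree with a full dense recomputation to near machine precision; for
#' undirected networks both reciprocal directions are moved jointly.
#'
#' @param net a [cascade_network()].
#' @param edge_out length-2 `c(i, j)`: an existing connection (row `i`
#'   receives from column `j`).
#' @param edge_in length-2 `c(i, j)`: an empty, off-diagonal slot.
#' @param undirected move the reciprocal pair jointly (defaults to the
#'   network's directedness).
#' @return The scalar \eqn{\Delta C}; `NA` when the exchange would cross
#'   into the supercritical regime.
#' @export
exact_exchange_deltaC <- function(net, edge_out, edge_in,
                                  undirected = !net$directed) {
  net <- as_cascade_network(net)
  i <- edge_out[1]; j <- edge_out[2]; ii <- edge_in[1]; jj <- edge_in[2]
  if (identical(as.integer(edge_out), as.integer(edge_in))) return(0)
  if (net$A[i, j] == 0) stop("edge_out is not a present connection", call. = FALSE)
  if (ii == jj) stop("exchange would create a self-loop", call. = FALSE)
  if (net$A[ii, jj] != 0) stop("edge_in already exists", call. = FALSE)
  w <- net$A[i, j]
  L <- leontief(net)
  u <- colSums(L); lam <- as.vector(L %*% net$rho)
  C0 <- C_from_state(u, lam)
  st <- sm_chain_state(L, u, lam, exchange_ops(w, edge_out, edge_in, undirected))
  if (!st$ok) return(NA_real_)
  C_from_state(st$u, st$lam) - C0
}

## ---- block-structured evaluation ------------------------------------------
## For networks whose nodes fall into G exchangeable groups with constant
## within/between weights, L is block-constant: with S = (I - diag(n) W)^{-1}
## (G x G), the column sum for a node of group g is
##   u_g = 1 + sum_h (sum_g' n_g' w_{g'h}) S[h, g],
## the row sum is 1 + (W S n)_g, and C follows with multiplicities n.
block_C <- function(W, n, rho = 1, R0_scale = 1) {
  W <- W * R0_scale
  G <- length(n)
  if (max(Mod(eigen(diag(n, G) %*% W, only.values = TRUE)$values)) >= 1)
    return(Inf)
  S <- solve(diag(G) - diag(n, G) %*% W)
  colw <- as.vector(t(W) %*% n)
  u <- 1 + as.vector(t(S) %*% colw)
  rs <- 1 + as.vector(W %*% (S %*% n))
  if (any(u < 0) || any(rs < 0)) return(Inf)
  lam <- rho * rs
  sum(n * u^2 * lam) / sum(n * lam)
}

# 2x2 block description of extreme kinds i-iii at connection fraction cc
extreme_blocks <- function(kind, cc, N, R0) {
  M <- switch(kind,
    i   = N * sqrt(cc),
    ii  = N * (1 - sqrt(1 - cc)),
    iii = N * (1 - sqrt(1 - 4 * cc)) / 2)   # smaller root of M(N-M)/N^2 = cc
  w <- R0 / (N * cc)
  W <- switch(kind,
    i   = matrix(c(w, 0, 0, 0), 2, 2),
    ii  = matrix(c(w, w, w, 0), 2, 2, byrow = TRUE),
    iii = matrix(c(0, w, 0, 0), 2, 2, byrow = TRUE))
  list(W = W, n = c(M, N - M))
}

#' Analytic critical point of an extreme block configuration
#'
#' Evaluates the cascading statistic of configurations i--iii through their
#' 2x2 block structure (cost independent of `N`; group sizes are treated as
#' continuous) and solves \eqn{C(R_0) = 2}.
#'
#' @param kind `"i"`, `"ii"` or `"iii"`.
#' @param c connection fraction (determines the group size).
#' @param N number of nodes.
#' @param tol bisection tolerance.
#' @return The critical reproduction ratio, `NA` when no transition exists
#'   below `R0 = 0.999`.
#' @examples
#' extreme_Rc("i", c = 0.1, N = 1000)
#' @export
extreme_Rc <- function(kind = c("i", "ii", "iii"), c, N, tol = 1e-6) {
  kind <- match.arg(kind)
  if (kind == "iii" && c > 0.25) stop("kind iii requires c <= 1/4", call. = FALSE)
  f <- function(R0) {
    bl <- extreme_blocks(kind, c, N, R0)
    block_C(bl$W, bl$n) - 2
  }
  bisect_C(f, tol, 0.999)
}

#' Crossover point of the extreme configurations i and ii
#'
#' The \eqn{R_c(c)} curves of the isolated clique (kind i) and of the
#' clique with reciprocal periphery (kind ii) intersect; below the
#' crossover kind ii has the lower critical point, above it kind i does.
#'
#' @param N number of nodes.
#' @param interval search interval for the crossover `c`.
#' @return The connection fraction at which the two curves intersect.
#' @export
extreme_crossover <- function(N = 1000, interval = c(0.05, 0.5)) {
  g <- function(cc) extreme_Rc("i", cc, N) - extreme_Rc("ii", cc, N)
  uniroot(g, interval, tol = 1e-5)$root
}
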