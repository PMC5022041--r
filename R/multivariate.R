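#' Simulate the multivariate Hawkes process on a network
#'
#' Linear mutually exciting point process on a weighted directed network:
#' node \eqn{i} fires with intensity
#' \deqn{\lambda_i(t) = \rho_i + \sum_j \alpha_{ij} \sum_k h(t - t_k^{(j)}),}
#' simulated by Bernoulli thinning per node in steps of `dt`.  The
#' exponential kernel allows a recursive per-node excitation state, so each
#' step costs one matrix--vector product.  Mean rates converge to
#' \eqn{L\rho} (see [mean_rates()]); the pooled stream of all nodes is the
#' object whose stationarity the cascading condition \eqn{C \gtrless 2}
#' predicts.
#'
#' @param net a [cascade_network()] with subcritical `A` (spectral radius
#'   < 1).
#' @param kernel a [exp_kernel()] (default `tau = 1`).
#' @param dt time step; aborts if any \eqn{\lambda_i\, \delta t \ge 1}.
#' @param T duration.
#' @param seed optional RNG seed.
#' @return A list of class `mv_hawkes_sim` with `events` (node-tagged
#'   [event_series()]), `rates_empirical` (per-node event counts over `T`)
#'   and the configuration.  Use `split_events()` to get per-node series.
#' @examples
#' net <- make_network("er", N = 10, c = 0.2, R0 = 0.3, rho = 0.5, seed = 1)
#' sim <- simulate_multivariate(net, T = 200, seed = 2)
#' cbind(empirical = sim$rates_empirical, analytic = mean_rates(net))
#' @export
simulate_multivariate <- function(net, kernel = exp_kernel(1), dt = 0.01, T,
                                  seed = NULL) {
  net <- as_cascade_network(net)
  sr <- spectral_radius(net$A)
  if (sr >= 1)
    stop(sprintf("supercritical network: spectral radius %.6g >= 1", sr),
         call. = FALSE)
  if (!inherits(kernel, "hawkes_kernel")) stop("'kernel' must come from exp_kernel()")
  if (dt <= 0 || T <= 0) stop("'dt' and 'T' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  N <- net$N
  tau <- kernel$tau
  dec <- exp(-dt / tau)
  A <- net$A
  rho <- net$rho
  nstep <- floor(T / dt)
  z <- numeric(N)                     # z_j = sum_k h(t - t_k^(j))
  t_buf <- vector("list", 1024L); id_buf <- vector("list", 1024L); nb <- 0L
  counts <- integer(N)

  for (s in seq_len(nstep)) {
    lam <- rho + as.vector(A %*% z)
    pr <- lam * dt
    if (any(pr >= 1)) stop("lambda * dt reached 1; use a smaller 'dt'",
                           call. = FALSE)
    fired <- which(runif(N) < pr)
    z <- z * dec
    if (length(fired)) {
      z[fired] <- z[fired] + 1 / tau
      counts[fired] <- counts[fired] + 1L
      nb <- nb + 1L
      t_buf[[nb]] <- rep.int((s - 1L) * dt, length(fired))
      id_buf[[nb]] <- fired
      if (nb == length(t_buf)) {
        t_buf <- c(t_buf, vector("list", nb))
        id_buf <- c(id_buf, vector("list", nb))
      }
    }
  }
  times <- unlist(t_buf[seq_len(nb)], use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  ids <- unlist(id_buf[seq_len(nb)], use.names = FALSE)
  structure(list(events = event_series(times, T = T, node_ids = ids),
                 rates_empirical = counts / T, net = net, dt = dt, T = T),
            class = "mv_hawkes_sim")
}

#' @export
print.mv_hawkes_sim <- function(x, ...) {
  cat(sprintf("Multivariate Hawkes simulation on %d nodes, T = %g\n",
              x$net$N, x$T))
  print(x$events)
  invisible(x)
}

#' Split a node-tagged event series by node
#'
#' @param es an [event_series()] with `node_ids`.
#' @param nodes which nodes to extract (default: all observed).
#' @return A named list of single-node [event_series()] objects sharing the
#'   parent's observation span.
#' @export
split_events <- function(es, nodes = NULL) {
  es <- as_event_series(es)
  if (is.null(es$node_ids)) stop("event series carries no node ids", call. = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(es$node_ids))
  out <- lapply(nodes, function(n)
    event_series(es$times[es$node_ids == n], T = es$T))
  names(out) <- as.character(nodes)
  out
}
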