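#' Microscopic SIS Markov process with spontaneous activation
#'
#' Simulates the agent-level stochastic counterpart of the revised SIS model
#' in synchronous discrete time.  In each step of length `dt`, every
#' susceptible individual independently becomes infected with probability
#' \eqn{(\beta i + \rho/N)\,\delta t}, where \eqn{i} is the infected
#' fraction at the start of the step, and every infected individual regains
#' susceptibility with probability \eqn{\gamma\,\delta t}.  Each transition
#' shifts \eqn{i} by \eqn{\pm 1/N}.  The recorded events are the infection
#' (S to I) times; recoveries are not events.
#'
#' `rho` is the *population-level* spontaneous rate: the whole population
#' generates spontaneous events at rate \eqn{\approx\rho} regardless of `N`,
#' which makes the pooled event stream directly comparable to a Hawkes
#' process with base rate \eqn{\rho} (see [simulate_hawkes()]).  In the
#' subcritical regime the infected pool stays microscopic and each infection
#' triggers on average \eqn{R_0 = \beta/\gamma} further infections, so the
#' pooled stream undergoes the stationary--nonstationary transition near
#' \eqn{R_0 = 1 - 1/\sqrt 2}, far below the epidemic threshold.
#'
#' @param params an object from [sis_params()] (`rho` read as the population
#'   rate).
#' @param N population size.
#' @param dt time step; all per-step probabilities must stay below 1.
#' @param T duration.
#' @param i0 initial infected fraction (default 0).
#' @param seed optional RNG seed for reproducibility.
#' @param track_ids record which individual each infection hit (default
#'   `TRUE`; infected-set bookkeeping is only touched on steps with events,
#'   so this is cheap).
#' @return A list of class `markov_sim` with `events` (an [event_series()]
#'   of infection times, node-tagged when `track_ids`), `infected` (the
#'   infected-count trajectory, one entry per step start) and the
#'   configuration.
#' @examples
#' sim <- simulate_markov(sis_params(0.06, 0.3, 0.5), N = 200, dt = 0.01,
#'                        T = 200, seed = 1)
#' sim$events
#' @export
simulate_markov <- function(params, N, dt = 0.01, T, i0 = 0, seed = NULL,
                            track_ids = TRUE) {
  p <- as_sis_params(params)
  if (!is.numeric(N) || N < 1) stop("'N' must be a positive count", call. = FALSE)
  N <- as.integer(N)
  if (dt <= 0 || T <= 0) stop("'dt' and 'T' must be positive", call. = FALSE)
  if ((p$beta + p$rho / N) * dt >= 1 || p$gamma * dt >= 1)
    stop("per-step probability reaches 1; use a smaller 'dt'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  nstep <- floor(T / dt)
  I <- as.integer(round(i0 * N))
  infected <- integer(nstep)
  inf_state <- if (track_ids) {
    s <- logical(N); if (I > 0) s[seq_len(I)] <- TRUE; s
  } else NULL
  t_buf <- vector("list", 1024L); id_buf <- vector("list", 1024L); nb <- 0L

  for (s in seq_len(nstep)) {
    infected[s] <- I
    p_inf <- (p$beta * I / N + p$rho / N) * dt
    n_inf <- rbinom(1L, N - I, p_inf)
    n_rec <- rbinom(1L, I, p$gamma * dt)
    if (n_inf > 0L) {
      nb <- nb + 1L
      t_buf[[nb]] <- rep.int((s - 1L) * dt, n_inf)
      if (track_ids) {
        ids <- sample(which(!inf_state), n_inf)
        inf_state[ids] <- TRUE
        id_buf[[nb]] <- ids
      }
      if (nb == length(t_buf)) {
        t_buf <- c(t_buf, vector("list", nb))
        id_buf <- c(id_buf, vector("list", nb))
      }
    }
    if (track_ids && n_rec > 0L)
      inf_state[sample(which(inf_state), n_rec)] <- FALSE
    I <- I + n_inf - n_rec
  }

  times <- unlist(t_buf[seq_len(nb)], use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  ids <- if (track_ids) unlist(id_buf[seq_len(nb)], use.names = FALSE) else NULL
  structure(list(
    events = event_series(times, T = T, node_ids = ids),
    infected = infected,
    params = p, N = N, dt = dt, T = T
  ), class = "markov_sim")
}

#' @export
print.markov_sim <- function(x, ...) {
  cat(sprintf("SIS Markov simulation: N = %d, T = %g, dt = %g (R0 = %g)\n",
              x$N, x$T, x$dt, x$params$R0))
  print(x$events)
  invisible(x)
}

#' Locate the SN transition by sweeping the reproduction ratio
#'
#' For each value of \eqn{R_0} on a grid, runs replicate simulations of the
#' SIS Markov process (or of the univariate Hawkes process), pools the event
#' times, applies [optimal_binsize()], and records the median inverse
#' optimal bin width \eqn{1/\Delta^*} across replicates.  Stationary series
#' give \eqn{1/\Delta^* = 0} (diverging bin size); the estimated critical
#' point \eqn{R_c} is the smallest grid value from which the median departs
#' from zero *and stays departed* through the top of the grid, so that an
#' isolated false detection below the transition does not set it.
#'
#' @param gamma recovery rate (Markov) or inverse refractory period
#'   (revised Hawkes); ignored for `model = "hawkes"` with
#'   `variant = "original"`.
#' @param rho population spontaneous rate.
#' @param N population size.
#' @param R0_grid increasing grid of reproduction ratios, all `< 1`.
#' @param replicates simulations per grid point (default 5).
#' @param model `"markov"` (default) or `"hawkes"`.
#' @param variant for the Hawkes model, `"revised"` (refractory, default) or
#'   `"original"`.
#' @param dt,T simulation step and duration.
#' @param tau kernel time constant for the Hawkes model.
#' @param seed RNG seed.
#' @param min_events grid points whose runs yield fewer pooled events than
#'   this are marked unusable with a warning (default 50).
#' @return A list of class `sn_sweep` with `R0_grid`, `median_inv` (median
#'   \eqn{1/\Delta^*} per grid point), `inv_all` (replicates-by-grid
#'   matrix), `R_c` (`Inf` when no departure is seen) and the
#'   configuration.
#' @examples
#' \donttest{
#' sw <- sweep_critical_R(gamma = 0.3, rho = 0.5, N = 1000,
#'                        R0_grid = seq(0.1, 0.6, 0.1), replicates = 3,
#'                        T = 1000, seed = 1)
#' sw$R_c
#' }
#' @export
sweep_critical_R <- function(gamma, rho, N, R0_grid, replicates = 5,
                             model = c("markov", "hawkes"),
                             variant = c("revised", "original"),
                             dt = 0.01, T = 2000, tau = 1, seed = NULL,
                             min_events = 50) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  if (any(diff(R0_grid) <= 0)) stop("'R0_grid' must be increasing", call. = FALSE)
  if (any(R0_grid >= 1)) stop("'R0_grid' values must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  inv_all <- matrix(NA_real_, nrow = replicates, ncol = length(R0_grid))
  usable <- rep(TRUE, length(R0_grid))
  for (gi in seq_along(R0_grid)) {
    R0 <- R0_grid[gi]
    for (r in seq_len(replicates)) {
      es <- if (model == "markov") {
        simulate_markov(sis_params(R0 * gamma, gamma, rho), N = N, dt = dt,
                        T = T, track_ids = FALSE)$events
      } else {
        simulate_hawkes(hawkes_params(rho = rho, R0 = R0, gamma = gamma,
                                      tau = tau, model = variant),
                        N = N, dt = dt, T = T)$events
      }
      if (length(es$times) < min_events) {
        warning(sprintf("R0 = %g: only %d events; grid point marked unusable",
                        R0, length(es$times)))
        usable[gi] <- FALSE
        break
      }
      inv_all[r, gi] <- optimal_binsize(es)$inv_delta_star
    }
  }
  med <- apply(inv_all, 2, median)
  med[!usable] <- NA_real_
  # sustained departure: the smallest grid R0 from which the median stays
  # positive through the top of the grid (isolated noise-induced positives
  # below the transition do not count)
  ok <- usable & !is.na(med)
  R_c <- Inf
  for (gi in rev(seq_along(R0_grid))) {
    if (!ok[gi]) next
    if (med[gi] > 0) R_c <- R0_grid[gi] else break
  }
  structure(list(R0_grid = R0_grid, median_inv = med, inv_all = inv_all,
                 usable = usable,
                 R_c = R_c,
                 model = model, variant = variant, gamma = gamma, rho = rho,
                 N = N, dt = dt, T = T, replicates = replicates),
            class = "sn_sweep")
}

#' @export
print.sn_sweep <- function(x, ...) {
  cat(sprintf("SN sweep (%s%s): gamma = %g, rho = %g, N = %d, T = %g\n",
              x$model, if (x$model == "hawkes") paste0("/", x$variant) else "",
              x$gamma, x$rho, x$N, x$T))
  print(data.frame(R0 = x$R0_grid, median_inv_delta_star = x$median_inv))
  cat(sprintf("Estimated SN critical point R_c = %s\n",
              if (is.finite(x$R_c)) format(x$R_c) else "none on grid (Inf)"))
  invisible(x)
}

#' @export
plot.sn_sweep <- function(x, ...) {
  plot(x$R0_grid, x$median_inv, type = "b", xlab = expression(R[0]),
       ylab = expression(1 / Delta^"*"), ...)
  if (is.finite(x$R_c)) abline(v = x$R_c, lty = 2)
  invisible(x)
}
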