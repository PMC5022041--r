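#' Exponential history kernel
#'
#' Normalized causal kernel \eqn{h(t) = e^{-t/\tau}/\tau} for \eqn{t \ge 0}
#' and 0 otherwise.  The kernel weighs the influence of a past event on the
#' current event rate; its unit integral makes \eqn{R_0} the expected number
#' of directly induced events.
#'
#' @param tau time constant (> 0).
#' @return An object of class `hawkes_kernel` with fields `family`, `tau`
#'   and the evaluator `h(t)`.
#' @examples
#' k <- exp_kernel(tau = 1)
#' k$h(c(-1, 0, 1))       # 0, 1, exp(-1)
#' @export
exp_kernel <- function(tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a positive scalar", call. = FALSE)
  force(tau)
  structure(list(family = "exponential", tau = tau,
                 h = function(t) ifelse(t >= 0, exp(-t / tau) / tau, 0)),
            class = "hawkes_kernel")
}

#' @export
print.hawkes_kernel <- function(x, ...) {
  cat(sprintf("Hawkes kernel: %s, tau = %g\n", x$family, x$tau))
  invisible(x)
}

#' Parameters of the univariate Hawkes process
#'
#' The original linear self-exciting process has intensity
#' \deqn{\lambda(t) = \rho + R_0 \sum_k h(t - t_k),}
#' where `rho` is the base rate of spontaneous events, `R0 < 1` the
#' reproduction ratio, and `h` a normalized causal kernel.  The revised form
#' introduces a refractory period \eqn{1/\gamma}: among `N` individuals
#' sharing the drive, those that produced an event within the last
#' \eqn{1/\gamma} time units cannot fire, so the intensity is multiplied by
#' the non-refractory fraction \eqn{1 - r(t)}.  This removes the artificial
#' divergence of the mean rate at \eqn{R_0 = 1}.
#'
#' @param rho base rate (events/time) of the whole process.
#' @param R0 reproduction ratio; must satisfy `0 <= R0 < 1` for the original
#'   model.
#' @param gamma inverse refractory period (1/time); `Inf` recovers the
#'   original model.
#' @param tau exponential kernel time constant.
#' @param model `"original"` or `"revised"`; defaults to `"revised"` when
#'   `gamma` is finite, `"original"` otherwise.
#' @return An object of class `hawkes_params`.
#' @export
hawkes_params <- function(rho, R0, gamma = Inf, tau = 1, model = NULL) {
  if (rho < 0) stop("'rho' must be non-negative", call. = FALSE)
  if (R0 < 0) stop("'R0' must be non-negative", call. = FALSE)
  if (!is.infinite(gamma) && gamma <= 0)
    stop("'gamma' must be positive or Inf", call. = FALSE)
  if (is.null(model)) model <- if (is.finite(gamma)) "revised" else "original"
  model <- match.arg(model, c("original", "revised"))
  if (model == "revised" && !is.finite(gamma))
    stop("the revised model needs a finite 'gamma'", call. = FALSE)
  structure(list(rho = rho, R0 = R0, gamma = gamma,
                 kernel = exp_kernel(tau), model = model),
            class = "hawkes_params")
}

#' @export
print.hawkes_params <- function(x, ...) {
  cat(sprintf("Hawkes parameters (%s): rho = %g, R0 = %g%s, kernel tau = %g\n",
              x$model, x$rho, x$R0,
              if (is.finite(x$gamma)) sprintf(", 1/gamma = %g", 1 / x$gamma) else "",
              x$kernel$tau))
  invisible(x)
}

#' Analytic mean event rate of the Hawkes process
#'
#' Original model: \eqn{\langle\lambda\rangle = \rho / (1 - R_0)}, diverging
#' as \eqn{R_0 \to 1}.  Revised (refractory) model: the ensemble average
#' with \eqn{\langle\lambda^2\rangle \approx \langle\lambda\rangle^2} maps
#' the process onto the revised SIS model with \eqn{\beta = R_0\gamma}, so
#' at scale `N` the mean rate is \eqn{N \gamma\, i_\infty} with
#' \eqn{i_\infty} = [sis_equilibrium()] at spontaneous rate \eqn{\rho/N}.
#' At the default `N = 1` this is \eqn{\gamma\, i_\infty(\beta = R_0\gamma,
#' \gamma, \rho)}, finite for every \eqn{R_0}.
#'
#' @param params an object from [hawkes_params()].
#' @param N scale of the revised model (number of individuals sharing the
#'   drive); irrelevant for the original model.
#' @return The mean rate (events/time).
#' @examples
#' hawkes_mean_rate(hawkes_params(rho = 0.5, R0 = 0.2))           # 0.625
#' hawkes_mean_rate(hawkes_params(rho = 0.5, R0 = 0.2, gamma = 0.3))
#' @export
hawkes_mean_rate <- function(params, N = 1) {
  p <- params
  if (!inherits(p, "hawkes_params")) stop("'params' must come from hawkes_params()")
  if (p$model == "original") {
    if (p$R0 >= 1)
      stop("mean rate diverges: R0 >= 1 in the original model", call. = FALSE)
    return(p$rho / (1 - p$R0))
  }
  N * p$gamma * sis_equilibrium(sis_params(p$R0 * p$gamma, p$gamma, p$rho / N))
}

#' Simulate the univariate Hawkes process
#'
#' Discrete-time Bernoulli-trial simulation: in every interval `dt` an event
#' occurs with probability \eqn{\lambda(t)\,\delta t}.  The exponential
#' kernel admits an O(1)-per-step recursive update of the excitation
#' \eqn{z(t) = \sum_k h(t - t_k)}.  For the revised model each event sends
#' one of the `N` individuals into a refractory window of length
#' \eqn{1/\gamma} and the intensity is \eqn{(1 - r(t))(\rho + R_0 z(t))}
#' with \eqn{r(t)} the refractory fraction.
#'
#' @param params an object from [hawkes_params()].
#' @param N number of individuals sharing the drive (refractory bookkeeping
#'   scale; the original model does not use it).
#' @param dt time step; the simulation aborts if \eqn{\lambda\,\delta t \ge 1}
#'   at any step.
#' @param T duration.
#' @param seed optional RNG seed.
#' @return A list of class `hawkes_sim` with `events` (an [event_series()])
#'   and the configuration.
#' @examples
#' sim <- simulate_hawkes(hawkes_params(rho = 0.5, R0 = 0.2), T = 500, seed = 1)
#' length(sim$events$times) / 500    # ~ 0.625
#' @export
simulate_hawkes <- function(params, N = 1000, dt = 0.01, T, seed = NULL) {
  p <- params
  if (!inherits(p, "hawkes_params")) stop("'params' must come from hawkes_params()")
  if (p$model == "original" && p$R0 >= 1)
    stop("original model with R0 >= 1 is supercritical", call. = FALSE)
  if (dt <= 0 || T <= 0) stop("'dt' and 'T' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  nstep <- floor(T / dt)
  tau <- p$kernel$tau
  dec <- exp(-dt / tau)
  revised <- p$model == "revised"
  refr_steps <- if (revised) max(1L, as.integer(round(1 / (p$gamma * dt)))) else 0L
  # circular buffer of event counts entering refractory at each step
  refr_buf <- integer(max(refr_steps, 1L))
  r_cnt <- 0L
  z <- 0
  t_buf <- vector("list", 1024L); nb <- 0L

  for (s in seq_len(nstep)) {
    lam <- p$rho + p$R0 * z
    if (revised) lam <- lam * (1 - r_cnt / N)
    pr <- lam * dt
    if (pr >= 1) stop("lambda * dt reached 1; use a smaller 'dt'", call. = FALSE)
    ev <- runif(1) < pr
    if (ev) {
      nb <- nb + 1L
      t_buf[[nb]] <- (s - 1L) * dt
      if (nb == length(t_buf)) t_buf <- c(t_buf, vector("list", nb))
    }
    if (revised) {
      slot <- (s - 1L) %% refr_steps + 1L
      r_cnt <- r_cnt - refr_buf[slot]       # individuals leaving refractory
      refr_buf[slot] <- 0L
      if (ev) {
        refr_buf[slot] <- 1L                # re-enters circulation in 1/gamma
        r_cnt <- r_cnt + 1L
      }
    }
    z <- z * dec + if (ev) 1 / tau else 0
  }
  times <- unlist(t_buf[seq_len(nb)], use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  structure(list(events = event_series(times, T = T), params = p,
                 N = N, dt = dt, T = T),
            class = "hawkes_sim")
}

#' @export
print.hawkes_sim <- function(x, ...) {
  cat(sprintf("Hawkes simulation (%s): rho = %g, R0 = %g, T = %g\n",
              x$params$model, x$params$rho, x$params$R0, x$T))
  print(x$events)
  invisible(x)
}
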