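#' Parameters of the revised SIS model
#'
#' Bundles the rates of the susceptible--infected--susceptible model with
#' spontaneous activation.  Susceptible individuals become infected at rate
#' \eqn{\beta i + \rho} (contact infection plus a spontaneous inflow) and
#' infected individuals recover at rate \eqn{\gamma}, so the fraction of
#' infected individuals follows
#' \deqn{di/dt = -\gamma i + (1 - i)(\rho + \beta i).}
#' The reproduction ratio \eqn{R_0 = \beta/\gamma} is stored as a derived
#' field.
#'
#' @param beta infection rate (1/time), `beta >= 0`.
#' @param gamma recovery rate (1/time), `gamma > 0`.
#' @param rho spontaneous activation rate (1/time), `rho >= 0`.
#' @return An object of class `sis_params` with fields `beta`, `gamma`,
#'   `rho` and `R0 = beta/gamma`.
#' @examples
#' sis_params(beta = 0.06, gamma = 0.3, rho = 0.5)
#' @export
sis_params <- function(beta, gamma, rho) {
  for (v in list(beta = beta, gamma = gamma, rho = rho)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("SIS rates must be finite numeric scalars", call. = FALSE)
  }
  if (beta < 0 || rho < 0) stop("'beta' and 'rho' must be non-negative", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, rho = rho, R0 = beta / gamma),
            class = "sis_params")
}

#' @export
print.sis_params <- function(x, ...) {
  cat(sprintf("SIS parameters: beta = %g, gamma = %g, rho = %g (R0 = %g)\n",
              x$beta, x$gamma, x$rho, x$R0))
  invisible(x)
}

as_sis_params <- function(params) {
  if (inherits(params, "sis_params")) return(params)
  if (is.list(params) && all(c("beta", "gamma", "rho") %in% names(params)))
    return(sis_params(params$beta, params$gamma, params$rho))
  stop("'params' must be created by sis_params()", call. = FALSE)
}

#' Equilibrium infected fraction of the revised SIS model
#'
#' Solves the fixed point of \eqn{di/dt = -\gamma i + (1-i)(\rho + \beta i)},
#' i.e. the quadratic \eqn{\beta i^2 + (\gamma + \rho - \beta) i - \rho = 0},
#' returning the root in \eqn{[0, 1]}.  With `rho = 0` this reduces to the
#' classic SIS equilibrium: 0 for \eqn{R_0 \le 1} and \eqn{1 - 1/R_0}
#' otherwise.  With `rho > 0` the epidemic transition at \eqn{R_0 = 1} is
#' softened and the equilibrium increases smoothly with \eqn{R_0}.
#'
#' @param params an object from [sis_params()].
#' @return The asymptotic infected fraction, a number in \eqn{[0, 1]}.
#' @examples
#' sis_equilibrium(sis_params(2, 1, 0))          # 1 - 1/R0 = 0.5
#' sis_equilibrium(sis_params(0.06, 0.3, 0.5))   # positive root of quadratic
#' @export
sis_equilibrium <- function(params) {
  p <- as_sis_params(params)
  if (p$beta == 0) return(min(1, p$rho / (p$gamma + p$rho)))
  # beta i^2 + (gamma + rho - beta) i - rho = 0, take the root in [0, 1]
  b <- p$gamma + p$rho - p$beta
  disc <- b^2 + 4 * p$beta * p$rho
  if (disc < 0) disc <- 0          # numerically marginal; exact disc >= 0
  i <- (-b + sqrt(disc)) / (2 * p$beta)
  if (p$rho == 0) i <- if (p$R0 <= 1) 0 else 1 - 1 / p$R0
  min(max(i, 0), 1)
}

#' Integrate the revised SIS mean-field dynamics
#'
#' Integrates \eqn{di/dt = -\gamma i + (1-i)(\rho + \beta i)} from `i0` over
#' `t_grid` with an adaptive Runge--Kutta scheme (via \pkg{deSolve}).
#'
#' @param params an object from [sis_params()].
#' @param i0 initial infected fraction in \eqn{[0, 1]}.
#' @param t_grid increasing vector of output times (the first entry is the
#'   initial time).
#' @return A data.frame with columns `time` and `i`.
#' @examples
#' tr <- sis_integrate(sis_params(0.18, 0.3, 0.5), i0 = 0, t_grid = seq(0, 60, 0.5))
#' tail(tr, 1)$i - sis_equilibrium(sis_params(0.18, 0.3, 0.5))   # ~ 0
#' @export
sis_integrate <- function(params, i0, t_grid) {
  p <- as_sis_params(params)
  if (!is.numeric(i0) || length(i0) != 1L || i0 < 0 || i0 > 1)
    stop("'i0' must be a fraction in [0, 1]", call. = FALSE)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be increasing with at least two points", call. = FALSE)
  drift <- function(t, y, parms) {
    i <- min(max(y[1], 0), 1)
    list(-p$gamma * i + (1 - i) * (p$rho + p$beta * i))
  }
  sol <- deSolve::ode(y = c(i = i0), times = t_grid, func = drift,
                      parms = NULL, method = "ode45", atol = 1e-9, rtol = 1e-9)
  data.frame(time = sol[, "time"], i = pmin(pmax(sol[, "i"], 0), 1))
}
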