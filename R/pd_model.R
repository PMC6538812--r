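#' Pharmacodynamic parameters of the treatment-response model
#'
#' The cell population follows logistic growth with a time-dependent death
#' rate switched on at treatment time `t = 0`:
#' \deqn{dN/dt = (k_p - k_d(t)) N (1 - N/\theta)}
#' The death rate mixes two empirical kernels: an immediately induced stable
#' rate (apoptosis-like) and a smoothly induced, decaying rate
#' (mitotic-catastrophe-like):
#' \deqn{k_d(t) = (1-\lambda) k_{d,a} + \lambda k_{d,b} \, r t \, e^{1 - r t},
#'   \quad t \ge 0}
#' and `k_d(t) = 0` for `t < 0`. The transient kernel attains its maximum
#' `k_d_b` at `t = 1/r` and decays to zero, allowing population recovery.
#'
#' `lam`, `k_d_a` and `k_d_b` enter only through the products
#' `(1-lam) k_d_a` and `lam k_d_b`, so `lam` is treated as a fixed mixing
#' weight (set by study configuration), not a free parameter.
#'
#' @param k_p Proliferation rate, 1/h.
#' @param theta Carrying capacity of the plate, cells.
#' @param k_d_a Stable post-treatment death rate, 1/h.
#' @param k_d_b Peak transient death rate, 1/h.
#' @param r Induction/decay rate of the transient kernel, 1/h.
#' @param lam Convex weight in `[0, 1]` mixing the two kernels
#'   (`0` = pure stable, `1` = pure transient). Default `0.5`.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(k_p, theta, k_d_a = 0, k_d_b = 0, r = 0.1, lam = 0.5) {
  vals <- c(k_p = k_p, theta = theta, k_d_a = k_d_a, k_d_b = k_d_b,
            r = r, lam = lam)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (k_p < 0 || k_d_a < 0 || k_d_b < 0 || r < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (theta <= 0) stop("'theta' must be positive", call. = FALSE)
  if (lam < 0 || lam > 1) stop("'lam' must lie in [0, 1]", call. = FALSE)
  structure(as.list(vals), class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf(
    "PD parameters: k_p = %g/h, theta = %g, k_d_a = %g/h, k_d_b = %g/h, r = %g/h, lam = %g\n",
    x$k_p, x$theta, x$k_d_a, x$k_d_b, x$r, x$lam))
  invisible(x)
}

#' Time-dependent death rate
#'
#' Evaluates the mixed death-rate kernel of the treatment-response model:
#' zero before treatment, and for `t >= 0`
#' `(1 - lam) * k_d_a + lam * k_d_b * r * t * exp(1 - r * t)`.
#'
#' @param t Time(s) since treatment, hours; vectorized.
#' @param p A [pd_params()] object.
#' @return Death rate(s), 1/h.
#' @export
#' @examples
#' p <- pd_params(k_p = 0.02, theta = 2e4, k_d_a = 0.01, k_d_b = 0.03,
#'                r = 0.05, lam = 1)
#' death_rate(1 / p$r, p)  # transient kernel peak: exactly k_d_b
death_rate <- function(t, p) {
  stopifnot(inherits(p, "pd_params"))
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (1 - p$lam) * p$k_d_a +
    p$lam * p$k_d_b * p$r * t[pos] * exp(1 - p$r * t[pos])
  out
}

#' Simulate noise-free cell counts
#'
#' Evaluates the logistic treatment-response model on a time grid. The model
#' `dN/dt = g(t) N (1 - N/theta)` with `g(t) = k_p - k_d(t)` is a
#' time-changed logistic: substituting `y = 1/N` linearizes it and the
#' forcing integral collapses analytically, giving
#' \deqn{N(t) = \frac{\theta N_0 e^{G(t)}}{\theta + N_0 (e^{G(t)} - 1)},
#'   \qquad G(t) = \int_0^t (k_p - k_d(s))\,ds,}
#' where `G` has a closed form for the death-rate kernel (the transient term
#' integrates to `lam * k_d_b * (e/r) * (1 - (1 + r t) exp(-r t))`). The
#' default `method = "closed"` evaluates this exactly; `method = "lsoda"`
#' integrates the ODE adaptively as an independent cross-check.
#' Pre-treatment times use the plain logistic with the bare proliferation
#' rate. Because the net rate is multiplied by `(1 - N/theta)`, `theta` is
#' an absorbing ceiling: trajectories started below it never cross it.
#'
#' @param p A [pd_params()] object.
#' @param N0 Cell count at `t = 0` (treatment time).
#' @param times Sorted sample times in hours; negative values are
#'   pre-treatment.
#' @param method `"closed"` (exact, default) or `"lsoda"`.
#' @param rtol,atol Tolerances for the adaptive method.
#' @return Data frame with columns `time_h` and `count` (model means).
#' @export
simulate_counts <- function(p, N0, times, method = c("closed", "lsoda"),
                            rtol = 1e-10, atol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(p, "pd_params"))
  if (!is.numeric(N0) || length(N0) != 1L || N0 < 0)
    stop("'N0' must be a single non-negative count", call. = FALSE)
  if (length(times) == 0L || any(!is.finite(times)))
    stop("'times' must be a non-empty finite vector", call. = FALSE)
  if (any(diff(times) < 0)) stop("'times' must be sorted", call. = FALSE)

  counts <- numeric(length(times))
  neg <- times < 0
  ## pre-treatment: plain logistic, closed form
  if (any(neg)) counts[neg] <- logistic_closed(N0, p$k_p, p$theta, times[neg])

  if (any(!neg)) {
    tt <- times[!neg]
    if (N0 == 0) {
      counts[!neg] <- 0
    } else if (method == "closed") {
      eg <- exp(net_growth_integral(tt, p))
      counts[!neg] <- p$theta * N0 * eg / (p$theta + N0 * (eg - 1))
    } else {
      grid <- sort(unique(c(0, tt)))
      rhs <- function(t, y, parms) {
        kd <- (1 - p$lam) * p$k_d_a +
          p$lam * p$k_d_b * p$r * t * exp(1 - p$r * t)
        list((p$k_p - kd) * y * (1 - y / p$theta))
      }
      sol <- deSolve::ode(y = N0, times = grid, func = rhs, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
      sol_at <- pmax(sol[, 2], 0)
      counts[!neg] <- sol_at[match(round(tt, 12), round(grid, 12))]
    }
  }
  data.frame(time_h = as.numeric(times), count = counts)
}

## cumulative net growth exponent G(t) = integral of (k_p - k_d) over [0, t]
net_growth_integral <- function(t, p) {
  base <- (p$k_p - (1 - p$lam) * p$k_d_a) * t
  if (p$lam > 0 && p$k_d_b > 0 && p$r > 0) {
    base <- base -
      p$lam * p$k_d_b * exp(1) / p$r * (1 - (1 + p$r * t) * exp(-p$r * t))
  }
  base
}

## closed-form logistic through N(0) = N0 evaluated at (possibly negative) t
logistic_closed <- function(N0, k_p, theta, t) {
  if (N0 == 0) return(rep(0, length(t)))
  e <- exp(k_p * t)
  theta * N0 * e / (theta + N0 * (e - 1))
}
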