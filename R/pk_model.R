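#' Pharmacokinetic rate constants for the three-compartment uptake model
#'
#' Constructs and validates the parameter set of the doxorubicin uptake model.
#' Drug moves between three compartments: extracellular (`C_E`), free
#' intracellular (`C_F`) and nucleus-bound (`C_B`):
#' \deqn{dC_E/dt = k_{FE} C_F / v - k_{EF} C_E}
#' \deqn{dC_F/dt = k_{EF} v C_E - (k_{FE} + k_{FB}) C_F}
#' \deqn{dC_B/dt = k_{FB} C_F}
#' where `v = v_ratio` is the extracellular-to-intracellular volume ratio.
#' The weighted total `v * C_E + C_F + C_B` is conserved between
#' media-replacement events.
#'
#' Only the product `k_EF * v_ratio` is identifiable from intracellular data
#' alone, so `v_ratio` is carried as a fixed configuration value rather than a
#' fitted quantity.
#'
#' @param k_EF Influx rate constant, extracellular to free intracellular, 1/h.
#' @param k_FE Efflux rate constant, free intracellular to extracellular, 1/h.
#' @param k_FB Net binding rate constant (binding mixed with DNA repair), 1/h.
#' @param v_ratio Extracellular over intracellular compartment volume, a
#'   positive dimensionless ratio. Only the product `k_EF * v_ratio` is
#'   identifiable from intracellular data, so this is an effective
#'   calibration rather than a measured geometry. The default `1.5e5`
#'   reproduces the signal scale of the reference uptake assay (peak
#'   intracellular concentration ~1.4 uM under 1 uM applied drug, so the
#'   ~50 nM measurement noise is a few percent of signal).
#' @return An object of class `pk_params`.
#' @export
#' @examples
#' pk_params(k_EF = 3.08e-6, k_FE = 0.313, k_FB = 0.0212)
pk_params <- function(k_EF, k_FE, k_FB, v_ratio = 1.5e5) {
  for (nm in c("k_EF", "k_FE", "k_FB", "v_ratio")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (k_EF < 0 || k_FE < 0 || k_FB < 0)
    stop("rate constants must be non-negative", call. = FALSE)
  if (v_ratio <= 0) stop("'v_ratio' must be positive", call. = FALSE)
  structure(list(k_EF = k_EF, k_FE = k_FE, k_FB = k_FB, v_ratio = v_ratio),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Three-compartment PK parameters (1/h):\n")
  cat(sprintf("  k_EF = %g   k_FE = %g   k_FB = %g   v_ratio = %g\n",
              x$k_EF, x$k_FE, x$k_FB, x$v_ratio))
  invisible(x)
}

#' Piecewise treatment schedule
#'
#' A treatment course is an ordered list of media-replacement events, each
#' instantaneously setting the extracellular drug concentration (the free and
#' bound intracellular compartments are continuous across events), plus an end
#' time. A typical uptake assay is one application followed by a washout:
#' `treatment_course(times_h = c(0, 8), conc_nM = c(1000, 0), horizon_h = 24)`.
#'
#' @param times_h Strictly increasing event times, hours. The first event is
#'   usually at `t = 0`.
#' @param conc_nM Non-negative extracellular concentrations set at each event,
#'   nM.
#' @param horizon_h End of the observation window, hours; must be at or after
#'   the last event.
#' @return An object of class `treatment_course`.
#' @export
treatment_course <- function(times_h, conc_nM, horizon_h) {
  if (length(times_h) != length(conc_nM) || length(times_h) == 0L)
    stop("'times_h' and 'conc_nM' must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(times_h)) || any(!is.finite(conc_nM)))
    stop("event times and concentrations must be finite", call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (any(conc_nM < 0))
    stop("event concentrations must be non-negative", call. = FALSE)
  if (!is.numeric(horizon_h) || length(horizon_h) != 1L ||
      horizon_h < times_h[length(times_h)])
    stop("'horizon_h' must be a single time at or after the last event",
         call. = FALSE)
  structure(list(times_h = as.numeric(times_h), conc_nM = as.numeric(conc_nM),
                 horizon_h = as.numeric(horizon_h)),
            class = "treatment_course")
}

#' @export
print.treatment_course <- function(x, ...) {
  cat("Treatment course (horizon", x$horizon_h, "h):\n")
  for (i in seq_along(x$times_h))
    cat(sprintf("  t = %6g h  ->  C_E set to %g nM\n",
                x$times_h[i], x$conc_nM[i]))
  invisible(x)
}

## system matrix of the per-segment linear ODE, state order (C_E, C_F, C_B)
pk_system_matrix <- function(p) {
  matrix(c(-p$k_EF,            p$k_FE / p$v_ratio,    0,
            p$k_EF * p$v_ratio, -(p$k_FE + p$k_FB),   0,
            0,                  p$k_FB,               0),
         nrow = 3, byrow = TRUE)
}

## propagate x0 through exp(A * dt) for a vector of elapsed times.
## The matrix always has real eigenvalues (the coupled 2x2 block has
## discriminant (kFE + kFB - kEF)^2 + 4 kEF kFE >= 0); an eigendecomposition
## is used when well conditioned, with a scaling-and-squaring Pade fallback
## for the (measure-zero) defective cases.
pk_propagate <- function(A, x0, dts) {
  if (all(A == 0) || all(x0 == 0))
    return(matrix(rep(x0, length(dts)), nrow = 3))
  eg <- eigen(A)
  ok <- all(abs(Im(eg$values)) < 1e-12) &&
    is.finite(rcond(Re(eg$vectors))) && rcond(Re(eg$vectors)) > 1e-10
  if (ok) {
    V <- Re(eg$vectors)
    lam <- Re(eg$values)
    c0 <- solve(V, x0)
    out <- V %*% (exp(outer(lam, dts)) * c0)
  } else {
    out <- vapply(dts, function(dt) c(expm_pade(A * dt) %*% x0), numeric(3))
    out <- matrix(out, nrow = 3)
  }
  out
}

## scaling-and-squaring Pade(6) matrix exponential for small dense matrices
expm_pade <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin)) + 1))
  As <- A / 2^s
  X <- As
  c_ <- 0.5
  E <- diag(n) + c_ * As
  D <- diag(n) - c_ * As
  q <- 6L
  sgn <- -1
  for (k in 2:q) {
    c_ <- c_ * (q - k + 1) / (k * (2 * q - k + 1))
    X <- As %*% X
    E <- E + c_ * X
    D <- D + sgn * c_ * X
    sgn <- -sgn
  }
  Fm <- solve(D, E)
  if (s > 0) for (i in seq_len(s)) Fm <- Fm %*% Fm
  Fm
}

## segment boundaries and initial states for a course; returns per-segment
## start time, end time and the C_E reset value at segment start
course_segments <- function(course) {
  starts <- course$times_h
  ends <- c(course$times_h[-1], course$horizon_h)
  list(starts = starts, ends = ends, conc = course$conc_nM)
}

#' Simulate the three-compartment uptake model
#'
#' Integrates the linear uptake system over `[0, horizon]` under a piecewise
#' treatment schedule. Within each inter-event segment the system is linear
#' with constant coefficients, so the default path evaluates the exact
#' matrix-exponential solution (via eigendecomposition of the 3x3 system
#' matrix); `method = "lsoda"` integrates the same system with an adaptive
#' stiff-capable solver as an independent cross-check.
#'
#' At each event the extracellular concentration is reset instantaneously
#' while `C_F` and `C_B` are continuous (media replacement exchanges the
#' extracellular medium only).
#'
#' @param params A [pk_params()] object.
#' @param course A [treatment_course()] object.
#' @param times Increasing sample times in hours, within `[0, horizon]`.
#' @param method `"expm"` (exact per-segment solution, default) or `"lsoda"`.
#' @param rtol,atol Tolerances for the adaptive solver.
#' @param init Initial state `c(C_E, C_F, C_B)` at `t = 0` before any event at
#'   zero is applied. Defaults to all-zero.
#' @return A `pk_trajectory`: data frame with columns `time_h`, `C_E_nM`,
#'   `C_F_nM`, `C_B_nM`.
#' @export
#' @examples
#' p <- pk_params(k_EF = 3.08e-6, k_FE = 0.313, k_FB = 0.0212)
#' crs <- treatment_course(c(0, 8), c(1000, 0), horizon_h = 24)
#' traj <- simulate_pk(p, crs, times = seq(0, 24, by = 0.5))
#' max(traj$C_B_nM)
simulate_pk <- function(params, course, times,
                        method = c("expm", "lsoda"),
                        rtol = 1e-10, atol = 1e-10,
                        init = c(0, 0, 0)) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pk_params"), inherits(course, "treatment_course"))
  if (length(times) == 0L) stop("empty time grid", call. = FALSE)
  if (any(!is.finite(times))) stop("non-finite sample times", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE) && any(diff(times) < 0))
    stop("sample times must be non-decreasing", call. = FALSE)
  if (min(times) < 0 || max(times) > course$horizon_h + 1e-12)
    stop("sample times must lie within [0, horizon]", call. = FALSE)
  if (length(init) != 3L || any(init < 0))
    stop("'init' must be three non-negative concentrations", call. = FALSE)

  seg <- course_segments(course)
  A <- pk_system_matrix(params)
  out <- matrix(NA_real_, nrow = 3, ncol = length(times))
  x <- as.numeric(init)

  ## portion of the grid before the first event evolves from `init` with no
  ## reset (events at t = 0 cover the usual case)
  t0 <- 0
  pre <- times < seg$starts[1] - 1e-12
  if (any(pre)) {
    out[, pre] <- pk_solve_segment(A, x, times[pre] - t0, method, rtol, atol)
  }
  if (seg$starts[1] > 0) {
    x <- pk_solve_segment(A, x, seg$starts[1] - t0, method, rtol, atol)[, 1]
  }

  for (s in seq_along(seg$starts)) {
    x[1] <- seg$conc[s]                      # instantaneous media replacement
    lo <- seg$starts[s]
    hi <- seg$ends[s]
    in_seg <- times >= lo - 1e-12 & (times < hi - 1e-12 | s == length(seg$starts))
    if (any(in_seg)) {
      out[, in_seg] <- pk_solve_segment(A, x, pmax(times[in_seg] - lo, 0),
                                        method, rtol, atol)
    }
    if (s < length(seg$starts))
      x <- pk_solve_segment(A, x, hi - lo, method, rtol, atol)[, 1]
  }

  traj <- data.frame(time_h = as.numeric(times),
                     C_E_nM = pmax(out[1, ], 0),
                     C_F_nM = pmax(out[2, ], 0),
                     C_B_nM = pmax(out[3, ], 0))
  class(traj) <- c("pk_trajectory", "data.frame")
  attr(traj, "params") <- params
  attr(traj, "course") <- course
  traj
}

pk_solve_segment <- function(A, x0, dts, method, rtol, atol) {
  if (method == "expm") {
    pk_propagate(A, x0, dts)
  } else {
    tt <- sort(unique(c(0, dts)))
    sol <- deSolve::ode(y = c(E = x0[1], F = x0[2], B = x0[3]), times = tt,
                        func = function(t, y, parms) list(c(A %*% y)),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    idx <- match(round(dts, 12), round(tt, 12))
    t(unname(sol[idx, 2:4, drop = FALSE]))
  }
}

#' Equivalent dose of a treatment course
#'
#' The equivalent dose `D_eq` is the maximum nucleus-bound drug concentration
#' `C_B` predicted by the uptake model over the course. `C_B` is
#' non-decreasing (its derivative `k_FB * C_F` is non-negative), so the
#' maximum is attained at the end of the simulated window. Because `C_B`
#' keeps growing slightly after washout while the free compartment drains,
#' the simulation is extended past the course horizon (holding the last event
#' concentration) until `C_F` falls below `tail_rel_tol` times its peak, or
#' `max_tail_h` hours, whichever comes first. Set `washout_tail = FALSE` to
#' evaluate strictly on `[0, horizon]`.
#'
#' @inheritParams simulate_pk
#' @param washout_tail Extend the simulation past the horizon to capture the
#'   residual binding of drained free drug. Default `TRUE`.
#' @param tail_rel_tol Stop the tail once `C_F` is below this fraction of its
#'   running peak. Default `1e-6`.
#' @param max_tail_h Hard cap on the tail length, hours.
#' @param n_grid Number of grid points used to track the free-compartment
#'   peak.
#' @return The equivalent dose in nM (a single number), with attribute
#'   `"t_end"` giving the time at which it was evaluated.
#' @export
equivalent_dose <- function(params, course, washout_tail = TRUE,
                            tail_rel_tol = 1e-6, max_tail_h = 500,
                            n_grid = 200L) {
  stopifnot(inherits(params, "pk_params"), inherits(course, "treatment_course"))
  grid <- unique(sort(c(seq(0, course$horizon_h, length.out = n_grid),
                        course$times_h)))
  traj <- simulate_pk(params, course, grid)
  d <- max(traj$C_B_nM)
  t_end <- course$horizon_h
  ## the tail is meaningful only once the drug has actually been washed out;
  ## with drug still applied, extending would simulate a longer course
  if (washout_tail && course$conc_nM[length(course$conc_nM)] == 0) {
    A <- pk_system_matrix(params)
    x <- c(traj$C_E_nM[nrow(traj)], traj$C_F_nM[nrow(traj)],
           traj$C_B_nM[nrow(traj)])
    peak_F <- max(traj$C_F_nM, x[2])
    drain <- params$k_FE + params$k_FB
    step <- if (drain > 0) 5 / drain else max_tail_h
    elapsed <- 0
    while (x[2] > tail_rel_tol * peak_F && elapsed < max_tail_h && peak_F > 0) {
      dt <- min(step, max_tail_h - elapsed)
      sub <- pk_propagate(A, x, seq(dt / 20, dt, length.out = 20))
      peak_F <- max(peak_F, sub[2, ])
      x <- sub[, ncol(sub)]
      elapsed <- elapsed + dt
      step <- step * 1.6                 # segment solution is exact; the step
    }                                    # only paces the stopping check
    d <- max(d, x[3])
    t_end <- course$horizon_h + elapsed
  }
  structure(d, t_end = t_end)
}

#' Total drug mass tracked by a trajectory
#'
#' Returns the volume-weighted total `v_ratio * C_E + C_F + C_B` at each
#' sample time. Between media-replacement events this quantity is conserved;
#' its relative drift is the standard solver-quality diagnostic for the
#' uptake model.
#'
#' @param traj A `pk_trajectory` from [simulate_pk()].
#' @param v_ratio Volume ratio; taken from the trajectory's parameters when
#'   omitted.
#' @return Numeric vector of conserved totals, nM (extracellular-volume
#'   weighted).
#' @export
pk_total_mass <- function(traj, v_ratio = NULL) {
  if (is.null(v_ratio)) v_ratio <- attr(traj, "params")$v_ratio
  v_ratio * traj$C_E_nM + traj$C_F_nM + traj$C_B_nM
}

#' @export
plot.pk_trajectory <- function(x, ...) {
  graphics::matplot(x$time_h, cbind(x$C_F_nM, x$C_B_nM, x$C_F_nM + x$C_B_nM),
                    type = "l", lty = c(2, 3, 1), col = c(4, 2, 1),
                    xlab = "time (h)", ylab = "concentration (nM)", ...)
  graphics::legend("topleft", c("C_F", "C_B", "C_F + C_B"),
                   lty = c(2, 3, 1), col = c(4, 2, 1), bty = "n")
  invisible(x)
}
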