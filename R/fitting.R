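## ---- shared nonlinear least-squares machinery ------------------------------

## evaluate `code` under a temporary RNG seed, restoring global RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

## Latin-hypercube multistart over log-uniform ranges; rows are start vectors
lhs_starts <- function(n_starts, ranges, seed) {
  k <- nrow(ranges)
  with_local_seed(seed, {
    u <- if (n_starts > 1) lhs::randomLHS(n_starts, k)
         else matrix(0.5, 1, k)
    t(apply(u, 1, function(z)
      exp(log(ranges[, 1]) + z * (log(ranges[, 2]) - log(ranges[, 1])))))
  })
}

## run nls.lm from each start, keep the best converged fit
ms_nls <- function(res_fn, starts, lower, upper, maxiter = 200) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                     ptol = 1e-10)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(starts[i, ], lower), upper),
                         fn = res_fn, lower = lower, upper = upper,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best
}

## asymptotic 95% CI half-widths from the local curvature (J'J)
curvature_ci <- function(fit, n_obs) {
  p <- length(fit$par)
  df <- max(n_obs - p, 1L)
  s2 <- fit$deviance / df
  vc <- tryCatch(solve(fit$hessian) * s2,
                 error = function(e) matrix(NA_real_, p, p))
  se <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  stats::qt(0.975, df) * se
}

new_fit_result <- function(estimate, ci_half, mae, converged, at_bound,
                           deviance, n_obs, extra = list()) {
  structure(c(list(estimate = estimate, ci_half = ci_half, mae = mae,
                   converged = converged, at_bound = at_bound,
                   deviance = deviance, n_obs = n_obs), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit (", x$n_obs, " observations)\n", sep = "")
  tab <- data.frame(estimate = unname(x$estimate),
                    ci95_half = unname(x$ci_half),
                    at_bound = unname(x$at_bound))
  rownames(tab) <- names(x$estimate)
  print(tab)
  cat(sprintf("mean |residual| = %.4g; converged: %s\n", x$mae,
              x$converged))
  invisible(x)
}

at_bound_flags <- function(par, lower, upper) {
  scale <- pmax(abs(upper - lower), 1e-300)
  (par - lower) < 1e-6 * scale | (upper - par) < 1e-6 * scale
}

## ---- PK fit ----------------------------------------------------------------

#' Fit the three-compartment uptake model to intracellular timecourses
#'
#' Estimates `k_EF`, `k_FE` and `k_FB` by nonlinear least squares on pooled
#' replicate observations of the total intracellular concentration
#' `C_F + C_B` (whole-cell fluorescence does not distinguish free from bound
#' drug). `v_ratio` is held fixed: it is not jointly identifiable with
#' `k_EF` from intracellular data. A Latin-hypercube multistart (log-uniform
#' over the bounds) guards against local minima; results are deterministic
#' given `seed`.
#'
#' @param observed Data frame with columns `time_h`, `replicate` and
#'   `conc_nM` (total intracellular concentration). A `value` column is
#'   accepted as a synonym for `conc_nM`.
#' @param course The [treatment_course()] applied to the wells.
#' @param v_ratio Fixed extracellular/intracellular volume ratio.
#' @param lower,upper Named bounds for `k_EF`, `k_FE`, `k_FB`.
#' @param n_starts Number of multistart points. Default 16.
#' @param seed RNG seed for the start design.
#' @return A `fit_result` whose `estimate` holds the three rates and which
#'   carries the fitted [pk_params()] in `$params`.
#' @export
fit_pk <- function(observed, course, v_ratio = 1.5e5,
                   lower = c(k_EF = 0, k_FE = 0, k_FB = 0),
                   upper = c(k_EF = 1e-3, k_FE = 10, k_FB = 1),
                   n_starts = 16L, seed = 1L) {
  if (!("conc_nM" %in% names(observed)) && "value" %in% names(observed))
    names(observed)[names(observed) == "value"] <- "conc_nM"
  stopifnot(all(c("time_h", "conc_nM") %in% names(observed)))
  if (any(!is.finite(observed$conc_nM)))
    stop("non-finite observations", call. = FALSE)
  if (all(course$conc_nM == 0) && any(observed$conc_nM > 0))
    warning("all-zero drug schedule with nonzero observations; fit proceeds")

  tt <- sort(unique(observed$time_h))
  idx <- match(observed$time_h, tt)
  obs <- observed$conc_nM

  model_at <- function(k) {
    p <- pk_params(k[1], k[2], k[3], v_ratio)
    traj <- simulate_pk(p, course, tt)
    traj$C_F_nM + traj$C_B_nM
  }
  res_fn <- function(k) model_at(k)[idx] - obs

  ranges <- cbind(pmax(lower, c(1e-9, 1e-4, 1e-5)), upper)
  starts <- lhs_starts(n_starts, ranges, seed)
  fit <- ms_nls(res_fn, starts, lower, upper)

  est <- stats::setNames(fit$par, c("k_EF", "k_FE", "k_FB"))
  bound <- at_bound_flags(fit$par, lower, upper)
  ci <- curvature_ci(fit, length(obs))
  ci[bound] <- NA_real_                       # degenerate at a bound
  new_fit_result(
    estimate = est,
    ci_half = stats::setNames(ci, names(est)),
    mae = mean(abs(fit$fvec)),
    converged = fit$info %in% 1:4,
    at_bound = stats::setNames(bound, names(est)),
    deviance = fit$deviance, n_obs = length(obs),
    extra = list(params = pk_params(est[["k_EF"]], est[["k_FE"]],
                                    est[["k_FB"]], v_ratio)))
}

## ---- PD fit ----------------------------------------------------------------

#' Fit the logistic treatment-response model to cell counts
#'
#' Estimates `k_p`, `theta`, `k_d_a`, `k_d_b`, `r` and the initial count `N0`
#' from replicate cell-count timecourses of one treatment condition by
#' nonlinear least squares (raw-count loss by default; log-count loss
#' available for strongly heteroscedastic data). Pre-treatment samples anchor
#' the proliferation rate. The kernel weight `lam` is fixed (see
#' [pd_params()] for why it is not free). Data-driven initial guesses are
#' refined by a Latin-hypercube multistart.
#'
#' @param counts Data frame with columns `time_h`, `count` and optionally
#'   `replicate`; times may be negative (pre-treatment).
#' @param lam Fixed kernel mixing weight.
#' @param loss `"raw"` (default) or `"log"` (counts are log1p-transformed).
#' @param lower,upper Optional named bounds for
#'   `k_p, theta, k_d_a, k_d_b, r, N0`. `theta` is bounded below by the
#'   maximum observed count.
#' @param n_starts Multistart points. Default 8.
#' @param seed RNG seed for the start design.
#' @return A `fit_result` carrying the fitted [pd_params()] in `$params` and
#'   the fitted initial count in `$N0`.
#' @export
fit_pd <- function(counts, lam = 0.5, loss = c("raw", "log"),
                   lower = NULL, upper = NULL, n_starts = 8L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(all(c("time_h", "count") %in% names(counts)))
  if (any(!is.finite(counts$count)) || any(counts$count < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (all(counts$count == 0)) stop("all-zero counts", call. = FALSE)
  if (nrow(counts) < 6L)
    stop("fewer timepoints than free parameters", call. = FALSE)

  tt <- sort(unique(counts$time_h))
  idx <- match(counts$time_h, tt)
  obs <- counts$count
  cmax <- max(obs)

  ## data-driven anchors: growth rate from early points, ceiling from max
  n0_guess <- {
    near0 <- which.min(abs(tt))
    m <- mean(obs[idx == near0])
    max(m, 1)
  }
  kp_guess <- {
    pre <- counts$time_h <= 0 & counts$count > 0
    if (sum(pre) >= 2) {
      sl <- tryCatch(stats::coef(stats::lm(log(count) ~ time_h,
                                           data = counts[pre, ]))[2],
                     error = function(e) 0.02)
      min(max(as.numeric(sl), 1e-3), 0.2)
    } else 0.02
  }

  if (is.null(lower))
    lower <- c(k_p = 0, theta = cmax, k_d_a = 0, k_d_b = 0, r = 1e-3,
               N0 = max(n0_guess / 5, 1))
  if (is.null(upper))
    upper <- c(k_p = 0.3, theta = 50 * cmax, k_d_a = 0.3, k_d_b = 0.5, r = 2,
               N0 = n0_guess * 5)
  lower["theta"] <- max(lower["theta"], cmax)

  transform <- if (loss == "log") function(x) log1p(x) else identity
  yobs <- transform(obs)

  res_fn <- function(par) {
    p <- pd_params(par[1], par[2], par[3], par[4], par[5], lam = lam)
    mu <- pmax(simulate_counts(p, par[6], tt)$count, 0)
    transform(mu)[idx] - yobs
  }

  ranges <- cbind(pmax(lower, c(1e-3, cmax * 1.001, 1e-4, 1e-4, 2e-3,
                                lower[["N0"]])),
                  pmin(upper, c(0.3, 50 * cmax, 0.3, 0.5, 2, upper[["N0"]])))
  starts <- lhs_starts(n_starts, ranges, seed)
  ## prepend the data-driven guess
  guess <- c(kp_guess, max(1.1 * cmax, 1.5 * n0_guess), 0.005, 0.01, 0.05,
             n0_guess)
  starts <- rbind(pmin(pmax(guess, lower), upper), starts)

  fit <- ms_nls(res_fn, starts, lower, upper)
  nm <- c("k_p", "theta", "k_d_a", "k_d_b", "r", "N0")
  est <- stats::setNames(fit$par, nm)
  bound <- at_bound_flags(fit$par, lower, upper)
  ci <- curvature_ci(fit, length(obs))
  new_fit_result(
    estimate = est,
    ci_half = stats::setNames(ci, nm),
    mae = mean(abs(fit$fvec)),
    converged = fit$info %in% 1:4,
    at_bound = stats::setNames(bound, nm),
    deviance = fit$deviance, n_obs = length(obs),
    extra = list(params = pd_params(est[["k_p"]], est[["theta"]],
                                    est[["k_d_a"]], est[["k_d_b"]],
                                    est[["r"]], lam = lam),
                 N0 = est[["N0"]], loss = loss))
}

## ---- Hill fit --------------------------------------------------------------

#' Fit a Hill dose-survival curve
#'
#' Fits `S(D) = E_inf + (1 - E_inf) / (1 + (D / EC50)^h)` to endpoint
#' survival data, on either extracellular dose or equivalent dose. Reports
#' the `EC50` (dose at half-maximal effect) with an asymptotic 95% CI. A
#' survival profile that is flat across doses carries no dose information;
#' the fit is then flagged non-identifiable and no `EC50` is returned.
#'
#' @param dose Doses, nM (extracellular concentration or equivalent dose);
#'   at least 4 distinct positive values.
#' @param survival Relative cell count at the fixed endpoint, typically in
#'   `[0, 1.2]`.
#' @param flat_tol Survival range below which the curve is declared flat.
#' @param n_starts Multistart points.
#' @param seed RNG seed for the start design.
#' @return An object of class `hill_fit` with elements `EC50` (Hill
#'   midpoint parameter), `slope`, `E_inf`, `D50` (absolute half-response
#'   dose, where the fitted curve crosses survival 0.5; `NA` when the floor
#'   exceeds 0.5), `ci_half` (per parameter), `identifiable`, `mae`.
#' @export
hill_fit <- function(dose, survival, flat_tol = 0.05, n_starts = 8L,
                     seed = 1L) {
  keep <- is.finite(dose) & is.finite(survival) & dose > 0
  dose <- dose[keep]; survival <- survival[keep]
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct positive doses", call. = FALSE)

  if (diff(range(survival)) < flat_tol) {
    return(structure(list(EC50 = NA_real_, slope = NA_real_,
                          E_inf = NA_real_, D50 = NA_real_,
                          ci_half = c(EC50 = NA, slope = NA, E_inf = NA),
                          identifiable = FALSE, mae = NA_real_),
                     class = "hill_fit"))
  }

  lower <- c(EC50 = min(dose) / 100, slope = 0.05, E_inf = 0)
  upper <- c(EC50 = max(dose) * 100, slope = 20, E_inf = 1)
  res_fn <- function(par)
    par[3] + (1 - par[3]) / (1 + (dose / par[1])^par[2]) - survival
  ranges <- cbind(c(min(dose), 0.3, 1e-4), c(max(dose), 5, 0.5))
  starts <- lhs_starts(n_starts, ranges, seed)
  fit <- ms_nls(res_fn, starts, lower, upper)

  ci <- curvature_ci(fit, length(dose))
  ## absolute half-response dose: where the fitted curve crosses S = 0.5.
  ## Unlike the Hill midpoint parameter, this is interpolated within the
  ## data whenever the curve spans 0.5, so it is robust to the floor
  ## (E_inf) extrapolation and is the preferred statistic for comparing
  ## dose scales across cell lines.
  D50 <- if (fit$par[3] < 0.5) {
    fit$par[1] * ((1 - fit$par[3]) / (0.5 - fit$par[3]) - 1)^(1 / fit$par[2])
  } else NA_real_
  structure(list(EC50 = fit$par[1], slope = fit$par[2], E_inf = fit$par[3],
                 D50 = D50,
                 ci_half = stats::setNames(ci, c("EC50", "slope", "E_inf")),
                 identifiable = TRUE, mae = mean(abs(fit$fvec)),
                 deviance = fit$deviance),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Hill fit: non-identifiable (flat survival across doses)\n")
  } else {
    cat(sprintf("Hill fit: EC50 = %.4g nM (+/- %.3g), slope = %.3g, E_inf = %.3g\n",
                x$EC50, x$ci_half[["EC50"]], x$slope, x$E_inf))
  }
  invisible(x)
}
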