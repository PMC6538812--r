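#' Monotherapy response surface over equivalent dose
#'
#' Interpolates the treatment-response parameter vector
#' `p = [k_d_a, k_d_b, r]` as a piecewise-linear (local linear) function of
#' equivalent dose, using the monotherapy conditions as nodes. The surface is
#' the reference against which co-treatment dynamics are matched: every
#' monotherapy condition has a perfectly known equivalent dose (its own
#' simulated peak bound concentration), and any response whose parameters lie
#' on the surface is assigned the corresponding dose.
#'
#' Queries outside the node range are refused (no extrapolation). Each
#' parameter dimension stores its node range as the normalization used by
#' [estimate_equivalent_dose()]; raw scales differ by orders of magnitude,
#' so matching is done in range-scaled coordinates.
#'
#' @param fits List of [pd_params()] objects (or `fit_result`s from
#'   [fit_pd()]) for the monotherapy conditions.
#' @param doses Equivalent dose of each condition, nM; must be distinct.
#' @param monotone If `TRUE`, project the node parameters onto the
#'   qualitative dose-response shape before interpolation — death rates
#'   (`k_d_a`, `k_d_b`) non-decreasing and induction rate `r`
#'   non-increasing in dose — by isotonic regression. This is still
#'   non-parametric; it removes spurious matching branches created by fit
#'   noise at the nodes. Default `FALSE` (interpolate the fits as given).
#' @param interp Interpolation rule between nodes: `"linear"` (piecewise
#'   local-linear, the default) or `"monotone-cubic"` (Fritsch-Carlson
#'   monotone Hermite). On a geometric (2-fold) dose grid the linear chords
#'   of a saturating response run below the curve, biasing matched doses
#'   upward mid-gap; the monotone cubic removes most of that bias while
#'   still interpolating the nodes exactly and adding no parametric form.
#'   Requires `monotone = TRUE` to guarantee monotone node sequences.
#' @return An object of class `response_surface`.
#' @export
build_response_surface <- function(fits, doses, monotone = FALSE,
                                   interp = c("linear", "monotone-cubic")) {
  interp <- match.arg(interp)
  if (length(fits) != length(doses))
    stop("'fits' and 'doses' must have equal length", call. = FALSE)
  if (length(doses) < 3L) stop("need at least 3 nodes", call. = FALSE)
  if (anyDuplicated(doses)) stop("duplicate equivalent-dose nodes",
                                 call. = FALSE)
  pmat <- t(vapply(fits, function(f) {
    p <- if (inherits(f, "fit_result")) f$params else f
    stopifnot(inherits(p, "pd_params"))
    c(k_d_a = p$k_d_a, k_d_b = p$k_d_b, r = p$r)
  }, numeric(3)))
  if (any(!is.finite(pmat))) stop("non-finite parameter vectors",
                                  call. = FALSE)
  ord <- order(doses)
  doses <- as.numeric(doses[ord])
  pmat <- pmat[ord, , drop = FALSE]
  if (isTRUE(monotone)) {
    pmat[, "k_d_a"] <- stats::isoreg(doses, pmat[, "k_d_a"])$yf
    pmat[, "k_d_b"] <- stats::isoreg(doses, pmat[, "k_d_b"])$yf
    pmat[, "r"] <- -stats::isoreg(doses, -pmat[, "r"])$yf
  }
  if (interp == "monotone-cubic" && !isTRUE(monotone))
    stop("interp = 'monotone-cubic' requires monotone = TRUE", call. = FALSE)
  scale <- apply(pmat, 2, function(x) diff(range(x)))
  structure(list(doses = doses, p = pmat, scale = scale, interp = interp),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "Response surface: %d nodes, D_eq in [%.4g, %.4g] nM; dims %s\n",
    length(x$doses), min(x$doses), max(x$doses),
    paste(colnames(x$p), collapse = ", ")))
  invisible(x)
}

#' Evaluate a response surface
#'
#' Piecewise-linear interpolation of the parameter vector at equivalent dose
#' `D`. Exact at nodes; errors outside the node range.
#'
#' @param surface A `response_surface`.
#' @param D Equivalent dose(s), nM, within the node range.
#' @return Matrix with one row per query and columns `k_d_a`, `k_d_b`, `r`.
#' @export
surface_params <- function(surface, D) {
  stopifnot(inherits(surface, "response_surface"))
  if (any(D < min(surface$doses) - 1e-9 | D > max(surface$doses) + 1e-9))
    stop("query outside the surface range (no extrapolation)", call. = FALSE)
  cubic <- identical(surface$interp, "monotone-cubic")
  out <- vapply(seq_len(ncol(surface$p)), function(j) {
    y <- surface$p[, j]
    if (cubic && length(unique(y)) > 1L) {
      f <- stats::splinefun(surface$doses, y, method = "monoH.FC")
      f(D)
    } else {
      stats::approx(surface$doses, y, xout = D, rule = 1)$y
    }
  }, numeric(length(D)))
  out <- matrix(out, nrow = length(D),
                dimnames = list(NULL, colnames(surface$p)))
  out
}

#' Estimate the equivalent dose of a co-treatment condition
#'
#' Finds the equivalent dose whose monotherapy response parameters best match
#' a fitted co-treatment parameter vector in the L2 sense:
#' `D_est = argmin_D || (p_est(D) - p_fit) / s ||_2`, where `s` is the
#' per-dimension node range of the surface. The minimum is located by a
#' dense grid scan (default 512 points) followed by golden-section
#' refinement, which is robust to the kinks of a piecewise-linear surface.
#'
#' @param p_fit A [pd_params()] object, `fit_result` from [fit_pd()], or a
#'   named/ordered numeric vector `(k_d_a, k_d_b, r)`.
#' @param surface A `response_surface` from [build_response_surface()].
#' @param n_grid Grid size for the initial scan.
#' @param ambig_tol Relative tolerance used to detect distinct near-optimal
#'   local minima (ambiguous matches).
#' @param scale Optional per-dimension normalization overriding the
#'   surface's node ranges, e.g. ranges inflated by parameter-estimate
#'   uncertainty so that poorly identified dimensions are downweighted.
#' @return A list of class `match_result`: `D_est` (nM), `residual`
#'   (normalized L2 distance at the optimum), `boundary` (logical), and
#'   `ambiguous` (logical).
#' @export
estimate_equivalent_dose <- function(p_fit, surface, n_grid = 512L,
                                     ambig_tol = 0.05, scale = NULL) {
  stopifnot(inherits(surface, "response_surface"))
  pvec <- if (inherits(p_fit, "fit_result")) p_fit$params else p_fit
  if (inherits(pvec, "pd_params"))
    pvec <- c(pvec$k_d_a, pvec$k_d_b, pvec$r)
  pvec <- as.numeric(pvec)
  if (length(pvec) != 3L || any(!is.finite(pvec)))
    stop("'p_fit' must supply finite (k_d_a, k_d_b, r)", call. = FALSE)

  s <- if (is.null(scale)) surface$scale else as.numeric(scale)
  if (all(s <= 0)) {
    return(structure(list(D_est = NA_real_, residual = NA_real_,
                          boundary = FALSE, ambiguous = TRUE,
                          degenerate = TRUE), class = "match_result"))
  }
  s[s <= 0] <- 1  # constant dimension carries no information

  dist_at <- function(D) {
    pe <- surface_params(surface, D)
    sqrt(colSums(((t(pe) - pvec) / s)^2))
  }

  lo <- min(surface$doses); hi <- max(surface$doses)
  grid <- seq(lo, hi, length.out = n_grid)
  dv <- dist_at(grid)
  i0 <- which.min(dv)

  ## golden-section refinement within the bracketing grid cells
  a <- grid[max(i0 - 1L, 1L)]; b <- grid[min(i0 + 1L, n_grid)]
  opt <- stats::optimize(function(D) dist_at(D), lower = a, upper = b,
                         tol = 1e-10 * (hi - lo) + 1e-12)
  D_est <- opt$minimum
  resid <- opt$objective
  ## snap to an exactly matching node (zero distance at nodes is exact)
  node_d <- dist_at(surface$doses)
  if (min(node_d) <= resid + 1e-12) {
    j <- which.min(node_d)
    if (node_d[j] < resid || abs(surface$doses[j] - D_est) < 1e-8 * (hi - lo)) {
      D_est <- surface$doses[j]; resid <- node_d[j]
    }
  }

  ## ambiguity: another local minimum of the grid scan nearly as good but far
  locmin <- which(diff(sign(diff(dv))) > 0) + 1L
  locmin <- union(locmin, c(1L, n_grid)[c(dv[1] < dv[2], dv[n_grid] < dv[n_grid - 1L])])
  spread <- max(dv) - min(dv)
  near <- locmin[dv[locmin] <= resid + ambig_tol * max(spread, 1e-300)]
  ambiguous <- length(near) > 1L &&
    (max(grid[near]) - min(grid[near])) > 0.05 * (hi - lo)

  boundary <- (D_est - lo) < 1e-3 * (hi - lo) || (hi - D_est) < 1e-3 * (hi - lo)
  structure(list(D_est = D_est, residual = resid, boundary = boundary,
                 ambiguous = ambiguous, degenerate = FALSE),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Match: degenerate surface (parameters constant in dose); no D_est\n")
  } else {
    cat(sprintf("Match: D_est = %.5g nM (residual %.4g%s%s)\n", x$D_est,
                x$residual, if (x$boundary) ", at boundary" else "",
                if (x$ambiguous) ", AMBIGUOUS" else ""))
  }
  invisible(x)
}

#' Estimate a sensitizer-modulated rate constant per sensitizer level
#'
#' Solves the constrained inverse problem for the rate constant `k_x`
#' (either `k_FE` or `k_FB`) at each of `n` sensitizer concentrations, given
#' matched equivalent-dose estimates `D_est` for `m` co-treatment conditions:
#' \deqn{G(k_x) = \min \sum_i (D_{est,i} - D_i(k_x))^2 \quad
#'   \text{s.t. } \tilde k_{x,q+1} - \tilde k_{x,q} \ge 0}
#' where `D_i(k_x)` is the model equivalent dose of condition `i`'s course
#' with the target rate set to its level's value, and all other PK rates are
#' fixed to the monotherapy values (each sensitizer is assumed to act on a
#' single rate). The monotone constraint is imposed exactly by optimizing
#' non-negative increments of the transformed rate
#' `k~ = k_x` (direction `"increasing"`, e.g. a DNA-repair inhibitor raising
#' `k_FB`) or `k~ = 1/k_x` (direction `"decreasing"`, e.g. an efflux-pump
#' inhibitor lowering `k_FE`).
#'
#' Starting values come from per-level scalar root solves of
#' `D(k_x) = mean(D_est)` (the model dose is monotone in either rate),
#' isotonized, then polished jointly.
#'
#' @param D_est Numeric vector of estimated equivalent doses (nM), one per
#'   co-treatment condition.
#' @param levels Integer vector (same length) mapping each condition to its
#'   sensitizer level `1..n`, ordered by increasing sensitizer concentration.
#' @param courses List of [treatment_course()] objects, one per condition.
#' @param params Monotherapy [pk_params()]; non-target rates are fixed to
#'   these values, and the monotherapy target rate seeds the search.
#' @param target `"k_FE"` or `"k_FB"`.
#' @param direction `"increasing"` or `"decreasing"` expected trend of the
#'   target rate with sensitizer concentration. Defaults to `"decreasing"`
#'   for `k_FE` and `"increasing"` for `k_FB`.
#' @param kx_bounds Positive search interval for each level's rate.
#' @param ... Passed to [equivalent_dose()] (e.g. `n_grid`).
#' @return An object of class `sensitizer_effect`: per-level `k_x` (natural
#'   scale), objective value `G`, `direction`, and a `large_residual` flag
#'   when some `D_est` cannot be attained by any admissible rate.
#' @export
estimate_kx <- function(D_est, levels, courses, params,
                        target = c("k_FE", "k_FB"),
                        direction = NULL,
                        kx_bounds = c(1e-6, 10), ...) {
  target <- match.arg(target)
  if (is.null(direction))
    direction <- if (target == "k_FE") "decreasing" else "increasing"
  direction <- match.arg(direction, c("increasing", "decreasing"))
  stopifnot(inherits(params, "pk_params"))
  m <- length(D_est)
  if (length(levels) != m || length(courses) != m)
    stop("'D_est', 'levels' and 'courses' must have one entry per condition",
         call. = FALSE)
  levels <- as.integer(levels)
  n <- max(levels)
  if (!all(seq_len(n) %in% levels))
    stop("every sensitizer level must have at least one condition",
         call. = FALSE)

  D_model <- function(kx, i) {
    p <- params
    p[[target]] <- kx
    as.numeric(equivalent_dose(p, courses[[i]], ...))
  }

  ## per-level scalar seed: solve D(kx) = median(D_est at level) by root
  ## finding (median resists stray matches)
  seed_kx <- vapply(seq_len(n), function(q) {
    idx <- which(levels == q)
    dbar <- stats::median(D_est[idx])
    i <- idx[1]
    f <- function(k) D_model(k, i) - dbar
    flo <- f(kx_bounds[1]); fhi <- f(kx_bounds[2])
    if (flo * fhi > 0) {
      ## target dose unreachable within bounds: clamp to the better end
      if (abs(flo) < abs(fhi)) kx_bounds[1] else kx_bounds[2]
    } else {
      stats::uniroot(f, kx_bounds, tol = 1e-12)$root
    }
  }, numeric(1))

  ## transform, isotonize the seed, express as base + increments
  tr <- function(k) if (direction == "increasing") k else 1 / k
  inv <- function(z) if (direction == "increasing") z else 1 / z
  z_seed <- cummax(tr(seed_kx))
  par0 <- c(z_seed[1], pmax(diff(z_seed), 0))

  z_bounds <- sort(tr(kx_bounds))
  lower <- c(z_bounds[1], rep(0, n - 1))
  upper <- c(z_bounds[2], rep(z_bounds[2] - z_bounds[1], n - 1))

  res_fn <- function(par) {
    z <- cumsum(par)
    z <- pmin(z, z_bounds[2])
    kx <- inv(z)
    vapply(seq_len(m), function(i) D_est[i] - D_model(kx[levels[i]], i),
           numeric(1))
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(par0, lower), upper), fn = res_fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance)) {
    par_best <- par0
    G <- sum(res_fn(par0)^2)
  } else {
    ## never worse than the seed
    if (sum(res_fn(par0)^2) < fit$deviance) {
      par_best <- par0; G <- sum(res_fn(par0)^2)
    } else {
      par_best <- fit$par; G <- fit$deviance
    }
  }
  z <- pmin(cumsum(par_best), z_bounds[2])
  kx <- inv(z)

  ## residual scale check: flag conditions whose D_est is unattainable
  resid <- res_fn(par_best)
  large <- any(abs(resid) > 0.2 * pmax(abs(D_est), 1e-300))
  structure(list(k_x = kx, target = target, direction = direction,
                 G = G, residuals = resid, large_residual = large),
            class = "sensitizer_effect")
}

#' @export
print.sensitizer_effect <- function(x, ...) {
  cat(sprintf("Sensitizer effect on %s (%s): G = %.4g%s\n", x$target,
              x$direction, x$G,
              if (x$large_residual) " [large residual]" else ""))
  cat("  per-level rates (1/h):", paste(signif(x$k_x, 4), collapse = ", "),
      "\n")
  invisible(x)
}
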