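#' Study design for synthetic datasets
#'
#' Collects the experimental-design constants shared by the synthetic-data
#' generators: a 2-fold dilution doxorubicin dose grid (5000 down to ~10
#' nM), three mid-range doxorubicin doses for co-treatment, seven 2-fold
#' sensitizer levels, a 24 h drug exposure removed by media replacement,
#' 20-25 min uptake sampling over 24 h (1 uM applied at 0, washed out at
#' 8 h), daily response imaging for 15 days with 3 days of pre-treatment
#' anchoring, six replicates per condition, additive Gaussian uptake noise
#' (sigma in nM) and multiplicative lognormal count noise (CV).
#'
#' @param dox_nM Monotherapy doxorubicin dose grid, nM.
#' @param co_dox_nM Doxorubicin doses used in co-treatment conditions, nM.
#' @param sensitizer_nM Sensitizer concentrations, increasing, nM.
#' @param exposure_h Drug exposure duration for response studies, h.
#' @param uptake_conc_nM,uptake_washout_h,uptake_horizon_h Uptake assay
#'   course: concentration applied at `t = 0`, washout time, observation end.
#' @param uptake_dt_min Uptake sampling interval, minutes.
#' @param response_times_h Response sampling times, h (negative =
#'   pre-treatment).
#' @param replicates Wells per condition.
#' @param sigma_nM Additive uptake noise SD, nM.
#' @param cv Multiplicative count noise coefficient of variation.
#' @param N0 Mean cell count at treatment time.
#' @param seed Base RNG seed; a fixed seed makes every generator output
#'   reproducible.
#' @return A list of class `study_design`.
#' @export
study_design <- function(dox_nM = 5000 / 2^(0:9),
                         co_dox_nM = c(625, 156.25, 39.0625),
                         sensitizer_nM = 250 / 2^(6:0),
                         exposure_h = 24,
                         uptake_conc_nM = 1000, uptake_washout_h = 8,
                         uptake_horizon_h = 24, uptake_dt_min = 25,
                         response_times_h = seq(-72, 360, by = 24),
                         replicates = 6L, sigma_nM = 50, cv = 0.05,
                         N0 = 2000, seed = 1L) {
  stopifnot(all(dox_nM > 0), !anyDuplicated(dox_nM), replicates >= 1L,
            all(diff(sensitizer_nM) > 0), sigma_nM >= 0, cv >= 0)
  structure(list(dox_nM = dox_nM, co_dox_nM = co_dox_nM,
                 sensitizer_nM = sensitizer_nM, exposure_h = exposure_h,
                 uptake_conc_nM = uptake_conc_nM,
                 uptake_washout_h = uptake_washout_h,
                 uptake_horizon_h = uptake_horizon_h,
                 uptake_dt_min = uptake_dt_min,
                 response_times_h = response_times_h,
                 replicates = as.integer(replicates),
                 sigma_nM = sigma_nM, cv = cv, N0 = N0,
                 seed = as.integer(seed)),
            class = "study_design")
}

uptake_course <- function(design) {
  treatment_course(c(0, design$uptake_washout_h),
                   c(design$uptake_conc_nM, 0),
                   horizon_h = design$uptake_horizon_h)
}

uptake_times <- function(design) {
  seq(0, design$uptake_horizon_h, by = design$uptake_dt_min / 60)
}

exposure_course <- function(design, dox_nM) {
  treatment_course(c(0, design$exposure_h), c(dox_nM, 0),
                   horizon_h = design$exposure_h + 1e-9)
}

#' Generate a synthetic drug-uptake dataset
#'
#' Replicate intracellular concentration timecourses: means are `C_F + C_B`
#' from [simulate_pk()] under the design's uptake course, with additive
#' Gaussian noise of SD `design$sigma_nM`. The generating truth travels with
#' the data.
#'
#' @param true_params True [pk_params()].
#' @param design A [study_design()].
#' @param course Treatment course; defaults to the design's uptake course.
#' @param seed RNG seed; defaults to `design$seed`.
#' @return List with `data` (data frame `time_h`, `replicate`, `conc_nM`)
#'   and `truth` (`params`, `course`, `sigma_nM`).
#' @export
gen_pk_dataset <- function(true_params, design, course = NULL, seed = NULL) {
  stopifnot(inherits(true_params, "pk_params"), inherits(design, "study_design"))
  if (is.null(course)) course <- uptake_course(design)
  if (is.null(seed)) seed <- design$seed
  tt <- uptake_times(design)
  tt <- tt[tt <= course$horizon_h]
  traj <- simulate_pk(true_params, course, tt)
  mu <- traj$C_F_nM + traj$C_B_nM
  nrep <- design$replicates
  data <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(nrep), function(r)
      data.frame(time_h = tt, replicate = r,
                 conc_nM = mu + stats::rnorm(length(mu), 0, design$sigma_nM))))
  })
  list(data = data,
       truth = list(params = true_params, course = course,
                    sigma_nM = design$sigma_nM, mean = mu))
}

#' Smooth default map from equivalent dose to response parameters
#'
#' Factory for the ground-truth pharmacodynamic map `p(D_eq)` used by the
#' response generators: death rates rise along saturating (Michaelis-type)
#' curves of equivalent dose and the induction rate falls, emulating the
#' qualitative shapes seen in monotherapy fits (fast shallow response at low
#' dose, slow deep response at high dose). The exact functional forms are a
#' modeling choice of this package, not a measured relationship.
#'
#' @param k_p Proliferation rate, 1/h.
#' @param theta Carrying capacity, cells.
#' @param lam Kernel mixing weight.
#' @param kd_a_max,h_a Plateau and half-saturation (nM `D_eq`) of the stable
#'   death rate. Half-saturations are calibrated to the reference line's
#'   equivalent-dose range (roughly 7-3500 nM over the monotherapy grid).
#' @param kd_b_max,h_b Plateau and half-saturation of the transient death
#'   rate.
#' @param r_lo,r_hi,h_r Induction-rate limits (high at zero dose, low at
#'   high dose) and half-saturation.
#' @return A function `D_eq -> pd_params`.
#' @export
default_pd_map <- function(k_p = 0.0212, theta = 2e4, lam = 0.5,
                           kd_a_max = 0.06, h_a = 600,
                           kd_b_max = 0.05, h_b = 900,
                           r_lo = 0.02, r_hi = 0.08, h_r = 750) {
  force(list(k_p, theta, lam, kd_a_max, h_a, kd_b_max, h_b, r_lo, r_hi, h_r))
  function(D_eq) {
    pd_params(k_p = k_p, theta = theta,
              k_d_a = kd_a_max * D_eq / (D_eq + h_a),
              k_d_b = kd_b_max * D_eq / (D_eq + h_b),
              r = r_lo + (r_hi - r_lo) * h_r / (h_r + D_eq),
              lam = lam)
  }
}

#' Hill-type ground-truth sensitizer effect on a PK rate
#'
#' Factory for the true `k_x(s)` curve of a sensitizer: saturating
#' (Hill-type) inhibition of the efflux rate `k_FE` (mirroring an MDR1
#' inhibitor, 0.313 down to 0.046 1/h over the level range) or activation of
#' the net binding rate `k_FB` (mirroring a DNA-repair inhibitor raising the
#' functional bound fraction).
#'
#' @param target `"k_FE"` (decreasing) or `"k_FB"` (increasing).
#' @param base Rate at zero sensitizer, 1/h.
#' @param span For `k_FE`: floor rate at saturating sensitizer; for
#'   `k_FB`: fold-increase amplitude at saturation.
#' @param K Half-effect sensitizer concentration, nM.
#' @param h Hill coefficient.
#' @return A monotone function `s -> k_x` (s in nM).
#' @export
default_kx_curve <- function(target = c("k_FE", "k_FB"), base = NULL,
                             span = NULL, K = 30, h = 1.5) {
  target <- match.arg(target)
  if (target == "k_FE") {
    if (is.null(base)) base <- 0.313
    if (is.null(span)) span <- 0.046
    function(s) span + (base - span) / (1 + (s / K)^h)
  } else {
    if (is.null(base)) base <- 0.0212
    if (is.null(span)) span <- 3        # up to (1 + span)-fold
    function(s) base * (1 + span * (s / K)^h / (1 + (s / K)^h))
  }
}

#' Generate synthetic treatment-response datasets
#'
#' For each condition, means come from [simulate_counts()] under the true
#' pharmacodynamic parameters; replicate counts get mean-preserving
#' multiplicative lognormal noise with the design's CV. Samples after the
#' time at which the mean first reaches `0.95 * theta` are dropped,
#' emulating the truncation of count data at confluence, where nuclei
#' overlap and counting degrades.
#'
#' @param pd_list Named list of [pd_params()], one per condition.
#' @param design A [study_design()].
#' @param seed RNG seed; defaults to `design$seed`.
#' @return List with `data` (data frame `condition`, `time_h`, `replicate`,
#'   `count`) and `truth` (the `pd_list` and noise settings).
#' @export
gen_pd_dataset <- function(pd_list, design, seed = NULL) {
  stopifnot(inherits(design, "study_design"), length(pd_list) >= 1L)
  if (is.null(seed)) seed <- design$seed
  if (is.null(names(pd_list)))
    names(pd_list) <- paste0("cond", seq_along(pd_list))
  tt <- design$response_times_h
  sdlog <- sqrt(log(1 + design$cv^2))
  nrep <- design$replicates
  data <- with_local_seed(seed, {
    do.call(rbind, lapply(names(pd_list), function(nm) {
      p <- pd_list[[nm]]
      mu <- simulate_counts(p, design$N0, tt)$count
      keep <- rep(TRUE, length(tt))
      hit <- which(mu >= 0.95 * p$theta)
      if (length(hit)) keep[tt > tt[hit[1]]] <- FALSE
      do.call(rbind, lapply(seq_len(nrep), function(rr) {
        eps <- stats::rnorm(sum(keep), 0, sdlog)
        data.frame(condition = nm, time_h = tt[keep], replicate = rr,
                   count = mu[keep] * exp(eps - sdlog^2 / 2))
      }))
    }))
  })
  list(data = data,
       truth = list(pd = pd_list, cv = design$cv, N0 = design$N0))
}

#' Generate a full synthetic sensitizer study
#'
#' Emulates the complete experimental design around one cell line and one
#' sensitizer: (a) an uptake dataset under the base PK parameters, (b)
#' monotherapy response data at every dose of the design grid plus an
#' untreated control, generated from `pd_map` evaluated at each condition's
#' true equivalent dose, and (c) co-treatment response data for each
#' (sensitizer level x co-treatment dose) pair, where the target rate is set
#' to the true `kx_curve` value for that level before computing the
#' condition's equivalent dose. The returned truth bundle carries every
#' per-level rate and per-condition equivalent dose, so the full inverse
#' pipeline can be validated end to end.
#'
#' @param base_params Monotherapy [pk_params()].
#' @param design A [study_design()].
#' @param target `"k_FE"` or `"k_FB"` (which rate the sensitizer modulates).
#' @param kx_curve Monotone function sensitizer-nM -> rate; defaults to
#'   [default_kx_curve()] for the target.
#' @param pd_map Function `D_eq -> pd_params`; defaults to
#'   [default_pd_map()].
#' @param seed RNG seed; defaults to `design$seed`.
#' @return List with `uptake` (as [gen_pk_dataset()]), `response` (pooled
#'   data frame over all conditions), `conditions` (data frame: `condition`,
#'   `type`, `dox_nM`, `sens_level`, `sens_nM`, `true_D_eq`), and `truth`
#'   (`kx` per level, `base_params`, `pd_map`).
#' @export
gen_sensitizer_study <- function(base_params, design,
                                 target = c("k_FB", "k_FE"),
                                 kx_curve = NULL, pd_map = NULL,
                                 seed = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(base_params, "pk_params"), inherits(design, "study_design"))
  if (is.null(kx_curve)) kx_curve <- default_kx_curve(target)
  if (is.null(pd_map)) pd_map <- default_pd_map()
  if (is.null(seed)) seed <- design$seed

  s_levels <- design$sensitizer_nM
  kx_true <- vapply(s_levels, kx_curve, numeric(1))
  dk <- diff(kx_true)
  if (!(all(dk >= -1e-12) || all(dk <= 1e-12)))
    stop("'kx_curve' must be monotone across the sensitizer levels",
         call. = FALSE)

  uptake <- gen_pk_dataset(base_params, design, seed = seed)

  ## condition table: monotherapy (incl. control) + co-treatments
  cond <- data.frame(condition = "control", type = "control", dox_nM = 0,
                     sens_level = 0L, sens_nM = 0)
  for (d in design$dox_nM)
    cond <- rbind(cond, data.frame(condition = sprintf("mono_%g", d),
                                   type = "mono", dox_nM = d,
                                   sens_level = 0L, sens_nM = 0))
  for (q in seq_along(s_levels)) for (d in design$co_dox_nM)
    cond <- rbind(cond, data.frame(
      condition = sprintf("co_L%d_%g", q, d), type = "co", dox_nM = d,
      sens_level = q, sens_nM = s_levels[q]))

  cond$true_D_eq <- vapply(seq_len(nrow(cond)), function(i) {
    if (cond$dox_nM[i] == 0) return(0)
    p <- base_params
    if (cond$type[i] == "co") p[[target]] <- kx_true[cond$sens_level[i]]
    as.numeric(equivalent_dose(p, exposure_course(design, cond$dox_nM[i])))
  }, numeric(1))

  pd_list <- lapply(cond$true_D_eq, pd_map)
  names(pd_list) <- cond$condition
  response <- gen_pd_dataset(pd_list, design, seed = seed + 1L)

  list(uptake = uptake, response = response$data, conditions = cond,
       truth = list(kx = kx_true, sensitizer_nM = s_levels, target = target,
                    base_params = base_params, pd = pd_list,
                    pd_map = pd_map))
}

#' Generate a synthetic spectral image stack
#'
#' Forward-synthesizes one timepoint of multi-channel fluorescence imaging:
#' `I_j = L * (sum_f S_f T[f, j]) + noise`, where `S_f` are the true
#' per-fluorophore maps (background included as a fluorophore), `T` the
#' mixing matrix and `L` the illumination field.
#'
#' @param S_maps Named list of fluorophore maps (matrices, same shape),
#'   order matching the rows of `T_mix`.
#' @param T_mix Mixing matrix (fluorophores x channels).
#' @param L Illumination field matrix (same shape as the maps).
#' @param sigma Additive Gaussian noise SD (0 = noiseless). Interpreted as
#'   a fraction of each pixel's clean intensity when `relative = TRUE`.
#' @param relative Whether `sigma` is relative. Default `FALSE`.
#' @param seed RNG seed.
#' @return List with `stack` (list of channel images) and `truth`
#'   (`S_maps`, `T_mix`, `L`).
#' @export
gen_spectral_stack <- function(S_maps, T_mix, L, sigma = 0,
                               relative = FALSE, seed = 1L) {
  stopifnot(is.list(S_maps), length(S_maps) == nrow(T_mix))
  dims <- dim(S_maps[[1]])
  stopifnot(identical(dim(L), dims))
  stack <- with_local_seed(seed, {
    lapply(seq_len(ncol(T_mix)), function(j) {
      clean <- Reduce(`+`, Map(function(S, w) S * w, S_maps,
                               unclass(T_mix)[, j]))
      img <- L * clean
      if (sigma > 0) {
        sd_px <- if (relative) sigma * abs(img) else sigma
        img <- img + stats::rnorm(length(img), 0, sd_px)
      }
      matrix(img, dims[1], dims[2])
    })
  })
  names(stack) <- colnames(T_mix)
  list(stack = stack, truth = list(S_maps = S_maps, T_mix = T_mix, L = L))
}
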