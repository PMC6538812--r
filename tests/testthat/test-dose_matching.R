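make_surface <- function(doses = c(0, 10, 40, 120, 240)) {
  map <- default_pd_map()
  build_response_surface(lapply(doses, map), doses)
}

test_that("the surface interpolates exactly at nodes and linearly between", {
  doses <- c(0, 10, 40, 120, 240)
  map <- default_pd_map()
  surf <- make_surface(doses)
  for (d in doses) {
    p <- map(d)
    expect_equal(as.numeric(surface_params(surf, d)),
                 c(p$k_d_a, p$k_d_b, p$r), tolerance = 1e-12)
  }
  # globally linear parameter map is reproduced everywhere
  lin_fits <- lapply(doses, function(d)
    pd_params(0.02, 2e4, k_d_a = 1e-4 * d, k_d_b = 2e-4 * d,
              r = 0.1 - 2e-4 * d))
  lin_surf <- build_response_surface(lin_fits, doses)
  for (d in c(5, 33.3, 77, 201)) {
    expect_equal(as.numeric(surface_params(lin_surf, d)),
                 c(1e-4 * d, 2e-4 * d, 0.1 - 2e-4 * d), tolerance = 1e-12)
  }
})

test_that("surface construction and queries enforce their contracts", {
  doses <- c(0, 10, 40)
  map <- default_pd_map()
  expect_error(build_response_surface(lapply(doses[1:2], map), doses[1:2]),
               "at least 3")
  expect_error(build_response_surface(lapply(c(0, 10, 10), map),
                                      c(0, 10, 10)), "duplicate")
  surf <- make_surface()
  expect_error(surface_params(surf, 500), "no extrapolation")
  expect_error(surface_params(surf, -1), "no extrapolation")
})

test_that("matching a node's own parameters returns that node's dose exactly", {
  doses <- c(0, 10, 40, 120, 240)
  surf <- make_surface(doses)
  map <- default_pd_map()
  for (d in doses) {
    m <- estimate_equivalent_dose(map(d), surf)
    expect_equal(m$D_est, d, tolerance = 1e-9)
    expect_lt(m$residual, 1e-10)
  }
  # between nodes: matching the map's own curve lands within interpolation
  # error of a refined surface
  fine <- build_response_surface(lapply(seq(0, 240, by = 5), map),
                                 seq(0, 240, by = 5))
  for (d in c(17, 66, 180)) {
    m <- estimate_equivalent_dose(map(d), fine)
    expect_lt(abs(m$D_est - d) / d, 0.01)
  }
})

test_that("a parameter-constant surface is flagged, not matched", {
  p <- pd_params(0.02, 2e4, k_d_a = 0.01, k_d_b = 0.02, r = 0.05)
  surf <- build_response_surface(list(p, p, p), c(0, 10, 40))
  m <- estimate_equivalent_dose(c(0.005, 0.01, 0.06), surf)
  expect_true(m$ambiguous)
  expect_true(is.na(m$D_est))
})

test_that("a zero-effect sensitizer returns the monotherapy rate", {
  des <- study_design()
  crs <- exposure_course(des, 625)
  base <- ref_pk()
  d_mono <- as.numeric(equivalent_dose(base, crs))
  eff <- estimate_kx(D_est = d_mono, levels = 1L, courses = list(crs),
                     params = base, target = "k_FB")
  expect_lt(rel_err(eff$k_x, base$k_FB), 1e-4)
  expect_false(eff$large_residual)
})

test_that("single-level estimates match a bisection oracle", {
  des <- study_design()
  crs <- exposure_course(des, 156.25)
  base <- ref_pk()
  for (kx_true in c(0.01, 0.05, 0.12)) {
    p <- base; p$k_FB <- kx_true
    d_target <- as.numeric(equivalent_dose(p, crs))
    # independent bisection on the model dose
    f <- function(k) {
      q <- base; q$k_FB <- k
      as.numeric(equivalent_dose(q, crs)) - d_target
    }
    lo <- 1e-6; hi <- 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    oracle <- (lo + hi) / 2
    eff <- estimate_kx(D_est = d_target, levels = 1L, courses = list(crs),
                       params = base, target = "k_FB")
    expect_lt(rel_err(eff$k_x, oracle), 1e-5)
  }
})

test_that("the monotone constraint holds exactly and G never beats the null", {
  des <- study_design()
  base <- ref_pk()
  kx_curve <- default_kx_curve("k_FB")
  lv <- rep(1:4, each = 2)
  doses <- rep(c(625, 156.25), 4)
  courses <- lapply(doses, exposure_course, design = des)
  kx_true <- kx_curve(c(10, 30, 90, 250))
  d_true <- vapply(seq_along(lv), function(i) {
    p <- base; p$k_FB <- kx_true[lv[i]]
    as.numeric(equivalent_dose(p, courses[[i]]))
  }, numeric(1))
  # perturb the matched doses, then require exact monotonicity anyway
  d_noisy <- d_true * c(1.1, 0.95, 0.9, 1.2, 1.05, 0.85, 1.15, 0.9)
  eff <- estimate_kx(D_est = d_noisy, levels = lv, courses = courses,
                     params = base, target = "k_FB")
  expect_true(all(diff(eff$k_x) >= -1e-12))
  # objective at solution <= objective with monotherapy rates at all levels
  null_resid <- vapply(seq_along(lv), function(i)
    d_noisy[i] - as.numeric(equivalent_dose(base, courses[[i]])),
    numeric(1))
  expect_lte(eff$G, sum(null_resid^2) + 1e-9)
  # and the recovered rates are close to the generating ones
  expect_lt(median(rel_err(eff$k_x, kx_true)), 0.2)
})

test_that("a decreasing target optimizes the reciprocal and stays monotone", {
  des <- study_design()
  base <- ref_pk()
  lv <- 1:4
  courses <- lapply(rep(625, 4), exposure_course, design = des)
  kx_true <- c(0.3, 0.2, 0.1, 0.05)      # efflux falls with sensitizer
  d_true <- vapply(1:4, function(i) {
    p <- base; p$k_FE <- kx_true[i]
    as.numeric(equivalent_dose(p, courses[[i]]))
  }, numeric(1))
  eff <- estimate_kx(D_est = d_true, levels = lv, courses = courses,
                     params = base, target = "k_FE")
  expect_equal(eff$direction, "decreasing")
  expect_true(all(diff(eff$k_x) <= 1e-12))
  expect_lt(max(rel_err(eff$k_x, kx_true)), 1e-3)
})
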