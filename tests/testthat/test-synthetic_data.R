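test_that("uptake generator is exact at zero noise and seed-deterministic", {
  des <- study_design(sigma_nM = 0, replicates = 2L)
  gen <- gen_pk_dataset(ref_pk(), des)
  one_rep <- gen$data[gen$data$replicate == 1, ]
  expect_equal(one_rep$conc_nM, gen$truth$mean)

  des2 <- study_design(sigma_nM = 50)
  a <- gen_pk_dataset(ref_pk(), des2, seed = 5)
  b <- gen_pk_dataset(ref_pk(), des2, seed = 5)
  c <- gen_pk_dataset(ref_pk(), des2, seed = 6)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("uptake noise has the designed scale", {
  des <- study_design(sigma_nM = 50, replicates = 1000L,
                      uptake_dt_min = 300)  # few timepoints, many wells
  gen <- gen_pk_dataset(ref_pk(), des, seed = 3)
  sds <- tapply(gen$data$conc_nM, gen$data$time_h, stats::sd)
  expect_true(all(abs(sds - 50) / 50 < 0.05))
})

test_that("count generator reproduces model means and truncates at confluence", {
  p_grow <- pd_params(0.03, 1e4, lam = 0.5)      # reaches the ceiling
  p_kill <- pd_params(0.02, 2e4, k_d_a = 0.04, k_d_b = 0.04, r = 0.05)
  des <- study_design(cv = 0, replicates = 1L, N0 = 2000)
  gen <- gen_pd_dataset(list(grow = p_grow, kill = p_kill), des)
  grow <- gen$data[gen$data$condition == "grow", ]
  mu <- simulate_counts(p_grow, 2000, grow$time_h)$count
  expect_equal(grow$count, mu)
  # truncation: no samples after the mean first reaches 0.95 * theta
  full_mu <- simulate_counts(p_grow, 2000, des$response_times_h)$count
  t_hit <- des$response_times_h[which(full_mu >= 0.95 * 1e4)[1]]
  expect_lte(max(grow$time_h), t_hit)
  expect_true(any(des$response_times_h > t_hit))  # something was dropped
  # the untruncated condition keeps the full grid
  kill <- gen$data[gen$data$condition == "kill", ]
  expect_equal(sort(unique(kill$time_h)), des$response_times_h)
})

test_that("count noise has the designed coefficient of variation", {
  p <- pd_params(0.02, 2e4, k_d_a = 0.005, k_d_b = 0.01, r = 0.05)
  des <- study_design(cv = 0.05, replicates = 1000L,
                      response_times_h = c(0, 120, 240))
  gen <- gen_pd_dataset(list(c = p), des, seed = 8)
  cvs <- tapply(gen$data$count, gen$data$time_h,
                function(x) stats::sd(x) / mean(x))
  expect_true(all(abs(cvs - 0.05) / 0.05 < 0.10))
})

test_that("sensitizer study carries a consistent truth bundle", {
  des <- study_design()
  st <- gen_sensitizer_study(ref_pk(), des, target = "k_FB", seed = 2)
  cond <- st$conditions
  expect_equal(nrow(cond), 1 + 10 + 7 * 3)
  expect_true(all(diff(st$truth$kx) >= 0))
  # monotherapy equivalent doses double with the 2-fold dose series
  mono <- cond[cond$type == "mono", ]
  mono <- mono[order(mono$dox_nM), ]
  expect_equal(mono$true_D_eq[-1] / mono$true_D_eq[-nrow(mono)],
               rep(2, nrow(mono) - 1), tolerance = 1e-3)
  # zero-effect sensitizer makes co-treatment doses equal monotherapy doses
  flat <- gen_sensitizer_study(ref_pk(), des, target = "k_FB",
                               kx_curve = function(s) 0.0212, seed = 2)
  fc <- flat$conditions
  for (i in which(fc$type == "co")) {
    mono_i <- which(fc$type == "mono" & fc$dox_nM == fc$dox_nM[i])
    expect_equal(fc$true_D_eq[i], fc$true_D_eq[mono_i], tolerance = 1e-12)
  }
  # non-monotone curves are rejected
  expect_error(
    gen_sensitizer_study(ref_pk(), des, target = "k_FB",
                         kx_curve = function(s) 0.02 + sin(s)^2, seed = 2),
    "monotone")
})

test_that("sensitizer study generation is seed-deterministic end to end", {
  des <- study_design()
  a <- gen_sensitizer_study(ref_pk(), des, target = "k_FE", seed = 4)
  b <- gen_sensitizer_study(ref_pk(), des, target = "k_FE", seed = 4)
  expect_identical(a$uptake$data, b$uptake$data)
  expect_identical(a$response, b$response)
  expect_identical(a$conditions, b$conditions)
})

test_that("spectral stack generator is the exact forward model at zero noise", {
  Tm <- build_mixing_matrix(list(a = c(1, 0, 0, 0, 0),
                                 b = c(0, 1, 0, 0, 0),
                                 c = c(0, 0, 1, 0, 0),
                                 d = c(0, 0, 0, 1, 0)))
  S <- list(a = matrix(2, 8, 9), b = matrix(3, 8, 9),
            c = matrix(4, 8, 9), d = matrix(5, 8, 9))
  ones <- matrix(1, 8, 9)
  gen <- gen_spectral_stack(S, Tm, ones, sigma = 0)
  # identity-padded T: channel j equals fluorophore j's map; channel 5 empty
  for (j in 1:4) expect_equal(gen$stack[[j]], S[[j]])
  expect_equal(gen$stack[[5]], matrix(0, 8, 9))
  # determinism under noise
  g1 <- gen_spectral_stack(S, Tm, ones, sigma = 0.1, seed = 12)
  g2 <- gen_spectral_stack(S, Tm, ones, sigma = 0.1, seed = 12)
  expect_identical(g1$stack, g2$stack)
})
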