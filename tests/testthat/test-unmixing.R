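# small synthetic imaging fixtures, built in code
quad_field <- function(nr = 40, nc = 50, dip = 0.15) {
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  L <- outer(seq_len(nr) - 1, seq_len(nc) - 1, function(y, x)
    1 - dip * (((x - cx) / cx)^2 + ((y - cy) / cy)^2) / 2)
  L / max(L)
}

# sparse bright discs on a flat background
cells_image <- function(nr = 40, nc = 50, centers, radius = 2, value = 60) {
  img <- matrix(0, nr, nc)
  for (ct in centers) {
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if ((r - ct[1])^2 + (cl - ct[2])^2 <= radius^2) img[r, cl] <- value
    }
  }
  img
}

ref_T <- function() {
  build_mixing_matrix(list(
    H2B = c(0.05, 0.45, 1.00, 0.30, 0.02),
    MDR = c(1.00, 0.30, 0.05, 0.60, 0.01),
    Dox = c(0.10, 0.80, 0.55, 0.25, 1.00),
    background = c(0.30, 0.25, 0.20, 1.00, 0.15)))
}

test_that("median disc filter removes compact objects from a flat background", {
  img <- matrix(5, 30, 30)
  img[14:16, 14:16] <- 100
  out <- median_disc(img, radius = 5)
  expect_equal(out, matrix(5, 30, 30))
})

test_that("uniform images give a unit illumination field", {
  L <- estimate_illumination(list(matrix(3, 20, 25), matrix(3, 20, 25)),
                             radius = 3)
  expect_equal(max(L), 1)
  expect_lt(max(abs(L - 1)), 1e-8)
})

test_that("a quadratic field with sparse cells is recovered within 2% RMS", {
  L <- quad_field()
  b <- 10
  centers <- list(c(8, 10), c(20, 30), c(31, 42), c(12, 38))
  imgs <- lapply(1:4, function(t) {
    C <- cells_image(centers = centers[seq_len(t %% 4 + 1)])
    L * (C + b)
  })
  Lhat <- estimate_illumination(imgs, radius = 6, degree = 2)
  expect_equal(max(Lhat), 1)
  rms <- sqrt(mean((Lhat - L)^2))
  expect_lt(rms, 0.02)
})

test_that("illumination correction inverts the forward model exactly", {
  L <- quad_field()
  img <- matrix(runif(prod(dim(L)), 1, 10), nrow(L), ncol(L))
  expect_equal(correct_illumination(img, matrix(1, nrow(L), ncol(L))), img)
  expect_equal(correct_illumination(L, L), matrix(1, nrow(L), ncol(L)))
  expect_lt(max(abs(correct_illumination(L * img, L) - img)), 1e-10)
  expect_error(correct_illumination(img, L * 0), "non-positive")
})

test_that("mixing matrix rows are unit-peak spectra; pure channels give basis rows", {
  Tm <- ref_T()
  expect_true(all(unclass(Tm) >= 0 & unclass(Tm) <= 1))
  expect_true(all(apply(Tm, 1, max) == 1))
  expect_equal(qr(Tm)$rank, 4)

  pure <- build_mixing_matrix(list(a = c(0, 7, 0, 0, 0),
                                   b = c(0, 0, 0, 3, 0),
                                   c = c(2, 0, 0, 0, 0)))
  expect_equal(unclass(pure)[1, ], c(I1 = 0, I2 = 1, I3 = 0, I4 = 0, I5 = 0))
  expect_error(build_mixing_matrix(list(a = c(0, 0, 0, 0, 0))), "all-zero")
})

test_that("duplicate spectra are reported as rank deficiency", {
  expect_warning(
    Tm <- build_mixing_matrix(list(a = c(1, 0.5, 0, 0, 0),
                                   b = c(1, 0.5, 0, 0, 0),
                                   c = c(0, 0, 1, 0, 0),
                                   d = c(0, 0, 0, 1, 0))),
    "rank deficient")
  expect_true(attr(Tm, "rank_deficient"))
  expect_error(unmix_signals(c(1, 1, 1, 1, 1), Tm), "rank-deficient")
})

test_that("unmixing solves exact mixtures to solver precision", {
  Tm <- ref_T()
  S_true <- c(12, 3, 40, 7)
  I_obs <- as.numeric(S_true %*% unclass(Tm))
  S <- unmix_signals(I_obs, Tm)
  expect_lt(max(rel_err(as.numeric(S), S_true)), 1e-8)
  expect_lt(attr(S, "residual_norm"), 1e-8)

  # identity-like T returns the first four channel means
  Te <- structure(diag(1, 4, 5), class = c("mixing_matrix", "matrix", "array"))
  S2 <- unmix_signals(c(5, 6, 7, 8, 0), Te)
  expect_equal(as.numeric(S2), c(5, 6, 7, 8))
})

test_that("unmixed doxorubicin survives 1% channel noise within 3% (median)", {
  Tm <- ref_T()
  S_true <- c(12, 3, 40, 7)
  I_clean <- as.numeric(S_true %*% unclass(Tm))
  errs <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      I_noisy <- I_clean * (1 + stats::rnorm(5, 0, 0.01))
      S <- unmix_signals(I_noisy, Tm)
      rel_err(S[1, "Dox"], S_true[3])
    }, numeric(1))
  })
  expect_lt(median(errs), 0.03)
})

test_that("calibration and conversion are exact mutual inverses", {
  cal <- calibrate_signal(c(0, 100, 250, 500), 0.04 * c(0, 100, 250, 500) + 2)
  expect_equal(cal$a, 0.04, tolerance = 1e-12)
  expect_equal(cal$b, 2, tolerance = 1e-12)
  expect_equal(as.numeric(signal_to_concentration(0.04 * 123 + 2, cal)), 123)
  # identity calibration
  ident <- calibrate_signal(c(0, 1), c(0, 1))
  expect_equal(as.numeric(signal_to_concentration(0.7, ident)), 0.7)
  # clipping below background
  out <- signal_to_concentration(1.5, cal)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "clipped"))
  expect_error(calibrate_signal(c(5, 5), c(1, 2)), "distinct")
})

test_that("threshold segmentation counts non-touching objects with 8-connectivity", {
  img <- matrix(0, 50, 60)
  centers <- expand.grid(r = c(10, 25, 40), c = c(10, 25, 40, 52))
  for (i in seq_len(nrow(centers)))
    img[centers$r[i] + (-1:1), centers$c[i] + (-1:1)] <- 50
  seg <- segment_cells(img, threshold = 10)
  expect_equal(seg$count, 12)
  expect_equal(sum(seg$mask), 12 * 9)
  # blank image and over-threshold cases
  expect_equal(segment_cells(matrix(0, 10, 10), 1)$count, 0)
  expect_equal(segment_cells(img, max(img) + 1)$count, 0)
  # diagonal contact merges objects
  d <- matrix(0, 6, 6); d[2, 2] <- 1; d[3, 3] <- 1
  expect_equal(segment_cells(d, 0.5)$count, 1)
})

test_that("full pipeline recovers concentrations exactly on noiseless stacks", {
  Tm <- ref_T()
  L <- quad_field(40, 50)
  flat <- matrix(1, 40, 50)
  mask <- cells_image(centers = list(c(12, 12), c(30, 35)), radius = 4,
                      value = 1) > 0
  dox_in <- 80; dox_out <- 20
  S_maps <- list(
    H2B = ifelse(mask, 25, 0),
    MDR = ifelse(mask, 10, 0),
    Dox = ifelse(mask, dox_in, dox_out),
    background = matrix(6, 40, 50))
  # the background is unmixed as its own fluorophore, so the doxorubicin
  # signal maps to concentration with a unit line (a = 1, b = 0)
  cal <- calibrate_signal(c(0, 50, 100, 200), c(0, 50, 100, 200))
  gen <- gen_spectral_stack(S_maps, Tm, L, sigma = 0)
  res <- unmix_stack(gen$stack, Tm, L, mask, cal, guard_px = 2)
  expect_lt(rel_err(res$signals["intracellular", "Dox"], dox_in), 1e-6)
  expect_lt(rel_err(res$signals["extracellular", "Dox"], dox_out), 1e-6)
  expect_lt(rel_err(res$conc[["intracellular"]], dox_in), 1e-6)
  expect_lt(rel_err(res$conc[["extracellular"]], dox_out), 1e-6)
  expect_lt(max(res$residual_norm), 1e-8)
})
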