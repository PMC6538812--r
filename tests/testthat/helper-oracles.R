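# Shared fixtures and independent oracles.

# Uptake parameters measured for the efflux-pump-overexpressing line
# (monotherapy): the standard fixture for PK tests.
ref_pk <- function(v_ratio = 1.5e5) {
  pk_params(k_EF = 3.08e-6, k_FE = 0.313, k_FB = 0.0212, v_ratio = v_ratio)
}

ref_course <- function() treatment_course(c(0, 8), c(1000, 0), horizon_h = 24)

# Independent piecewise matrix-exponential oracle for the uptake system,
# built on Matrix::expm (a different algorithm from the package's
# eigendecomposition path). State order (C_E, C_F, C_B).
oracle_pk <- function(params, course, times) {
  A <- rbind(c(-params$k_EF, params$k_FE / params$v_ratio, 0),
             c(params$k_EF * params$v_ratio,
               -(params$k_FE + params$k_FB), 0),
             c(0, params$k_FB, 0))
  ev_t <- course$times_h
  ev_c <- course$conc_nM
  x <- c(0, 0, 0)
  t_cur <- 0
  out <- matrix(NA_real_, length(times), 3)
  bounds <- c(ev_t, course$horizon_h)
  for (s in seq_along(ev_t)) {
    x <- as.numeric(Matrix::expm(A * (ev_t[s] - t_cur)) %*% x)
    x[1] <- ev_c[s]
    t_cur <- ev_t[s]
    sel <- which(times >= ev_t[s] - 1e-12 &
                   (times < bounds[s + 1] - 1e-12 | s == length(ev_t)))
    for (i in sel)
      out[i, ] <- as.numeric(Matrix::expm(A * (times[i] - t_cur)) %*% x)
  }
  colnames(out) <- c("C_E", "C_F", "C_B")
  out
}

# random uptake parameter sets, rates log-uniform in [1e-6, 1] / h
random_pk_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- 10^stats::runif(3, -6, 0)
      pk_params(k[1], k[2], k[3], v_ratio = 10^stats::runif(1, 0, 4))
    })
  })
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# relative discrepancy between two trajectories, per compartment, scaled by
# each compartment's peak magnitude
traj_rel_diff <- function(a, b) {
  m <- pmax(apply(abs(b), 2, max), 1e-12)
  max(abs(a - b) / rep(m, each = nrow(a)))
}
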