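# Independent oracles used across the suite. These deliberately avoid the
# package's own integration/enumeration code paths.

# Reference solution of the two-state membrane ODE via deSolve (adaptive
# lsoda), independent of the package's matrix-exponential integrator.
ode_membrane_oracle <- function(params, current_fun, times) {
  f <- function(t, y, p) {
    I <- current_fun(t)
    dv <- (-p$g_L * (y[1] - p$E_L) - p$a * y[2] + I) / p$C
    dw <- ((y[1] - p$E_L) - y[2]) / p$tau_w
    list(c(dv, dw))
  }
  out <- deSolve::lsoda(c(params$E_L, 0), times, f, params,
                        rtol = 1e-10, atol = 1e-10)
  out[, 2]
}

# step-current closure
step_current <- function(onset, duration, amp) {
  function(t) ifelse(t >= onset & t < onset + duration, amp, 0)
}

# Brute-force exact p for the Wilcoxon signed-rank test: all 2^n sign
# assignments, mid-ranks, two-sided as twice the smaller tail.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
}

# Brute-force exact p for the Mann-Whitney test: all choose(n, n1) labelings.
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  cmb <- utils::combn(length(pooled), n1)
  Rs <- apply(cmb, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(Rs <= R1), mean(Rs >= R1)))
}

# Brute-force exact p for the two-sample KS test.
brute_ks_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  zs <- sort(unique(pooled))
  Dof <- function(a, b) max(abs(ecdf(a)(zs) - ecdf(b)(zs)))
  D <- Dof(x, y)
  cmb <- utils::combn(length(pooled), n1)
  Ds <- apply(cmb, 2, function(i) Dof(pooled[i], pooled[-i]))
  mean(Ds >= D - 1e-12)
}

# Noiseless voltage response to a set of synaptic current kernels, computed by
# direct numerical superposition (convolution with the membrane impulse
# response obtained from deSolve), independent of the simulator.
superposition_oracle <- function(params, synapse, onset, duration, dt) {
  times <- seq(0, duration, by = dt)
  v <- rep(params$E_L, length(times))
  for (nm in names(synapse$components)) {
    co <- synapse$components[[nm]]
    if (co[["amp"]] == 0) next
    cur <- kernel_current_fun(params, co, onset, dt)
    v <- v + ode_membrane_oracle(params, cur, times) - params$E_L
  }
  v
}

# closure returning the calibrated kernel current at arbitrary t (linear
# interpolation of the sampled kernel; calibration by the oracle itself on a
# fine grid)
kernel_current_fun <- function(params, co, onset, dt) {
  tk <- seq(0, min(1500, co[["decay"]] * 12), by = dt)
  k <- exp(-tk / co[["decay"]]) - exp(-tk / co[["rise"]])
  k <- k / max(k)
  # unit-peak kernel gain via the ODE oracle
  times <- seq(0, max(tk) + 4 * co[["decay"]], by = dt)
  kf <- function(t) approx(tk, k, xout = t, yleft = 0, yright = 0)$y
  v1 <- ode_membrane_oracle(params, kf, times)
  gain <- max(abs(v1 - params$E_L))
  scale <- co[["amp"]] / gain
  function(t) scale * approx(tk, k, xout = t - onset - co[["latency"]],
                             yleft = 0, yright = 0)$y
}

# small random membrane within the regimes used by the cohort generator
random_membrane <- function(resonant = FALSE, noise_sd = 0) {
  if (resonant)
    membrane_params(C = runif(1, 120, 250), g_L = runif(1, 6, 14),
                    a = runif(1, 4, 10), tau_w = runif(1, 60, 150),
                    noise_sd = noise_sd)
  else
    membrane_params(C = runif(1, 100, 250), g_L = runif(1, 4, 10), a = 0,
                    noise_sd = noise_sd)
}

make_step_sweep <- function(params, amp = -80, seed = 1) {
  prot <- stimulus_protocol("current_step", onset_ms = 500,
                            amplitude_pa = amp, duration_ms = 3000)
  simulate_membrane(params, prot, 4000, seed = seed)
}

small_run_config <- function(noise_sd = 0.2) {
  cfg <- default_run_config(noise_sd = noise_sd)
  cfg$cohort$classes$L2_SC$n <- 10
  cfg$cohort$classes$L2_PC$n <- 8
  cfg$cohort$n_sweeps <- 3
  cfg$intrinsic_n <- 2
  cfg$train_n <- 3
  cfg$anatomy$n_slices <- 5
  cfg
}
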