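# Independent oracles used by the tests.  These deliberately avoid the code
# paths they check: linear algebra instead of time stepping, fine-step
# Euler-Maruyama instead of the exact OU update, jump-ODE integration
# instead of the short-term-plasticity recursion, and PSTH Fourier
# coefficients instead of the circular resultant.

# steady-state voltages of the passive compartmental circuit by a direct
# linear solve: G V = b with axial couplings and leak, current into soma
passive_steady_state_oracle <- function(model, i_soma_nA) {
  tab <- model$table
  nc <- nrow(tab)
  G <- matrix(0, nc, nc)
  b <- numeric(nc)
  for (i in seq_len(nc)) {
    G[i, i] <- tab$gL_nS[i]
    b[i] <- tab$gL_nS[i] * model$densities$E_leak
  }
  for (i in seq_len(nc - 1)) {
    g <- model$g_axial_nS[i]
    G[i, i] <- G[i, i] + g
    G[i + 1, i + 1] <- G[i + 1, i + 1] + g
    G[i, i + 1] <- G[i, i + 1] - g
    G[i + 1, i] <- G[i + 1, i] - g
  }
  b[1] <- b[1] + i_soma_nA * 1000
  solve(G, b)  # mV
}

# continuous sealed-end finite cable + lumped soma input resistance (MOhm)
passive_cable_rin_analytic <- function(geometry, g_leak_pS_um2,
                                       E = NULL) {
  rm_ohm_cm2 <- 1 / (g_leak_pS_um2 * 1e-12 / 1e-8)     # Ohm cm^2
  ra <- geometry$axial_resistivity                      # Ohm cm
  d_cm <- geometry$axon_diameter * 1e-4
  lambda <- sqrt(rm_ohm_cm2 * d_cm / (4 * ra))          # cm
  # semi-infinite cable input resistance: (2/pi) sqrt(rm ra) / d^(3/2)
  r_inf <- (2 / pi) * sqrt(rm_ohm_cm2 * ra) / d_cm^1.5
  L <- geometry$axon_length * 1e-4 / lambda             # electrotonic length
  r_cable <- r_inf / tanh(L)                            # sealed end
  soma_area_cm2 <- pi * geometry$soma_diameter^2 * 1e-8
  r_soma <- rm_ohm_cm2 / soma_area_cm2
  1 / (1 / r_cable + 1 / r_soma) / 1e6                  # MOhm
}

# Euler-Maruyama OU simulation at a finer step, downsampled
ou_euler_oracle <- function(n, dt, tau, refine = 10, seed = 1) {
  set.seed(seed)
  h <- dt / refine
  m <- n * refine
  x <- numeric(m + 1)
  x[1] <- rnorm(1)
  xi <- rnorm(m)
  for (k in seq_len(m))
    x[k + 1] <- x[k] - x[k] * h / tau + sqrt(2 * h / tau) * xi[k]
  x[1 + seq_len(n) * refine]
}

# inhomogeneous Poisson spikes with rate r0 * (1 + m sin(2 pi f t)) by
# thinning, times in seconds
modulated_poisson_oracle <- function(r0, m, f, duration, seed = 1) {
  set.seed(seed)
  rmax <- r0 * (1 + abs(m))
  n <- rpois(1, rmax * duration)
  t <- sort(runif(n, 0, duration))
  keep <- runif(n) < (1 + m * sin(2 * pi * f * t)) / (1 + abs(m))
  t[keep]
}

# fundamental Fourier coefficient of the cycle-folded PSTH, divided by the
# mean rate: the binned estimate of the modulation index r1 / r0
psth_modulation_oracle <- function(spikes, f, duration, n_bins = 64) {
  phase <- (spikes * f) %% 1
  counts <- tabulate(pmin(floor(phase * n_bins) + 1, n_bins), n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  rate <- counts / (duration * f) * n_bins * f  # spikes/s per bin
  a <- 2 * mean(rate * cos(2 * pi * centers))
  b <- 2 * mean(rate * sin(2 * pi * centers))
  sqrt(a^2 + b^2) / mean(rate)
}

# continuous-time Tsodyks-Markram dynamics integrated numerically between
# spikes (deSolve at tight tolerances) with jumps at spike times; returns
# the efficacy applied at each spike
stp_ode_oracle <- function(spike_times, U, D, F, w0 = 1) {
  deriv <- function(t, y, p)
    list(c((1 - y[1]) / D, -y[2] / F))
  R <- 1
  u <- 0
  t <- 0
  w <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    ts <- spike_times[k]
    if (ts > t) {
      sol <- deSolve::ode(c(R = unname(R), u = unname(u)), c(t, ts),
                          deriv, NULL, rtol = 1e-12, atol = 1e-12)
      R <- unname(sol[nrow(sol), "R"])
      u <- unname(sol[nrow(sol), "u"])
    }
    t <- ts
    u <- u + U * (1 - u)      # facilitation jump; applied utilization
    w[k] <- w0 * R * u
    R <- R * (1 - u)          # resource consumption after release
  }
  unname(w)
}

# brute-force numeric rheobase of an eIF by bisection on a long constant
# current (nA)
eif_rheobase_oracle <- function(p, lo = 0, hi = 2, dur_ms = 2000,
                                tol = 1e-4) {
  fires <- function(i_nA) {
    sim <- simulate_eif(p, rep(i_nA, round(dur_ms / 0.01)), dt = 0.01,
                        record_v = FALSE)
    length(sim$spikes$times) > 0
  }
  while (!fires(hi)) hi <- hi * 2
  for (k in 1:40) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# small helpers shared across tests
desk_bas <- function(d, ...) {
  bas_model(cable_geometry(), channel_densities(g_leak = 0.33, ...),
            ais_distance = d)
}
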