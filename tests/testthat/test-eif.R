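test_that("eIF parameter validation enforces the model constraints", {
  expect_error(eif_params(tau_m = 5, E_L = -70, V_T = -55, Delta_T = -1),
               "Delta_T")
  expect_error(eif_params(tau_m = 5, E_L = -70, V_T = -90, Delta_T = 1),
               "V_reset")
  p <- eif_params(tau_m = 5, E_L = -70, V_T = -55, Delta_T = 1)
  expect_equal(p$C_m, 70)  # tau_m * g_L with the 14 nS default
  expect_equal(p$tau_m, p$C_m / p$g_L)
  tab <- eif_reference_params()
  expect_equal(nrow(tab), 11)
  expect_true(all(diff(tab$Delta_T) < 0))  # sharpness falls with distance
})

test_that("subthreshold response follows the LIF charging curve", {
  # with V far below V_T the exponential term is negligible
  p <- eif_params(tau_m = 10, E_L = -70, V_T = -30, Delta_T = 0.5)
  i_nA <- 0.1
  sim <- simulate_eif(p, rep(i_nA, 60000), dt = 0.005)
  t_ms <- trace_times(sim$trace)
  v_inf <- -70 + i_nA * 1000 / p$g_L  # mV
  pred <- v_inf + (p$E_L - v_inf) * exp(-t_ms / p$tau_m)
  expect_lt(max(abs(sim$trace$v - pred)), 0.05)
  expect_equal(length(sim$spikes$times), 0L)
})

test_that("rheobase matches the closed form and a bisection oracle", {
  p <- eif_params(tau_m = 7.85, E_L = -74.51, V_T = -59.14, Delta_T = 1.63)
  i_rh_closed <- p$g_L * (p$V_T - p$E_L - p$Delta_T) / 1000  # nA
  i_rh_num <- eif_rheobase_oracle(p)
  expect_lt(abs(i_rh_num - i_rh_closed) / i_rh_closed, 0.02)
  fires <- function(i_nA) length(simulate_eif(
    p, rep(i_nA, 4e5), dt = 0.005, record_v = FALSE)$spikes$times) > 0
  expect_true(fires(i_rh_num * 1.05))
  expect_false(fires(i_rh_num * 0.95))
})

test_that("a pure leak neuron yields a linear I-V with the right slope", {
  p <- eif_params(tau_m = 10, E_L = -70, V_T = -20, Delta_T = 0.5)
  st <- compose_stimulus(stimulus_config(I0 = 0, s = 0.3, tau_noise = 5,
                                         duration = 20, seed = 8))
  sim <- simulate_eif(p, st)
  iv <- empirical_iv(sim$trace, st$current, sim$spikes,
                     v_max = -40)
  fit <- lm(f ~ v, data = iv[iv$usable, ], weights = count)
  expect_equal(-1 / coef(fit)[[2]], 10, tolerance = 0.05)
  expect_equal(-coef(fit)[[1]] / coef(fit)[[2]], -70, tolerance = 0.01)
  # the variance-minimizing capacitance recovers C_m
  expect_equal(attr(iv, "C_m"), p$C_m, tolerance = 0.02)
})

test_that("fitting analytic I-V samples recovers the parameters", {
  # noisy samples of the eIF f(V) itself, on a realistic bin grid
  set.seed(4)
  p <- list(tau_m = 7.85, E_L = -74.51, V_T = -59.14, Delta_T = 1.63)
  v <- seq(-90, -50, 0.5)
  f <- (p$E_L - v + p$Delta_T * exp((v - p$V_T) / p$Delta_T)) / p$tau_m
  iv <- data.frame(v = v, f = f * (1 + rnorm(length(v), 0, 0.01)),
                   f_sd = abs(f) * 0.01, count = rep(1000, length(v)),
                   usable = TRUE)
  class(iv) <- c("iv_curve", "data.frame")
  attr(iv, "C_m") <- 109.9
  fit <- fit_eif(iv)
  for (nm in names(p))
    expect_lt(abs(fit[[nm]] - p[[nm]]) / abs(p[[nm]]), 0.05)
})

test_that("degenerate I-V input is rejected", {
  iv <- data.frame(v = c(-70.25), f = 0, f_sd = 0, count = 1e4,
                   usable = TRUE)
  class(iv) <- c("iv_curve", "data.frame")
  expect_error(fit_eif(iv), "too few bins")
  tr <- voltage_trace(rep(-70, 1000), 0.005)
  expect_error(empirical_iv(tr, rep(0, 1000),
                            spike_train(numeric(0), 0.005),
                            C_m = 100),
               "too few usable voltage bins")
})

test_that("eIF spike trains reproduce the source model's timing", {
  # simulate a known eIF, then simulate the fitted reduction under the
  # same stimulus and count coincident spikes within +-5 ms
  tab <- eif_reference_params()
  row <- tab[tab$d == 25, ]
  p <- eif_params(tau_m = row$tau_m, E_L = row$E_L, V_T = row$V_T,
                  Delta_T = row$Delta_T)
  st <- compose_stimulus(stimulus_config(I0 = 0.05, s = 0.17,
                                         duration = 20, seed = 12))
  ref <- simulate_eif(p, st)
  iv <- empirical_iv(ref$trace, st$current, ref$spikes)
  fit <- fit_eif(iv)
  p2 <- eif_params(tau_m = fit$tau_m, E_L = fit$E_L, V_T = fit$V_T,
                   Delta_T = fit$Delta_T,
                   g_L = attr(iv, "C_m") / fit$tau_m)
  rep2 <- simulate_eif(p2, st, record_v = FALSE)
  hits <- sum(vapply(ref$spikes$times, function(t)
    any(abs(rep2$spikes$times - t) <= 0.005), logical(1)))
  expect_gte(hits / length(ref$spikes$times), 0.8)
})
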