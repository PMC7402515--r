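test_that("model construction assigns the AIS to the nearest compartment", {
  m <- bas_model()
  expect_equal(nrow(m$table), 12)  # soma + 11 axonal compartments
  expect_equal(m$geometry$n_axon_compartments, 11L)

  # d = 0: AIS on the compartment adjacent to the soma
  m0 <- bas_model(ais_distance = 0)
  expect_equal(m0$ais_index, 1L)

  # d = 25 um: brute-force nearest-center search over the 4.545 um grid
  centers <- (seq_len(11) - 0.5) * (50 / 11)
  expect_equal(bas_model(ais_distance = 25)$ais_index,
               which.min(abs(centers - 25)))
  expect_equal(bas_model(ais_distance = 25)$ais_index, 6L)

  # exactly one compartment carries AIS-level densities
  for (d in c(0, 7, 25, 50)) {
    md <- bas_model(ais_distance = d)
    expect_equal(sum(md$table$gNa_nS > 100), 1L)
  }
})

test_that("invalid geometry and AIS placement are rejected", {
  expect_error(bas_model(ais_distance = 60), "ais_distance")
  expect_error(bas_model(ais_distance = -1), "ais_distance")
  expect_error(cable_geometry(axon_diameter = -1), "positive")
  expect_error(cable_geometry(n_axon_compartments = 1), "integer >= 2")
  expect_error(channel_densities(gNa_ais = 0.5), "gNa_ais")
  expect_error(channel_densities(E_K = 100), "reversal")
})

test_that("passive limit matches closed-form cable solutions", {
  m <- passive_model(desk_bas(25))

  # zero current, active conductances disabled: relax to E_leak
  sim <- simulate_bas(m, rep(0, 40000), dt = 0.005, v_init = -70)
  expect_lt(abs(tail(sim$trace$v, 1) - (-60)), 0.05)

  # DC step: somatic steady state against the linear-algebra oracle
  sim2 <- simulate_bas(m, rep(-0.005, 60000), dt = 0.005, v_init = -60)
  v_num <- tail(sim2$trace$v, 1)
  v_ora <- passive_steady_state_oracle(m, -0.005)[1]
  expect_lt(abs(v_num - v_ora) / abs(v_ora - (-60)), 1e-3)

  # input resistance against both the discrete and the continuous oracle
  rin <- input_resistance(m, hold = 0)
  rin_disc <- (passive_steady_state_oracle(m, -0.002)[1] - (-60)) / -0.002
  expect_lt(abs(rin - rin_disc) / rin_disc, 1e-3)
  rin_cont <- passive_cable_rin_analytic(m$geometry, 0.33)
  expect_lt(abs(rin - rin_cont) / rin_cont, 1e-3)

  # uniform passive membrane relaxes with a single time constant C_m / g_L
  sim3 <- simulate_bas(m, rep(0, 8000), dt = 0.005, v_init = -70)
  v <- sim3$trace$v
  t_ms <- trace_times(sim3$trace)
  sel <- t_ms >= 2 & t_ms <= 30
  tau_fit <- -1 / coef(lm(log(-60 - v[sel]) ~ t_ms[sel]))[[2]]
  tau_true <- 0.5625 * 0.01 / (0.33e-3)  # ms, per-area C over per-area g
  expect_lt(abs(tau_fit - tau_true) / tau_true, 1e-3)

  # doubling the soma area decreases the input resistance
  big <- passive_model(bas_model(
    cable_geometry(soma_diameter = 20 * sqrt(2)),
    channel_densities(g_leak = 0.33), 25))
  expect_lt(input_resistance(big, hold = 0), rin)
})

test_that("AIS relocation leaves passive properties essentially unchanged", {
  r0 <- input_resistance(desk_bas(0))
  r50 <- input_resistance(desk_bas(50))
  expect_lt(abs(r50 - r0) / r0, 5e-4)
  # total membrane area is invariant under relocation
  expect_equal(sum(desk_bas(0)$table$area_um2),
               sum(desk_bas(50)$table$area_um2))
})

test_that("simulation is deterministic and convergent in dt", {
  m <- desk_bas(25)
  st <- compose_stimulus(stimulus_config(I0 = -0.01, s = 0.0075,
                                         duration = 3, seed = 4))
  s1 <- simulate_bas(m, st, record = "none")
  s2 <- simulate_bas(m, st, record = "none")
  expect_identical(s1$spikes$times, s2$spikes$times)
  expect_gt(length(s1$spikes$times), 0)

  # refinement: halving dt moves each spike by less than 0.01 ms on a
  # smooth deterministic drive at the low-rate operating regime
  mk <- function(dt) {
    t_ms <- (seq_len(round(600 / dt)) - 1) * dt
    -0.008 + 0.006 * sin(2 * pi * 5 * t_ms / 1000)
  }
  sa <- simulate_bas(m, mk(0.005), dt = 0.005, record = "none")
  sb <- simulate_bas(m, mk(0.0025), dt = 0.0025, record = "none")
  expect_equal(length(sa$spikes$times), length(sb$spikes$times))
  expect_lt(max(abs(sa$spikes$times - sb$spikes$times)) * 1000, 0.01)

  # spatial refinement: passive somatic properties converge when the
  # axon is discretized twice as finely
  r11 <- input_resistance(passive_model(desk_bas(25)), hold = 0)
  m22 <- passive_model(bas_model(
    cable_geometry(n_axon_compartments = 22),
    channel_densities(g_leak = 0.33), 25))
  expect_lt(abs(input_resistance(m22, hold = 0) - r11) / r11, 1e-3)
})

test_that("calibrated noisy stimulation fires near the target rate", {
  m <- desk_bas(25)
  op <- calibrate_operating_point(m, duration = 20, seed = 1)
  expect_lt(abs(op$rate - 5), 0.25 + 1e-9)
  expect_gte(op$sd_v, 5)
  expect_lte(op$sd_v, 10)
  # an independent noise realization stays close to the target rate
  st <- compose_stimulus(stimulus_config(I0 = op$I0, s = op$s,
                                         duration = 30, seed = 999))
  r <- simulate_bas(m, st, record = "none")$spikes$rate
  expect_lt(abs(r - 5), 1.5)
})

test_that("spiking during the input-resistance probe is an error", {
  m <- desk_bas(25)
  expect_error(input_resistance(m, hold = 0.05), "spiked")
})

test_that("model serialization round-trips bit-exactly", {
  m <- bas_model(cable_geometry(soma_diameter = 17.3),
                 channel_densities(g_leak = 0.33), ais_distance = 12.5)
  js <- model_to_json(m)
  m2 <- model_from_json(js)
  expect_identical(m$table, m2$table)
  expect_identical(m$g_axial_nS, m2$g_axial_nS)
  expect_identical(unclass(m$kinetics), unclass(m2$kinetics))
  expect_identical(m$ais_distance, m2$ais_distance)
})
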