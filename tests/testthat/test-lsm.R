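test_that("the short-term plasticity recursion has the stated limits", {
  p <- stp_params(U = 0.59, D = 813, F = 1, w0 = 2)
  first <- stp_update(stp_state(), p = p)
  expect_equal(first$state$R, 1)
  expect_equal(first$state$u, 0.59)
  expect_equal(first$w, 2 * 0.59)

  # full recovery at long intervals
  later <- stp_update(first$state, dt = 1e7, p = p)
  expect_equal(later$state$R, 1, tolerance = 1e-9)
  expect_equal(later$state$u, p$U, tolerance = 1e-9)

  expect_error(stp_update(first$state, dt = -1, p = p), "positive")
  expect_error(stp_params(U = 1.5, D = 1, F = 1), "U must")
})

test_that("periodic trains reach the analytic fixed point", {
  p <- stp_params(U = 0.2, D = 300, F = 500, w0 = 1)
  dt <- 40
  s <- stp_state()
  for (k in 1:1000) s <- stp_update(s, dt = dt, p = p)$state
  # fixed point of the recursion, solved in closed form
  eF <- exp(-dt / p$F)
  eD <- exp(-dt / p$D)
  u_star <- p$U / (1 - (1 - p$U) * eF)
  r_star <- (1 - eD) / (1 - (1 - u_star) * eD)
  expect_equal(s$u, u_star, tolerance = 1e-10)
  expect_equal(s$R, r_star, tolerance = 1e-10)
})

test_that("the recursion matches a continuous-time jump-ODE oracle", {
  set.seed(7)
  spikes <- cumsum(rexp(300, 1 / 50))  # ms
  for (cls in list(c(0.59, 813, 1), c(0.049, 399, 1790),
                   c(0.016, 45, 376), c(0.25, 706, 21))) {
    p <- stp_params(U = cls[1], D = cls[2], F = cls[3], w0 = 1.3)
    s <- stp_state()
    w_rec <- vapply(seq_along(spikes), function(k) {
      dt <- if (k == 1) NA else spikes[k] - spikes[k - 1]
      r <- stp_update(s, dt = dt, p = p)
      s <<- r$state
      r$w
    }, numeric(1))
    w_ode <- stp_ode_oracle(spikes, p$U, p$D, p$F, w0 = 1.3)
    expect_lt(max(abs(w_rec - w_ode) / w_ode), 1e-6)
  }
})

test_that("network wiring honors the fixed degrees and is reproducible", {
  cfg <- network_config(n_exc = 120, n_inh = 30, n_input = 4,
                        n_readout = 20,
                        degree = c(`in` = 15, EE = 10, EI = 10,
                                   IE = 8, II = 8))
  net <- build_network(cfg, seed = 3)
  e <- net$edges
  # every excitatory neuron has exactly 10 incoming EE connections
  ee <- e[e$class == "EE", ]
  expect_true(all(table(factor(ee$post, levels = 1:120)) == 10))
  ie <- e[e$class == "IE", ]
  expect_true(all(table(factor(ie$post, levels = 1:120)) == 8))
  expect_true(all(ie$pre > 120))
  # each input unit projects to exactly 15 excitatory targets
  expect_true(all(table(net$input_edges$channel) == 15))
  expect_true(all(net$input_edges$post <= 120))
  # no autapses, nonnegative weights, delays in class ranges
  expect_true(all(e$pre != e$post))
  expect_true(all(e$w >= 0))
  expect_true(all(e$delay[e$class %in% c("EE", "EI")] >= 1))
  expect_true(all(e$delay[e$class %in% c("IE", "II")] <= 2))

  net2 <- build_network(cfg, seed = 3)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$readout, net2$readout)
  expect_error(build_network(network_config(n_exc = 10, n_inh = 5),
                             seed = 1),
               "degrees")
})

test_that("an unstimulated, noiseless network is silent and runs are
           reproducible", {
  cfg <- network_config(n_exc = 120, n_inh = 30, n_input = 4,
                        n_readout = 20, noise_rate = 0,
                        degree = c(`in` = 15, EE = 10, EI = 10,
                                   IE = 8, II = 8))
  net <- build_network(cfg, seed = 3)
  eif <- eif_params(tau_m = 7.6, E_L = -74.39, V_T = -59.16,
                    Delta_T = 1.5)
  sp <- simulate_network(net, eif, NULL, duration = 500, seed = 5)
  expect_equal(nrow(sp), 0L)

  # input-driven activity is deterministic given the seed
  input <- data.frame(channel = c(1, 2, 3), time = c(5, 9, 13))
  cfg2 <- network_config(n_exc = 120, n_inh = 30, n_input = 4,
                         n_readout = 20,
                         degree = c(`in` = 15, EE = 10, EI = 10,
                                    IE = 8, II = 8))
  net2 <- build_network(cfg2, seed = 3)
  a <- simulate_network(net2, eif, input, duration = 500, seed = 5)
  b <- simulate_network(net2, eif, input, duration = 500, seed = 5)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  expect_gt(nrow(a), 0)
})

test_that("liquid states apply the exponential kernel at epoch ends", {
  spikes <- data.frame(neuron = c(7, 7, 9), time = c(50, 80, 30))
  attr(spikes, "duration") <- 100
  st <- extract_states(spikes, readout = c(7, 9), duration = 100,
                       epoch = 50, tau = 20)
  expect_equal(dim(st), c(2, 2))
  expect_equal(st[1, 1], 1.0)                      # spike at epoch end
  expect_equal(st[2, 1], exp(-50 / 20) + exp(-20 / 20))
  expect_equal(st[1, 2], exp(-20 / 20))            # 20 ms before the end
  # silent neuron contributes zeros
  st2 <- extract_states(spikes, readout = c(7, 11), duration = 100)
  expect_true(all(st2[, 2] == 0))
})

test_that("linear readouts separate what is separable and not chance", {
  set.seed(6)
  n <- 400
  lab <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 1] <- x[, 1] + 8 * lab  # linearly separable feature
  acc <- train_readout(x, lab, n_splits = 20, seed = 1)
  expect_gt(acc, 0.99)
  # shuffled labels: chance level for a balanced task
  acc0 <- train_readout(x, sample(lab), n_splits = 40, seed = 2)
  expect_lt(abs(acc0 - 0.5), 0.08)
  # deterministic given the split seed
  expect_identical(as.numeric(train_readout(x, lab, n_splits = 10, seed = 3)),
                   as.numeric(train_readout(x, lab, n_splits = 10, seed = 3)))
  expect_error(train_readout(x, rep(1, n)), "both classes")
})

test_that("identical eIF parameters give statistically identical accuracy", {
  # null control at a micro scale: two "distances" that share one
  # parameter row must not differ significantly
  tab <- eif_reference_params()
  tab2 <- rbind(tab, within(tab[tab$d == 25, ], d <- 99))
  res <- run_xor_experiment(distances = c(25, 99), eif_table = tab2,
                            n_networks = 4, train_duration = 15,
                            n_readout_splits = 10,
                            cfg = network_config(n_exc = 200, n_inh = 50,
                                                 n_readout = 50,
                                                 degree = c(`in` = 30,
                                                            EE = 20,
                                                            EI = 20,
                                                            IE = 15,
                                                            II = 15)),
                            seed = 21)
  p <- xor_significance(res)[1, 2]
  expect_gt(p, 0.05)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})
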