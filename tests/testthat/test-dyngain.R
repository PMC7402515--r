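test_that("vector strength handles exact and degenerate cases", {
  # all spikes at phase 0 of a 10 cycle/s sine
  pv <- vector_strength(c(0, 0.1, 0.2, 0.5), f = 10)
  expect_equal(pv$magnitude, 1, tolerance = 1e-12)
  expect_equal(pv$angle, 0, tolerance = 1e-12)

  # two spikes at phases 0 and pi/2: r = (1 + i)/2
  pv2 <- vector_strength(c(0, 0.025), f = 10)
  expect_equal(pv2$r, (1 + 1i) / 2, tolerance = 1e-12)
  expect_equal(pv2$magnitude, sqrt(2) / 2, tolerance = 1e-12)

  # Rayleigh null: uniform phases
  set.seed(1)
  pv3 <- vector_strength(runif(1e5, 0, 1000), f = 1)
  expect_lt(pv3$magnitude, 0.01)

  expect_error(vector_strength(numeric(0), 1), "empty")
})

test_that("the resultant noise floor follows the Rayleigh expectation", {
  set.seed(2)
  n <- 400
  mags <- replicate(200, Mod(mean(exp(2i * pi * runif(n)))))
  expect_lt(abs(mean(mags) - sqrt(pi / (4 * n))) / sqrt(pi / (4 * n)), 0.1)
})

test_that("gain estimation recovers the modulation of a Poisson process", {
  # one stimulated frequency per run, as in the protocol
  sp1 <- modulated_poisson_oracle(r0 = 20, m = 0.4, f = 1, duration = 600,
                                  seed = 4)
  sp <- modulated_poisson_oracle(r0 = 20, m = 0.4, f = 7, duration = 600,
                                 seed = 5)
  gc <- gain_curve(c(1, 7), list(list(sp1), list(sp)), rep_duration = 600)
  raw7 <- gc$gain_raw[gc$f == 7]
  expect_lt(abs(raw7 - 0.4), 0.05)
  # PSTH Fourier oracle agrees with the circular estimate
  psth <- psth_modulation_oracle(sp, 7, 600)
  expect_lt(abs(raw7 - psth) / psth, 0.02)

  # unmodulated process: debiased gain near zero at non-stimulus frequency
  sp0 <- modulated_poisson_oracle(r0 = 20, m = 0, f = 7, duration = 600,
                                  seed = 6)
  pv0 <- vector_strength(sp0, 31)
  expect_lt(2 * pv0$magnitude, 2.5 * sqrt(pi / pv0$N))

  expect_error(gain_curve(c(2, 5), list(list(sp), list(sp))),
               "f = 1")
})

test_that("gain normalization is invariant to pooling more repetitions", {
  mk <- function(f, seed) modulated_poisson_oracle(20, 0.4, f, 150, seed)
  g2 <- gain_curve(c(1, 7), list(lapply(1:2, mk, f = 1),
                                 lapply(3:4, mk, f = 7)))
  g6 <- gain_curve(c(1, 7), list(lapply(5:10, mk, f = 1),
                                 lapply(11:16, mk, f = 7)))
  expect_lt(abs(g2$gain[g2$f == 7] - g6$gain[g6$f == 7]), 0.15)
  expect_lt(g6$gain_sd[g6$f == 7], 0.25)
})

test_that("cutoff frequency matches the one-pole closed form", {
  f <- pracma::logspace(0, 3, 46)
  fc <- 80
  curve <- data.frame(f = f, gain = 1 / sqrt(1 + (f / fc)^2))
  g1 <- 1 / sqrt(1 + (1 / fc)^2)  # raw value at the normalization point
  curve$gain <- curve$gain / g1
  # closed form: the normalized curve crosses 0.70 at ~1.02 fc
  target <- fc * sqrt(1 / (0.7 * g1)^2 - 1)
  expect_lt(abs(cutoff_frequency(curve) - target) / target, 0.02)

  # flat curve: no crossing
  expect_error(cutoff_frequency(data.frame(f = f, gain = rep(1, 46))),
               "no crossing")
  # already attenuated at the lowest frequency
  expect_error(cutoff_frequency(data.frame(f = f, gain = rep(0.1, 46))),
               "below")
})

test_that("power-law exponent is exact on synthetic power laws", {
  f <- pracma::logspace(0, 3, 30)
  curve <- data.frame(f = f, gain = f^-1.5)
  expect_equal(powerlaw_exponent(curve), 1.5, tolerance = 1e-9)
  # invariant to rescaling the curve
  curve2 <- data.frame(f = f, gain = 7.3 * f^-1.5)
  expect_equal(powerlaw_exponent(curve2), 1.5, tolerance = 1e-9)
  expect_error(powerlaw_exponent(curve, f_window = c(900, 1000)),
               "at least 3")
})

test_that("phase slope measures a pure propagation delay", {
  f <- pracma::logspace(0, 3, 30)
  delay_s <- 0.001
  curve <- data.frame(f = f,
                      phase = ((-2 * pi * f * delay_s + pi) %% (2 * pi)) - pi,
                      gain = rep(1, 30))
  expect_equal(phase_delay(curve), 1, tolerance = 1e-6)
  # zero delay
  curve0 <- data.frame(f = f, phase = rep(0, 30), gain = rep(1, 30))
  expect_equal(phase_delay(curve0), 0, tolerance = 1e-9)
})

test_that("logistic fit recovers parameters and evaluates published ones", {
  # direct evaluation of the fitted curve reported for the BAS model
  pub <- list(a = 57.69, k = 0.0541, d0 = 53.32, b = 81.3)
  expect_equal(predict_logistic(pub, 0), 84.35, tolerance = 0.01)
  expect_gt(predict_logistic(pub, 50), predict_logistic(pub, 0))

  set.seed(3)
  d <- seq(0, 50, 5)
  truth <- predict_logistic(pub, d)
  fit <- fit_logistic(d, truth + rnorm(length(d), 0, 0.2))
  expect_lt(abs(fit$b - pub$b) / pub$b, 0.05)
  expect_lt(max(abs(predict_logistic(fit, d) - truth)), 1.5)

  # degenerate constant input is flagged
  flat <- fit_logistic(d, rep(90, length(d)) + rnorm(length(d), 0, 1e-6))
  expect_true(flat$degenerate)
  expect_error(fit_logistic(c(0, 10, 20), c(1, 2, 3)), "at least 4")
})
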