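#' Ornstein-Uhlenbeck noise with unit variance
#'
#' Stationary zero-mean, unit-SD colored noise with exponential
#' autocorrelation of time constant \code{tau}, generated by the exact
#' update \eqn{x_{k+1} = x_k e^{-dt/\tau} + \sqrt{1 - e^{-2 dt/\tau}}\,\xi_k}
#' with standard-normal innovations and a stationary initial condition.
#'
#' @param n Number of samples.
#' @param dt Sampling step (ms).
#' @param tau Autocorrelation time constant (ms).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length \code{n}.
#' @export
ou_noise <- function(n, dt, tau = 5, seed = NULL) {
  if (tau <= 0 || dt <= 0) stop("tau and dt must be positive")
  if (dt >= tau) stop("dt must be smaller than tau")
  if (!is.null(seed)) set.seed(seed)
  .ou_noise_exact(as.integer(n), dt, tau)
}

#' Stimulus configuration
#'
#' Parameters of the injected current waveform
#' \eqn{I(t) = I_0 + I_1 \sin(2\pi f t) + s\, I_n(t)}, where \eqn{I_n} is
#' unit-variance Ornstein-Uhlenbeck noise.
#'
#' @param I0 DC offset (nA).
#' @param I1 Sine amplitude (nA), \code{>= 0}.
#' @param f Harmonic frequency (cycle/s), \code{>= 0}.
#' @param s Noise standard deviation (nA), \code{>= 0}.
#' @param tau_noise OU autocorrelation time constant (ms).
#' @param dt Sampling step (ms).
#' @param duration Duration (s).
#' @param seed Optional integer seed for the noise realization.
#' @return An object of class \code{stimulus_config}.
#' @export
stimulus_config <- function(I0 = 0, I1 = 0, f = 0, s = 0, tau_noise = 5,
                            dt = 0.005, duration = 1, seed = NULL) {
  if (s < 0) stop("s must be >= 0")
  if (I1 < 0) stop("I1 must be >= 0")
  if (f < 0) stop("f must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  structure(list(I0 = I0, I1 = I1, f = f, s = s, tau_noise = tau_noise,
                 dt = dt, duration = duration, seed = seed),
            class = "stimulus_config")
}

#' Compose the injected current waveform
#'
#' Samples \eqn{I(t) = I_0 + I_1 \sin(2\pi f t) + s\, I_n(t)} on the grid
#' \eqn{t_k = k\,dt}; the sine has phase 0 at \eqn{t = 0}.
#'
#' @param cfg A \code{\link{stimulus_config}}.
#' @return An object of class \code{stimulus} with elements \code{current}
#'   (nA), \code{dt} (ms), \code{duration} (s) and \code{config}.
#' @export
compose_stimulus <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"))
  n <- round(cfg$duration * 1000 / cfg$dt)
  t_ms <- (seq_len(n) - 1) * cfg$dt
  i <- rep(cfg$I0, n)
  if (cfg$I1 > 0 && cfg$f > 0)
    i <- i + cfg$I1 * sin(2 * pi * cfg$f * t_ms / 1000)
  if (cfg$s > 0)
    i <- i + cfg$s * ou_noise(n, cfg$dt, cfg$tau_noise, seed = cfg$seed)
  structure(list(current = i, dt = cfg$dt, duration = cfg$duration,
                 config = cfg), class = "stimulus")
}

# rate and subthreshold SD of one frozen-noise run; V samples within
# exclude_ms of a spike are dropped from the SD
.probe_run <- function(model, i0, s_nA, noise, dt, discard_s,
                       exclude_ms = 5) {
  sim <- if (inherits(model, "eif_params")) {
    r <- simulate_eif(model, i0 + s_nA * noise, dt = dt)
    r$trace$v <- r$trace$v[seq(1, length(r$trace$v), by = 10)]
    r$trace$dt <- r$trace$dt * 10
    r
  } else {
    simulate_bas(model, i0 + s_nA * noise, dt = dt, record = "soma",
                 record_stride = 10L)
  }
  st <- sim$spikes$times
  dur <- sim$spikes$duration
  rate <- sum(st > discard_s) / (dur - discard_s)
  v <- sim$trace$v
  dts <- sim$trace$dt
  keep <- rep(TRUE, length(v))
  keep[seq_len(min(length(v), round(discard_s * 1000 / dts)))] <- FALSE
  if (length(st) > 0) {
    for (t_s in st) {
      i1 <- max(1L, floor((t_s * 1000 - exclude_ms) / dts) + 1L)
      i2 <- min(length(v), ceiling((t_s * 1000 + exclude_ms) / dts) + 1L)
      keep[i1:i2] <- FALSE
    }
  }
  list(rate = rate, sd_v = sd(v[keep]), mean_v = mean(v[keep]))
}

#' Calibrate the stimulus operating point
#'
#' With \code{I1 = 0}, adapts the DC offset \code{I0} and the noise SD
#' \code{s} so that the model fires at \code{target_rate} while the SD of the
#' subthreshold somatic potential stays inside \code{sd_range}.  The search
#' uses a frozen noise realization: the noise amplitude is first scaled
#' linearly to put the subthreshold SD at the center of \code{sd_range}
#' (measured below rheobase), then \code{I0} is found by bisection on the
#' firing rate, and the subthreshold SD is re-checked at the solution
#' (at most \code{max_outer} adjustment rounds).
#'
#' @param model A \code{\link{bas_model}} (or \code{\link{eif_params}}; any
#'   object accepted by \code{simulator}).
#' @param target_rate Target mean rate (spikes/s).
#' @param rate_tol Acceptable rate deviation (spikes/s).
#' @param sd_range Acceptable subthreshold SD range (mV).
#' @param tau_noise OU time constant (ms).
#' @param dt Integration step (ms).
#' @param duration Duration of each probe simulation (s).
#' @param seed Seed of the frozen noise realization.
#' @param s_init Initial noise SD guess (nA).
#' @param max_iter Maximum bisection iterations.
#' @param max_outer Maximum outer rounds of noise-SD adjustment.
#' @param discard Initial transient discarded from rate/SD estimates (s).
#' @return An object of class \code{operating_point} with achieved
#'   \code{I0}, \code{s}, \code{rate} and \code{sd_v}.
#' @export
calibrate_operating_point <- function(model, target_rate = 5,
                                      rate_tol = 0.25,
                                      sd_range = c(5, 10), tau_noise = 5,
                                      dt = 0.005, duration = 20, seed = 1,
                                      s_init = 0.005, max_iter = 30,
                                      max_outer = 3, discard = 0.5) {
  if (target_rate <= 0)
    stop("target_rate must be positive (a zero-rate operating point is ",
         "below rheobase by construction)")
  n <- round(duration * 1000 / dt)
  noise <- ou_noise(n, dt, tau_noise, seed = seed)
  probe <- function(i0, s) .probe_run(model, i0, s, noise, dt, discard)

  s <- s_init
  sd_target <- mean(sd_range)
  i0_quiet <- 0
  for (outer in seq_len(max_outer)) {
    # hyperpolarize until silent, then scale the noise SD linearly
    step <- 0.005
    repeat {
      p <- probe(i0_quiet, s)
      if (p$rate == 0) break
      i0_quiet <- i0_quiet - step
      step <- step * 2
      if (i0_quiet < -10) stop("calibration failed: cannot silence model")
    }
    s <- s * sd_target / p$sd_v
    p <- probe(i0_quiet, s)
    if (abs(p$sd_v - sd_target) > 0.5) s <- s * sd_target / p$sd_v

    # bracket the target rate in I0, then bisect
    lo <- i0_quiet
    hi <- i0_quiet + 0.005
    repeat {
      p_hi <- probe(hi, s)
      if (p_hi$rate > target_rate) break
      lo <- hi
      hi <- hi + (hi - i0_quiet + 0.005)
      if (hi > 10) stop("calibration failed: cannot reach target rate")
    }
    it <- 0
    repeat {
      mid <- (lo + hi) / 2
      p <- probe(mid, s)
      it <- it + 1
      if (abs(p$rate - target_rate) <= rate_tol || it >= max_iter) break
      if (p$rate > target_rate) hi <- mid else lo <- mid
    }
    if (abs(p$rate - target_rate) > rate_tol && it >= max_iter)
      stop(sprintf(
        "calibration did not converge: last I0 = %.4f nA, rate = %.2f",
        mid, p$rate))
    if (p$sd_v >= sd_range[1] && p$sd_v <= sd_range[2]) {
      return(structure(list(I0 = mid, s = s, rate = p$rate, sd_v = p$sd_v,
                            target_rate = target_rate, seed = seed,
                            outer_rounds = outer, bisections = it),
                       class = "operating_point"))
    }
    # subthreshold SD off target at the firing point: rescale and retry
    s <- s * sd_target / p$sd_v
    i0_quiet <- min(i0_quiet, mid - 0.02)
  }
  stop(sprintf(
    "calibration failed: subthreshold SD %.2f mV outside [%g, %g] mV",
    p$sd_v, sd_range[1], sd_range[2]))
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "operating point: I0 = %.4f nA, s = %.4f nA -> %.2f spikes/s, subthreshold SD %.2f mV\n",
    x$I0, x$s, x$rate, x$sd_v))
  invisible(x)
}

#' Poisson spike templates for the network task
#'
#' Each of \code{n_channels} input units fires at times drawn from a Poisson
#' point process of the given rate over the template duration.
#'
#' @param n_channels Number of input channels.
#' @param duration Template duration (ms).
#' @param rate Event rate per channel (events/s).
#' @param seed Optional integer seed.
#' @return An object of class \code{spike_template}: a list with per-channel
#'   spike times (ms).
#' @export
spike_template <- function(n_channels = 10, duration = 50, rate = 20,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- lapply(seq_len(n_channels), function(i) {
    k <- rpois(1, rate * duration / 1000)
    sort(runif(k, 0, duration))
  })
  structure(list(times = times, n_channels = n_channels,
                 duration = duration, rate = rate),
            class = "spike_template")
}

#' Base template pair for one experiment
#'
#' @param seed Integer seed; the two templates use \code{seed} and
#'   \code{seed + 1}.
#' @inheritParams spike_template
#' @return List of two \code{\link{spike_template}} objects.
#' @export
make_templates <- function(seed, n_channels = 10, duration = 50, rate = 20) {
  list(spike_template(n_channels, duration, rate, seed = seed),
       spike_template(n_channels, duration, rate, seed = seed + 1))
}

#' Jitter a spike template
#'
#' Shifts every spike time by an i.i.d. Gaussian amount.  Times leaving the
#' template window are clipped to the boundary by default (\code{mode =
#' "clip"}); \code{mode = "drop"} removes them instead.
#'
#' @param template A \code{\link{spike_template}}.
#' @param sd Jitter SD (ms).
#' @param seed Optional integer seed.
#' @param mode \code{"clip"} or \code{"drop"}.
#' @return A jittered \code{spike_template}.
#' @export
jitter_template <- function(template, sd = 5, seed = NULL,
                            mode = c("clip", "drop")) {
  stopifnot(inherits(template, "spike_template"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  dur <- template$duration
  template$times <- lapply(template$times, function(t) {
    if (length(t) == 0 || sd == 0) return(t)
    t2 <- t + rnorm(length(t), 0, sd)
    if (mode == "clip") t2 <- pmin(pmax(t2, 0), dur)
    else t2 <- t2[t2 >= 0 & t2 <= dur]
    sort(t2)
  })
  template
}
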