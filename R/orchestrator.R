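#' Experiment configuration with scale presets
#'
#' Two presets: \code{"production"} reproduces the full protocol (100 s
#' repetitions, up to 100 per frequency, 11 distances, 50 networks, 500 s
#' of liquid training) and \code{"desk"} is a scaled-down version for
#' interactive use and testing (15 log-spaced frequencies, 4 x 50 s
#' repetitions, distances {0, 25, 50} um, 10 networks, 100 s training).
#' Any field can be overridden.
#'
#' @param preset \code{"desk"} or \code{"production"}.
#' @param ... Named overrides of any configuration field.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(preset = c("desk", "production"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") list(
    distances = c(0, 25, 50),
    frequencies = pracma::logspace(0, 3, 15),
    # repetitions per frequency: the reference and cutoff region (<= ~50
    # cycle/s) carries most of the estimator variance and gets the larger
    # share of the simulation budget
    n_reps = c(rep(6L, 9), rep(3L, 6)), rep_duration = 40,
    cal_duration = 20, ap_duration = 40, iv_duration = 60,
    dt = 0.005, g_leak = 0.33, soma_diameter = 20,
    tau_noise = 5, I1_frac = 0.1, target_rate = 5,
    n_networks = 10, train_duration = 100, n_readout_splits = 100,
    seed = 1)
  else list(
    distances = seq(0, 50, 5),
    frequencies = pracma::logspace(0, 3, 46),
    n_reps = 100, rep_duration = 100,
    cal_duration = 100, ap_duration = 40, iv_duration = 100,
    dt = 0.005, g_leak = 0.33, soma_diameter = 20,
    tau_noise = 5, I1_frac = 0.1, target_rate = 5,
    n_networks = 50, train_duration = 500, n_readout_splits = 100,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ",
                            paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$preset <- preset
  if (any(cfg$distances < 0 | cfg$distances > 50))
    stop("distances must lie within the axon (0-50 um)")
  structure(cfg, class = "experiment_config")
}

.sweep_model <- function(cfg, d) {
  dens <- channel_densities(g_leak = cfg$g_leak)
  geom <- cable_geometry(soma_diameter = cfg$soma_diameter)
  bas_model(geom, dens, ais_distance = d)
}

# sine amplitude for the gain protocol: a fixed fraction of |I0|, falling
# back to the same fraction of the noise SD when the calibrated offset is
# close to zero (the weak-signal regime must stay well defined)
.sine_amplitude <- function(op, frac) {
  base <- abs(op$I0)
  if (base < 0.1 * op$s) base <- op$s
  frac * base
}

#' Gain-bandwidth sweep over AIS distances
#'
#' For each AIS distance: calibrates the operating point (5 spikes/s,
#' subthreshold SD 5-10 mV), runs the sinusoid-in-noise protocol over the
#' frequency grid (pooling spikes across repetitions), and runs a
#' noisy-only stimulation for the AP phase-plane metrics.  Reports COF,
#' power-law exponent, propagation delay, AP threshold and rapidity, and
#' input resistance per distance, plus a logistic COF(d) fit when at least
#' four distances are available.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param progress Print per-stage progress messages?
#' @return An object of class \code{sweep_result}: a list with
#'   \code{records} (one row per distance), \code{gain_curves},
#'   \code{waveforms}, \code{operating_points}, \code{logistic} (or NULL)
#'   and a \code{manifest} of seeds and timings.
#' @export
run_gain_sweep <- function(cfg = experiment_config(), progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t_start <- Sys.time()
  say("leak density in use: %g pS/um^2", cfg$g_leak)
  records <- list()
  curves <- list()
  waveforms <- list()
  ops <- list()
  manifest <- list(seed = cfg$seed, preset = cfg$preset, stages = list())

  for (di in seq_along(cfg$distances)) {
    d <- cfg$distances[di]
    t0 <- Sys.time()
    model <- .sweep_model(cfg, d)
    cal_seed <- cfg$seed + 1000L * di
    op <- calibrate_operating_point(
      model, target_rate = cfg$target_rate, tau_noise = cfg$tau_noise,
      dt = cfg$dt, duration = cfg$cal_duration, seed = cal_seed)
    ops[[as.character(d)]] <- op
    say("d = %g um: I0 = %.4f nA, s = %.4f nA (rate %.2f, SD %.1f mV)",
        d, op$I0, op$s, op$rate, op$sd_v)

    i1 <- .sine_amplitude(op, cfg$I1_frac)
    n_reps <- rep_len(cfg$n_reps, length(cfg$frequencies))
    sets <- vector("list", length(cfg$frequencies))
    for (fi in seq_along(cfg$frequencies)) {
      f <- cfg$frequencies[fi]
      reps <- vector("list", n_reps[fi])
      for (r in seq_len(n_reps[fi])) {
        st <- compose_stimulus(stimulus_config(
          I0 = op$I0, I1 = i1, f = f, s = op$s,
          tau_noise = cfg$tau_noise, dt = cfg$dt,
          duration = cfg$rep_duration,
          seed = (cfg$seed + 7L * di + 101L * fi + 13L * r) %%
            .Machine$integer.max))
        reps[[r]] <- simulate_bas(model, st, record = "none")$spikes$times
      }
      sets[[fi]] <- reps
    }
    curve <- gain_curve(cfg$frequencies, sets,
                        rep_duration = cfg$rep_duration)
    curves[[as.character(d)]] <- curve

    ap_stim <- compose_stimulus(stimulus_config(
      I0 = op$I0, I1 = 0, s = op$s, tau_noise = cfg$tau_noise,
      dt = cfg$dt, duration = cfg$ap_duration,
      seed = cfg$seed + 17L * di))
    ap_sim <- simulate_bas(model, ap_stim, record = "soma")
    wf <- extract_waveforms(ap_sim$trace, ap_sim$spikes)
    om <- onset_metrics(wf)
    waveforms[[as.character(d)]] <- wf

    try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    cof <- try_na(cutoff_frequency(curve))
    # high-frequency fits over the resolvable decay region: beyond ~3x
    # the cutoff (falling back to the top measured decade)
    fit_win <- if (is.finite(cof)) c(3 * cof, max(curve$f)) else NULL
    if (!is.null(fit_win) && sum(curve$f >= fit_win[1] & curve$gain > 0) < 3)
      fit_win <- NULL
    rec <- data.frame(
      distance = d, I0 = op$I0, s = op$s, rate = op$rate, sd_v = op$sd_v,
      cof = cof,
      alpha = try_na(powerlaw_exponent(curve, f_window = fit_win)),
      delay_ms = try_na(phase_delay(curve, f_window = fit_win)),
      v_threshold = om$v_threshold, rapidity = om$rapidity,
      r_in = input_resistance(model), n_aps = wf$n_aps)
    records[[di]] <- rec
    manifest$stages[[as.character(d)]] <- list(
      cal_seed = cal_seed, I1 = i1,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    say("d = %g um: COF %.1f cycle/s, alpha %.2f, delay %.2f ms, threshold %.1f mV, rapidity %.1f /ms",
        d, rec$cof, rec$alpha, rec$delay_ms, rec$v_threshold, rec$rapidity)
  }
  records <- do.call(rbind, records)
  logistic <- NULL
  if (length(unique(records$distance)) >= 4)
    logistic <- fit_logistic(records$distance, records$cof)
  manifest$elapsed_s <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  structure(list(records = records, gain_curves = curves,
                 waveforms = waveforms, operating_points = ops,
                 logistic = logistic, manifest = manifest),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("AIS-distance sweep:\n")
  print(x$records[, c("distance", "cof", "alpha", "delay_ms",
                      "v_threshold", "rapidity", "r_in")], row.names = FALSE)
  if (!is.null(x$logistic)) print(x$logistic)
  invisible(x)
}

#' Reduce the ball-and-stick model to eIF parameters per AIS distance
#'
#' For each distance: calibrates the operating point, runs a noisy-only
#' simulation, estimates the dynamic I-V curve and fits the eIF
#' current-voltage relation, yielding one parameter row per distance.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param operating_points Optional named list of precomputed operating
#'   points (names = distances), e.g. from \code{\link{run_gain_sweep}}.
#' @param progress Print progress messages?
#' @return Data frame with one row per distance: \code{d}, \code{tau_m},
#'   \code{E_L}, \code{V_T}, \code{Delta_T}, \code{C_m}, \code{residual}.
#' @export
run_reduction_sweep <- function(cfg = experiment_config(),
                                operating_points = NULL,
                                progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  rows <- list()
  for (di in seq_along(cfg$distances)) {
    d <- cfg$distances[di]
    model <- .sweep_model(cfg, d)
    op <- operating_points[[as.character(d)]]
    if (is.null(op))
      op <- calibrate_operating_point(
        model, target_rate = cfg$target_rate, tau_noise = cfg$tau_noise,
        dt = cfg$dt, duration = cfg$cal_duration,
        seed = cfg$seed + 1000L * di)
    st <- compose_stimulus(stimulus_config(
      I0 = op$I0, I1 = 0, s = op$s, tau_noise = cfg$tau_noise,
      dt = cfg$dt, duration = cfg$iv_duration,
      seed = cfg$seed + 23L * di))
    sim <- simulate_bas(model, st, record = "soma")
    fit <- tryCatch({
      iv <- empirical_iv(sim$trace, st$current, sim$spikes)
      fit_eif(iv)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      say("d = %g um: eIF fit FAILED (%s)", d, conditionMessage(fit))
      rows[[di]] <- data.frame(d = d, tau_m = NA, E_L = NA, V_T = NA,
                               Delta_T = NA, C_m = NA, residual = NA)
    } else {
      say("d = %g um: tau_m %.2f ms, E_L %.1f mV, V_T %.1f mV, Delta_T %.2f mV",
          d, fit$tau_m, fit$E_L, fit$V_T, fit$Delta_T)
      rows[[di]] <- data.frame(d = d, tau_m = fit$tau_m, E_L = fit$E_L,
                               V_T = fit$V_T, Delta_T = fit$Delta_T,
                               C_m = attr(fit, "C_m_iv"),
                               residual = attr(fit, "residual"))
    }
  }
  do.call(rbind, rows)
}

#' Network experiment driver
#'
#' Runs the delayed-XOR liquid-state-machine comparison across AIS
#' distances at the configured scale and reports per-network accuracies and
#' the pairwise rank-sum significance matrix.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param eif_table eIF parameters per distance (defaults to the reference
#'   reduction table).
#' @param ... Passed to \code{\link{run_xor_experiment}} (e.g.
#'   \code{delta_t_values}, or a custom \code{cfg} network configuration).
#' @return A list with \code{result} (the accuracy table), \code{summary}
#'   (mean/sd per distance) and \code{p_values}.
#' @export
run_lsm_experiment <- function(cfg = experiment_config(),
                               eif_table = eif_reference_params(), ...) {
  stopifnot(inherits(cfg, "experiment_config"))
  res <- run_xor_experiment(distances = cfg$distances,
                            eif_table = eif_table,
                            n_networks = cfg$n_networks,
                            train_duration = cfg$train_duration,
                            n_readout_splits = cfg$n_readout_splits,
                            seed = cfg$seed, ...)
  summary <- aggregate(accuracy ~ distance, data = res, FUN = mean)
  summary$sd <- aggregate(accuracy ~ distance, data = res,
                          FUN = sd)$accuracy
  list(result = res, summary = summary, p_values = xor_significance(res))
}
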