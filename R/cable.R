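#' Cable geometry of the ball-and-stick neuron
#'
#' The model consists of a single isopotential soma attached at position 0 of
#' a cylindrical axon that is discretized into \code{n_axon_compartments}
#' equal segments.  Compartment centers sit at \eqn{(i - 1/2)\Delta x} from
#' the soma, \eqn{i = 1 \ldots n}.
#'
#' @param axon_diameter Axon diameter (um).
#' @param axon_length Axon length (um).
#' @param n_axon_compartments Number of axonal compartments (>= 2).
#' @param soma_diameter Soma diameter (um); the soma is treated as a sphere.
#' @param axial_resistivity Axial resistivity (Ohm cm).
#' @param specific_capacitance Specific membrane capacitance (uF/cm^2).
#' @return An object of class \code{cable_geometry}.
#' @export
cable_geometry <- function(axon_diameter = 1, axon_length = 50,
                           n_axon_compartments = 11, soma_diameter = 20,
                           axial_resistivity = 150,
                           specific_capacitance = 0.5625) {
  vals <- c(axon_diameter = axon_diameter, axon_length = axon_length,
            n_axon_compartments = n_axon_compartments,
            soma_diameter = soma_diameter,
            axial_resistivity = axial_resistivity,
            specific_capacitance = specific_capacitance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive and finite")
  if (n_axon_compartments < 2 || n_axon_compartments != round(n_axon_compartments))
    stop("n_axon_compartments must be an integer >= 2")
  g <- as.list(vals)
  g$n_axon_compartments <- as.integer(n_axon_compartments)
  g$compartment_length <- axon_length / n_axon_compartments
  structure(g, class = "cable_geometry")
}

#' Channel conductance densities and reversal potentials
#'
#' Na and K densities are given separately for the AIS compartment and for
#' the rest of the axon (the AIS carries roughly 100-fold higher densities).
#' The leak density defaults to the printed model value of
#' \code{3.3e-5 pS/um^2}; calibrated experiments use the documented
#' alternative \code{0.33 pS/um^2}, which yields a passive membrane time
#' constant near 17 ms (see the methods vignette).
#'
#' @param gNa_ais,gK_ais AIS Na/K conductance densities (nS/um^2).
#' @param gNa_axon,gK_axon Na/K densities elsewhere along the axon (nS/um^2).
#' @param g_leak Leak conductance density (pS/um^2), applied to every
#'   compartment including the soma.
#' @param E_Na,E_K,E_leak Reversal potentials (mV).
#' @return An object of class \code{channel_densities}.
#' @export
channel_densities <- function(gNa_ais = 88, gK_ais = 17.6,
                              gNa_axon = 0.8, gK_axon = 0.16,
                              g_leak = 3.3e-5,
                              E_Na = 60, E_K = -80, E_leak = -60) {
  if (gNa_ais <= gNa_axon) stop("gNa_ais must exceed gNa_axon")
  if (gK_ais <= gK_axon) stop("gK_ais must exceed gK_axon")
  if (!(E_Na > E_leak && E_leak > E_K))
    stop("reversal potentials must satisfy E_Na > E_leak > E_K")
  if (g_leak < 0) stop("g_leak must be non-negative")
  structure(list(gNa_ais = gNa_ais, gK_ais = gK_ais, gNa_axon = gNa_axon,
                 gK_axon = gK_axon, g_leak = g_leak,
                 E_Na = E_Na, E_K = E_K, E_leak = E_leak),
            class = "channel_densities")
}

#' Voltage-gated channel kinetics parameters
#'
#' Rate-function parameters for the fast-inactivating Na current (m^3 h) and
#' the high-threshold delayed-rectifier K current (n), in the style used by
#' axo-somatic models of cortical spike initiation and backpropagation.  All
#' rates are scaled by \code{q10^((temperature - ref_temperature)/10)}.
#'
#' @param na_tha,na_qa,na_Ra,na_Rb Na activation: half-point (mV), slope
#'   (mV), forward and backward rate coefficients (1/ms/mV).
#' @param na_thi1,na_thi2,na_qi,na_Rd,na_Rg Na inactivation rate parameters.
#' @param na_thinf,na_qinf Na inactivation steady-state Boltzmann (mV).
#' @param kv_tha,kv_qa,kv_Ra,kv_Rb K activation rate parameters.
#' @param temperature,ref_temperature,q10 Temperature scaling of all rates.
#' @param vshift Global shift of the channel voltage dependence (mV).
#' @return Named numeric vector of class \code{channel_kinetics}.
#' @export
channel_kinetics <- function(na_tha = -35, na_qa = 9, na_Ra = 0.182,
                             na_Rb = 0.124, na_thi1 = -50, na_thi2 = -75,
                             na_qi = 5, na_Rd = 0.024, na_Rg = 0.0091,
                             na_thinf = -65, na_qinf = 6.2,
                             kv_tha = 25, kv_qa = 9, kv_Ra = 0.02,
                             kv_Rb = 0.002,
                             temperature = 37, ref_temperature = 23,
                             q10 = 2.3, vshift = 0) {
  k <- c(na_tha = na_tha, na_qa = na_qa, na_Ra = na_Ra, na_Rb = na_Rb,
         na_thi1 = na_thi1, na_thi2 = na_thi2, na_qi = na_qi,
         na_Rd = na_Rd, na_Rg = na_Rg, na_thinf = na_thinf,
         na_qinf = na_qinf, kv_tha = kv_tha, kv_qa = kv_qa,
         kv_Ra = kv_Ra, kv_Rb = kv_Rb,
         tadj = q10^((temperature - ref_temperature) / 10),
         vshift = vshift)
  structure(k, class = "channel_kinetics")
}

#' Build a ball-and-stick model with a relocatable AIS
#'
#' Assigns AIS-level Na/K densities to exactly the axonal compartment whose
#' center is nearest \code{ais_distance}; all other axonal compartments carry
#' the lower axonal densities, and the soma carries leak only.
#'
#' @param geometry A \code{\link{cable_geometry}}.
#' @param densities A \code{\link{channel_densities}}.
#' @param ais_distance Distance of the AIS from the soma (um), in
#'   \code{[0, axon_length]}.
#' @param kinetics A \code{\link{channel_kinetics}}.
#' @return An object of class \code{bas_model} with a per-compartment
#'   conductance table (row 1 = soma, rows 2..n+1 = axon).
#' @export
bas_model <- function(geometry = cable_geometry(),
                      densities = channel_densities(),
                      ais_distance = 25,
                      kinetics = channel_kinetics()) {
  stopifnot(inherits(geometry, "cable_geometry"),
            inherits(densities, "channel_densities"))
  if (!is.finite(ais_distance) || ais_distance < 0 ||
      ais_distance > geometry$axon_length)
    stop("ais_distance must lie within [0, ", geometry$axon_length,
         "] um (got ", ais_distance, ")")
  n <- geometry$n_axon_compartments
  dx <- geometry$compartment_length
  centers <- (seq_len(n) - 0.5) * dx
  ais_index <- which.min(abs(centers - ais_distance))

  soma_area <- pi * geometry$soma_diameter^2              # sphere, um^2
  axon_area <- pi * geometry$axon_diameter * dx           # cylinder side
  area <- c(soma_area, rep(axon_area, n))
  gna_dens <- c(0, rep(densities$gNa_axon, n))
  gk_dens <- c(0, rep(densities$gK_axon, n))
  gna_dens[1 + ais_index] <- densities$gNa_ais
  gk_dens[1 + ais_index] <- densities$gK_ais

  tab <- data.frame(
    compartment = 0:n,
    center_um = c(0, centers),
    area_um2 = area,
    C_pF = area * geometry$specific_capacitance * 0.01,
    gNa_nS = gna_dens * area,
    gK_nS = gk_dens * area,
    gL_nS = densities$g_leak * 1e-3 * area)

  # axial couplings: soma<->comp1 over half a segment, then full segments
  xarea <- pi * geometry$axon_diameter^2 / 4
  g_seg <- 1e5 * xarea / (geometry$axial_resistivity * dx)
  g_axial <- c(2 * g_seg, rep(g_seg, n - 1))

  structure(list(geometry = geometry, densities = densities,
                 kinetics = kinetics, ais_distance = ais_distance,
                 ais_index = ais_index, table = tab,
                 g_axial_nS = g_axial),
            class = "bas_model")
}

#' @export
print.bas_model <- function(x, ...) {
  g <- x$geometry
  cat("ball-and-stick model: soma +", g$n_axon_compartments,
      "axonal compartments\n")
  cat(sprintf("  axon %.3g um x %.3g um, Ra = %g Ohm cm, Cm = %g uF/cm^2\n",
              g$axon_diameter, g$axon_length, g$axial_resistivity,
              g$specific_capacitance))
  cat(sprintf("  AIS at d = %g um (compartment %d, center %.2f um)\n",
              x$ais_distance, x$ais_index,
              x$table$center_um[1 + x$ais_index]))
  cat(sprintf("  leak density %g pS/um^2\n", x$densities$g_leak))
  invisible(x)
}

#' Strip active conductances from a model
#'
#' Returns a copy of the model with all Na and K conductances set to zero,
#' leaving the passive (leak + capacitance + axial) circuit.  Used for
#' passive-limit checks against closed-form cable solutions.
#'
#' @param model A \code{\link{bas_model}}.
#' @return A passive \code{bas_model}.
#' @export
passive_model <- function(model) {
  stopifnot(inherits(model, "bas_model"))
  model$table$gNa_nS[] <- 0
  model$table$gK_nS[] <- 0
  model
}

#' Simulate the ball-and-stick model
#'
#' Integrates the spatially discretized cable equation with HH-type Na, K and
#' leak currents by a linearly implicit backward-Euler step (tridiagonal
#' solve); gating variables advance by exponential Euler on tabulated rates.
#' Somatic spikes are detected as upward crossings of
#' \code{spike_threshold} with a \code{refractory} lockout.
#'
#' @param model A \code{\link{bas_model}}.
#' @param stimulus Injected somatic current: either a numeric vector (nA)
#'   sampled at \code{dt}, or a \code{stimulus} object from
#'   \code{\link{compose_stimulus}}.
#' @param dt Integration step (ms).  Ignored (taken from the stimulus) when a
#'   \code{stimulus} object is supplied.
#' @param record \code{"none"}, \code{"soma"} or \code{"all"}.
#' @param record_stride Keep every k-th sample of the recorded voltage.
#' @param v_init Initial membrane potential (mV), gates at steady state.
#' @param spike_threshold Somatic detection level (mV).
#' @param refractory Detector lockout (ms).
#' @param theta Implicitness of the voltage step: 0.5 is Crank-Nicolson
#'   (second-order spike timing, the default), 1 is backward Euler.
#' @return A list with components \code{trace} (a \code{voltage_trace}, or
#'   \code{NULL} when \code{record = "none"}) and \code{spikes}
#'   (a \code{\link{spike_train}}, times in seconds).
#' @export
simulate_bas <- function(model, stimulus, dt = 0.005,
                         record = c("soma", "none", "all"),
                         record_stride = 1L,
                         v_init = -70, spike_threshold = 0,
                         refractory = 2, theta = 0.5) {
  stopifnot(inherits(model, "bas_model"))
  record <- match.arg(record)
  if (inherits(stimulus, "stimulus")) {
    dt <- stimulus$dt
    stimulus <- stimulus$current
  }
  if (!is.numeric(stimulus) || length(stimulus) < 1)
    stop("stimulus must be a numeric current waveform (nA)")
  tab <- model$table
  res <- .cable_simulate(tab$C_pF, tab$gNa_nS, tab$gK_nS, tab$gL_nS,
                         model$g_axial_nS,
                         model$densities$E_Na, model$densities$E_K,
                         model$densities$E_leak,
                         unclass(model$kinetics),
                         stimulus, dt, v_init,
                         spike_threshold, refractory,
                         switch(record, none = 0L, soma = 1L, all = 2L),
                         as.integer(record_stride), theta)
  duration_s <- length(stimulus) * dt / 1000
  spikes <- spike_train(res$spikes_ms / 1000, duration_s)
  trace <- NULL
  if (record == "soma")
    trace <- voltage_trace(res$v_soma, dt * record_stride)
  if (record == "all")
    trace <- voltage_trace(res$v_all[1, ], dt * record_stride,
                           v_all = res$v_all)
  list(trace = trace, spikes = spikes, v_final = res$v_final)
}

#' Somatic voltage trace
#'
#' Uniformly sampled somatic membrane potential.  Sample times are implicit:
#' sample \code{k} corresponds to \code{(k - 1) * dt} ms (use
#' \code{\link{trace_times}}).
#'
#' @param v Somatic potential samples (mV).
#' @param dt Sampling step (ms).
#' @param v_all Optional matrix of all-compartment potentials
#'   (compartments x samples).
#' @return An object of class \code{voltage_trace}.
#' @export
voltage_trace <- function(v, dt, v_all = NULL) {
  if (any(!is.finite(v))) stop("voltage trace contains non-finite values")
  structure(list(v = v, dt = dt, v_all = v_all), class = "voltage_trace")
}

#' @rdname voltage_trace
#' @param trace A \code{voltage_trace}.
#' @return \code{trace_times}: sample times in ms.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$v) - 1) * trace$dt
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage trace: %d samples, dt = %g ms (%.3f s), range [%.1f, %.1f] mV\n",
              length(x$v), x$dt, (length(x$v) - 1) * x$dt / 1000,
              min(x$v), max(x$v)))
  invisible(x)
}

#' Spike train
#'
#' @param times Spike times (seconds), strictly increasing.
#' @param duration Recording duration (seconds).
#' @return An object of class \code{spike_train} with elements \code{times},
#'   \code{duration} and mean \code{rate} (spikes/s).
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (duration <= 0) stop("duration must be positive")
  structure(list(times = times, duration = duration,
                 rate = length(times) / duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d spikes over %.3f s (%.2f spikes/s)\n",
              length(x$times), x$duration, x$rate))
  invisible(x)
}

#' Somatic input resistance
#'
#' Measures the steady-state somatic voltage deflection to a small
#' hyperpolarizing current step, around a slightly hyperpolarized holding
#' level (so that the probe is not contaminated by spontaneous spiking).
#'
#' @param model A \code{\link{bas_model}}.
#' @param probe Probe step amplitude (nA); should be small and negative.
#' @param hold Holding current (nA) applied throughout (default hyperpolarizing).
#' @param settle Settling time before each measurement window (ms).
#' @param window Averaging window (ms).
#' @param dt Integration step (ms).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(model, probe = -0.002, hold = -0.02,
                             settle = 400, window = 100, dt = 0.005) {
  if (probe == 0) stop("probe must be non-zero")
  n <- round((settle + window) / dt)
  iw <- (n - round(window / dt) + 1):n
  run <- function(i_nA) {
    sim <- simulate_bas(model, rep(i_nA, n), dt = dt, record = "soma")
    if (length(sim$spikes$times) > 0)
      stop("model spiked during the input-resistance probe; ",
           "reduce `probe` or use a more hyperpolarized `hold`")
    mean(sim$trace$v[iw])
  }
  v0 <- run(hold)
  v1 <- run(hold + probe)
  (v1 - v0) / probe  # mV / nA = MOhm
}
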