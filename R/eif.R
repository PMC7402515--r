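#' Exponential integrate-and-fire parameters
#'
#' Parameters of the eIF point neuron
#' \deqn{C_m dV/dt = g_L (E_L - V) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I}
#' with reset to \code{V_reset} and absolute refractory period \code{t_ref}
#' after the voltage exceeds the cutoff \code{V_cut}.  Exactly one of
#' \code{C_m} or \code{tau_m} may be given; the other follows from
#' \eqn{\tau_m = C_m / g_L}.
#'
#' @param tau_m Membrane time constant (ms).
#' @param E_L Effective resting potential (mV).
#' @param V_T Threshold parameter of the exponential term (mV).
#' @param Delta_T Spike-onset sharpness (mV), \code{> 0}.
#' @param g_L Leak conductance (nS); default 14.
#' @param C_m Membrane capacitance (pF); default \code{tau_m * g_L}.
#' @param V_reset Reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param V_cut Numerical spike cutoff (mV); the spike time is recorded at
#'   the cutoff crossing.
#' @return An object of class \code{eif_params}.
#' @export
eif_params <- function(tau_m = NULL, E_L, V_T, Delta_T, g_L = 14,
                       C_m = NULL, V_reset = -80, t_ref = 2, V_cut = 0) {
  if (is.null(C_m) && is.null(tau_m))
    stop("supply tau_m or C_m")
  if (is.null(C_m)) C_m <- tau_m * g_L
  if (is.null(tau_m)) tau_m <- C_m / g_L
  if (abs(tau_m - C_m / g_L) > 1e-8 * tau_m)
    stop("inconsistent tau_m, C_m, g_L (tau_m must equal C_m / g_L)")
  if (Delta_T <= 0) stop("Delta_T must be positive")
  if (V_reset >= V_T) stop("V_reset must be below V_T")
  structure(list(C_m = C_m, g_L = g_L, tau_m = tau_m, E_L = E_L,
                 V_T = V_T, Delta_T = Delta_T, V_reset = V_reset,
                 t_ref = t_ref, V_cut = V_cut),
            class = "eif_params")
}

#' @export
print.eif_params <- function(x, ...) {
  cat(sprintf(
    "eIF: tau_m = %.3g ms, E_L = %.4g mV, V_T = %.4g mV, Delta_T = %.3g mV (g_L = %g nS, C_m = %.3g pF)\n",
    x$tau_m, x$E_L, x$V_T, x$Delta_T, x$g_L, x$C_m))
  invisible(x)
}

#' Reference eIF parameter set across AIS distances
#'
#' The eIF parameters obtained by reducing the ball-and-stick model at each
#' AIS-soma distance (dynamic I-V method with g_L fixed at 14 nS), used as
#' the input parameter table of the network experiment.  Spike-onset
#' sharpness \code{Delta_T} decreases, and \code{tau_m} increases, with AIS
#' distance.
#'
#' @return Data frame with columns \code{d} (um), \code{tau_m} (ms),
#'   \code{E_L}, \code{V_T}, \code{Delta_T} (mV).
#' @export
eif_reference_params <- function() {
  data.frame(
    d = seq(0, 50, 5),
    tau_m = c(3.40, 5.05, 5.93, 6.89, 7.85, 7.60, 7.86, 7.58, 7.70,
              7.74, 7.76),
    E_L = c(-74.14, -74.04, -74.09, -74.27, -74.51, -74.39, -74.46,
            -74.36, -74.39, -74.40, -74.40),
    V_T = c(-62.34, -61.28, -60.61, -59.90, -59.14, -59.16, -58.95,
            -59.14, -59.01, -58.96, -58.89),
    Delta_T = c(4.57, 3.31, 2.66, 2.09, 1.63, 1.50, 1.29, 1.25, 1.10,
                0.98, 0.87))
}

#' Simulate an eIF neuron under an injected current
#'
#' @param params An \code{\link{eif_params}}.
#' @param stimulus Injected current: numeric vector (nA) sampled at
#'   \code{dt}, or a \code{stimulus} object.
#' @param dt Integration step (ms); taken from the stimulus object if given.
#' @param record_v Record the voltage trace?
#' @param v_init Initial voltage (mV); defaults to \code{E_L}.
#' @return List with \code{trace} (a \code{\link{voltage_trace}} or
#'   \code{NULL}) and \code{spikes} (a \code{\link{spike_train}}, seconds).
#' @export
simulate_eif <- function(params, stimulus, dt = 0.005, record_v = TRUE,
                         v_init = NULL) {
  stopifnot(inherits(params, "eif_params"))
  if (inherits(stimulus, "stimulus")) {
    dt <- stimulus$dt
    stimulus <- stimulus$current
  }
  if (is.null(v_init)) v_init <- params$E_L
  res <- .eif_simulate(params$C_m, params$g_L, params$E_L, params$V_T,
                       params$Delta_T, params$V_reset, params$t_ref,
                       params$V_cut, stimulus, dt, v_init, record_v)
  duration_s <- length(stimulus) * dt / 1000
  list(trace = if (record_v) voltage_trace(res$v, dt) else NULL,
       spikes = spike_train(res$spikes_ms / 1000, duration_s))
}

# pooled within-bin least squares for the capacitance: minimizing the
# within-bin variance of dV/dt - a*I over subthreshold bins is quadratic in
# a, so a* (and hence C = 1000/a*) has a closed form.
.estimate_cm <- function(dvdt, i_nA, bin_idx, n_bins, usable) {
  u <- which(usable)
  x <- dvdt[u]
  y <- i_nA[u]
  b <- bin_idx[u]
  cnt <- tabulate(b, n_bins)
  keep <- cnt[b] >= 50
  x <- x[keep]; y <- y[keep]; b <- b[keep]
  cnt <- tabulate(b, n_bins)
  cnt[cnt == 0] <- 1L
  # pooled within-bin covariance/variance via sufficient statistics
  sx <- tabulate_sum(b, x, n_bins) / cnt
  sy <- tabulate_sum(b, y, n_bins) / cnt
  xc <- x - sx[b]
  yc <- y - sy[b]
  a <- sum(xc * yc) / sum(yc * yc)
  if (!is.finite(a) || a <= 0)
    stop("capacitance estimate failed (non-positive slope)")
  1000 / a
}

# group sums over 1-based integer bin indices
tabulate_sum <- function(bin, x, n_bins) {
  rs <- rowsum(x, bin)
  out <- numeric(n_bins)
  out[as.integer(rownames(rs))] <- rs
  out
}

#' Dynamic (empirical) current-voltage curve
#'
#' Estimates the membrane's effective I-V relation as the voltage-binned
#' average of \eqn{dV/dt - I/C_m}, excluding samples around each spike
#' (\code{blank_pre} before to \code{blank_post} after; the default
#' post-spike blanking is 3 ms plus the refractory period).  The derivative
#' is the forward difference aligned with the current sample that drives
#' the same step, so the estimate is free of derivative-offset bias.  When
#' \code{C_m} is not supplied it is estimated by minimizing the pooled
#' within-bin variance of \eqn{dV/dt - I/C_m} over the well-populated
#' subthreshold bins, which is the standard dynamic I-V practice.
#'
#' @param trace A \code{\link{voltage_trace}} sampled at the stimulus step.
#' @param current Injected current (nA), same sampling as the trace.
#' @param spikes A \code{\link{spike_train}} detected on the trace.
#' @param C_m Membrane capacitance (pF), or \code{NULL} to estimate it.
#' @param bin_width Voltage bin width (mV).
#' @param blank_pre,blank_post Blanking window around each spike (ms).
#' @param min_count Minimum samples for a usable bin.
#' @param v_max Upper voltage limit of the analysis (mV).
#' @return A data frame of class \code{iv_curve} with columns \code{v}
#'   (bin centers), \code{f} (mV/ms), \code{count}, \code{usable}; the
#'   capacitance is stored in \code{attr(, "C_m")}.
#' @export
empirical_iv <- function(trace, current, spikes, C_m = NULL,
                         bin_width = 0.5, blank_pre = 0.1, blank_post = 5,
                         min_count = 20, v_max = -20) {
  stopifnot(inherits(trace, "voltage_trace"))
  v <- trace$v
  dt <- trace$dt
  nv <- length(v)
  # traces carry a leading t = 0 sample; sample k aligns with stimulus
  # sample k, and the final post-stimulus sample is dropped
  if (length(current) == nv - 1) {
    nv <- nv - 1L
    v <- v[seq_len(nv)]
  } else if (length(current) < nv) {
    stop("current and trace must align")
  }
  current <- current[seq_len(nv)]
  dvdt <- c((v[2:nv] - v[1:(nv - 1)]) / dt, NA)

  usable <- !is.na(dvdt) & v <= v_max
  st <- if (inherits(spikes, "spike_train")) spikes$times * 1000 else
    as.numeric(spikes) * 1000
  for (t_ms in st) {
    i1 <- max(1L, floor((t_ms - blank_pre) / dt) + 1L)
    i2 <- min(nv, ceiling((t_ms + blank_post) / dt) + 1L)
    usable[i1:i2] <- FALSE
  }
  if (!any(usable)) stop("no usable samples for the I-V estimate")

  bin_id <- floor(v / bin_width)
  bin0 <- min(bin_id[usable])
  n_bins <- max(bin_id[usable]) - bin0 + 1L
  bin_idx <- bin_id - bin0 + 1L
  if (is.null(C_m))
    C_m <- .estimate_cm(dvdt, current, bin_idx, n_bins, usable)

  f_all <- dvdt - 1000 * current / C_m  # nA/pF -> mV/ms
  u <- which(usable)
  b <- bin_idx[u]
  fb <- f_all[u]
  cnt <- tabulate(b, n_bins)
  s1 <- tabulate_sum(b, fb, n_bins)
  s2 <- tabulate_sum(b, fb * fb, n_bins)
  nonempty <- which(cnt > 0)
  mean_f <- s1[nonempty] / cnt[nonempty]
  var_f <- pmax(0, s2[nonempty] / cnt[nonempty] - mean_f^2) *
    cnt[nonempty] / pmax(1, cnt[nonempty] - 1)
  out <- data.frame(v = (nonempty + bin0 - 1 + 0.5) * bin_width,
                    f = mean_f, f_sd = sqrt(var_f),
                    count = as.integer(cnt[nonempty]))
  out$usable <- out$count >= min_count
  rownames(out) <- NULL
  if (sum(out$usable) < 5) stop("too few usable voltage bins")
  if (length(unique(out$usable)) == 1 && nrow(out) == 1)
    warning("all samples fell in a single voltage bin")
  attr(out, "C_m") <- C_m
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Fit the eIF current-voltage relation to an empirical I-V curve
#'
#' Nonlinear least squares of
#' \eqn{f(V) = (E_L - V + \Delta_T e^{(V - V_T)/\Delta_T}) / \tau_m}
#' to the usable bins of a dynamic I-V curve, with multi-start
#' initialization over \code{Delta_T}.  Bins are weighted by the square
#' root of their sample count.  By default the fit covers bins up to the
#' point where the averaged function exceeds \code{f_max} (so the exponential
#' rise is included but the far supra-threshold upstroke, where the
#' single-exponential form no longer applies, is not).
#'
#' @param iv An \code{\link{empirical_iv}} result.
#' @param f_max Upper limit on f for bins entering the fit (mV/ms).
#' @param delta_starts Multi-start values for \code{Delta_T} (mV).
#' @param g_L Leak conductance used to convert \code{tau_m} into \code{C_m}
#'   for the returned parameter object (the fit itself determines
#'   \code{tau_m}).
#' @return An \code{\link{eif_params}} with attributes \code{residual}
#'   (weighted RSS), \code{C_m_iv} (capacitance used for the I-V) and
#'   \code{n_bins}.
#' @export
fit_eif <- function(iv, f_max = 30, delta_starts = c(0.5, 1, 2, 4, 8),
                    g_L = 14) {
  stopifnot(inherits(iv, "iv_curve"))
  dat <- iv[iv$usable, c("v", "f", "count")]
  # cut above the exponential rise
  over <- which(dat$f > f_max & dat$v > dat$v[which.min(dat$f)])
  if (length(over) > 0) dat <- dat[seq_len(min(over) - 1), ]
  if (nrow(dat) < 6)
    stop("too few bins in the fit range (I-V curve must cover the ",
         "subthreshold range and part of the exponential rise)")
  w <- sqrt(dat$count)

  # linear part of the curve initializes tau_m and E_L
  lin <- dat[dat$v <= quantile(dat$v, 0.5), ]
  lf <- lm(f ~ v, data = lin, weights = sqrt(lin$count))
  tau0 <- -1 / coef(lf)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 10
  el0 <- unname(coef(lf)[1] * tau0)
  if (!is.finite(el0) || el0 < -120 || el0 > -20) el0 <- median(dat$v)
  vt0 <- dat$v[which.min(dat$f)]

  best <- NULL
  for (dT in delta_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ (E_L - v + Delta_T * exp((v - V_T) / Delta_T)) / tau_m,
        data = dat, weights = w,
        start = list(tau_m = unname(tau0), E_L = el0, V_T = vt0,
                     Delta_T = dT),
        lower = c(0.1, -120, -90, 0.05), upper = c(200, -20, 0, 30),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("eIF fit did not converge for any Delta_T start (tried: ",
         paste(delta_starts, collapse = ", "), ")")
  cf <- coef(best$fit)
  if (cf["Delta_T"] <= 0.05)
    stop("eIF fit degenerate: Delta_T at the lower bound")
  out <- eif_params(tau_m = unname(cf["tau_m"]), E_L = unname(cf["E_L"]),
                    V_T = unname(cf["V_T"]),
                    Delta_T = unname(cf["Delta_T"]), g_L = g_L)
  attr(out, "residual") <- best$rss
  attr(out, "C_m_iv") <- attr(iv, "C_m")
  attr(out, "n_bins") <- nrow(dat)
  out
}
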