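#' Spike-triggered average action-potential waveform
#'
#' Aligns somatic action potentials on the time of the first upward crossing
#' of \code{criterion} mV/ms preceding each detected spike (so onset
#' features are not blurred by peak jitter) and averages the voltage and its
#' time derivative over the window.  APs whose window would overlap a
#' neighbouring spike are skipped and counted.
#'
#' @param trace A \code{\link{voltage_trace}} (somatic potential).
#' @param spikes A \code{\link{spike_train}} detected on the same trace.
#' @param window Length-2 numeric, window around onset (ms), e.g.
#'   \code{c(-10, 5)}.
#' @param criterion Onset criterion on dV/dt (mV/ms).
#' @param search_back How far before the detected spike to search for the
#'   onset crossing (ms).
#' @return An object of class \code{ap_waveform} with the aligned time grid
#'   \code{t} (ms, 0 at onset), mean \code{v} (mV), mean \code{dvdt}
#'   (mV/ms), \code{n_aps} averaged and \code{n_skipped}.
#' @export
extract_waveforms <- function(trace, spikes, window = c(-10, 5),
                              criterion = 10, search_back = 3) {
  stopifnot(inherits(trace, "voltage_trace"),
            inherits(spikes, "spike_train"))
  st <- spikes$times * 1000  # ms
  if (length(st) == 0) stop("no spikes: cannot extract AP waveforms")
  v <- trace$v
  dt <- trace$dt
  nv <- length(v)
  dvdt <- c(NA, (v[3:nv] - v[1:(nv - 2)]) / (2 * dt), NA)
  w1 <- round(window[1] / dt)
  w2 <- round(window[2] / dt)
  nb <- round(search_back / dt)
  span_ms <- diff(window)

  sum_v <- numeric(w2 - w1 + 1)
  sum_d <- numeric(w2 - w1 + 1)
  n_ok <- 0L
  n_skip <- 0L
  for (k in seq_along(st)) {
    # overlap rule: neighbouring spikes must be clear of the window
    if ((k > 1 && st[k] - st[k - 1] < span_ms) ||
        (k < length(st) && st[k + 1] - st[k] < window[2])) {
      n_skip <- n_skip + 1L
      next
    }
    si <- round(st[k] / dt) + 1L
    lo <- max(2L, si - nb)
    seg <- dvdt[lo:si]
    cross <- which(seg[-1] >= criterion & seg[-length(seg)] < criterion)
    if (length(cross) == 0) { n_skip <- n_skip + 1L; next }
    oi <- lo + cross[length(cross)]  # last (closest) onset crossing
    i1 <- oi + w1
    i2 <- oi + w2
    if (i1 < 2 || i2 > nv - 1) { n_skip <- n_skip + 1L; next }
    sum_v <- sum_v + v[i1:i2]
    sum_d <- sum_d + dvdt[i1:i2]
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0) stop("no usable APs after overlap/onset screening")
  structure(list(t = seq(w1, w2) * dt, v = sum_v / n_ok,
                 dvdt = sum_d / n_ok, n_aps = n_ok, n_skipped = n_skip,
                 dt = dt, criterion = criterion),
            class = "ap_waveform")
}

#' @export
print.ap_waveform <- function(x, ...) {
  cat(sprintf("AP waveform: average of %d APs (%d skipped), window [%g, %g] ms, peak %.1f mV\n",
              x$n_aps, x$n_skipped, min(x$t), max(x$t), max(x$v)))
  invisible(x)
}

#' Phase-plane onset metrics of an AP waveform
#'
#' The AP onset is the first upward crossing of \code{criterion} (default
#' 10 mV/ms) in the phase plane (dV/dt versus V), restricted to the voltage
#' window of spike initiation.  The threshold potential is the voltage at
#' that crossing; the rapidity is the slope of the tangent to the
#' phase-plane trajectory there, estimated by a local linear fit of dV/dt
#' against V over a band of \code{fit_band} mV/ms around the criterion.
#'
#' @param wf An \code{\link{ap_waveform}}.
#' @param criterion Onset criterion (mV/ms).
#' @param v_window Voltage window of AP initiation (mV).
#' @param fit_band Half-width of the local tangent-fit band (mV/ms); widened
#'   automatically if it captures fewer than 3 samples.
#' @return An object of class \code{onset_metrics} with
#'   \code{v_threshold} (mV), \code{rapidity} (1/ms) and \code{onset_time}
#'   (ms within the waveform).
#' @export
onset_metrics <- function(wf, criterion = 10, v_window = c(-70, 50),
                          fit_band = 2) {
  stopifnot(inherits(wf, "ap_waveform"))
  v <- wf$v
  d <- wf$dvdt
  ok <- v >= v_window[1] & v <= v_window[2]
  cross <- which(d[-1] >= criterion & d[-length(d)] < criterion &
                   ok[-1] & ok[-length(ok)])
  if (length(cross) == 0)
    stop("subthreshold waveform: no upward crossing of ", criterion,
         " mV/ms in the initiation window")
  i <- cross[1]
  frac <- (criterion - d[i]) / (d[i + 1] - d[i])
  v_thr <- v[i] + frac * (v[i + 1] - v[i])
  t_on <- wf$t[i] + frac * (wf$t[i + 1] - wf$t[i])

  band <- fit_band
  repeat {
    sel <- which(d >= criterion - band & d <= criterion + band & ok)
    if (length(sel) > 0) {
      # keep the contiguous run of samples containing the crossing
      runs <- cumsum(c(1, diff(sel) > 1))
      sel <- sel[runs == runs[which.min(abs(sel - i))]]
    }
    if (length(sel) >= 3 || band > 50) break
    band <- band * 2
  }
  if (length(sel) < 3)
    stop("too few phase-plane samples for the tangent fit")
  rap <- unname(coef(lm(d[sel] ~ v[sel]))[2])
  structure(list(v_threshold = v_thr, rapidity = rap, onset_time = t_on,
                 criterion = criterion, fit_band = band,
                 n_fit_points = length(sel)),
            class = "onset_metrics")
}

#' @export
print.onset_metrics <- function(x, ...) {
  cat(sprintf("AP onset: threshold %.2f mV, rapidity %.2f /ms (criterion %g mV/ms)\n",
              x$v_threshold, x$rapidity, x$criterion))
  invisible(x)
}
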