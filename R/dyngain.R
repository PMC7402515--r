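#' Circular resultant (vector strength) of spike times
#'
#' Computes \eqn{r = N^{-1} \sum_k e^{j 2\pi f t_k}}, the mean complex phase
#' factor of the spike times relative to a sinusoid of frequency \code{f}
#' with phase 0 at \eqn{t = 0}.
#'
#' @param spikes A \code{\link{spike_train}} or numeric spike times (s).
#' @param f Harmonic frequency (cycle/s).
#' @return An object of class \code{phase_vector} with the complex resultant
#'   \code{r}, its \code{magnitude} and \code{angle}, the spike count
#'   \code{N} and \code{f}.
#' @export
vector_strength <- function(spikes, f) {
  t <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  if (length(t) == 0)
    stop("vector strength is undefined for an empty spike train")
  r <- mean(exp(2i * pi * f * t))
  structure(list(r = r, magnitude = Mod(r), angle = Arg(r),
                 N = length(t), f = f),
            class = "phase_vector")
}

#' @export
print.phase_vector <- function(x, ...) {
  cat(sprintf("phase vector at f = %g cycle/s: |r| = %.4f, angle = %.3f rad (N = %d)\n",
              x$f, x$magnitude, x$angle, x$N))
  invisible(x)
}

.wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi  # phases in (-pi, pi]
  y
}

#' Transfer-gain curve from per-frequency spike sets
#'
#' For each stimulation frequency the raw modulation is estimated as twice
#' the magnitude of the circular resultant of the spikes pooled across
#' repetitions; the curve is normalized by its value at \code{f = 1}
#' cycle/s.  The response phase \eqn{\Phi(f)} of
#' \eqn{r(t) = r_0 + r_1\sin(2\pi f t + \Phi)} is recovered from the
#' resultant angle as \eqn{\Phi = \pi/2 - \arg r}, wrapped to
#' \eqn{(-\pi, \pi]}.  Per-frequency error bars are the SD of the
#' per-repetition raw modulations on the normalized scale.
#'
#' @param freqs Numeric vector of stimulation frequencies (cycle/s); must
#'   include 1 for normalization.
#' @param spike_sets List parallel to \code{freqs}; each element is a list of
#'   per-repetition spike-time vectors (seconds, relative to the repetition's
#'   own stimulus onset).
#' @param r0 Baseline firing rate (spikes/s); defaults to total spikes over
#'   total time if the repetition durations are supplied.
#' @param rep_duration Duration of one repetition (s), used for \code{r0}.
#' @param debias Apply the Rayleigh-floor bias correction
#'   \eqn{2\sqrt{\max(0, |\hat r|^2 - 1/N)}} before normalizing?  For a
#'   finite spike count the raw magnitude has expectation
#'   \eqn{\sqrt{|r|^2 + 1/N}}; the correction removes this noise-floor
#'   inflation (it is negligible when \eqn{N |r|^2 \gg 1}).
#' @return A data frame of class \code{gain_curve} with columns \code{f},
#'   \code{gain_raw} (= 2|r|, uncorrected), \code{gain} (normalized, from
#'   the debiased magnitude when \code{debias}), \code{gain_sd},
#'   \code{phase} (rad), \code{n_spikes}, \code{n_reps}.
#' @export
gain_curve <- function(freqs, spike_sets, r0 = NULL, rep_duration = NULL,
                       debias = TRUE) {
  stopifnot(length(freqs) == length(spike_sets))
  if (!any(freqs == 1))
    stop("the frequency grid must include f = 1 cycle/s for normalization")
  rows <- lapply(seq_along(freqs), function(i) {
    reps <- spike_sets[[i]]
    if (inherits(reps, "spike_train")) reps <- list(reps$times)
    reps <- lapply(reps, function(x)
      if (inherits(x, "spike_train")) x$times else as.numeric(x))
    pooled <- unlist(reps)
    if (length(pooled) == 0)
      stop("no spikes at f = ", freqs[i])
    r <- mean(exp(2i * pi * freqs[i] * pooled))
    per_rep <- vapply(reps, function(t)
      if (length(t) > 0) 2 * Mod(mean(exp(2i * pi * freqs[i] * t)))
      else NA_real_, numeric(1))
    data.frame(f = freqs[i], gain_raw = 2 * Mod(r),
               gain_deb = 2 * sqrt(max(0, Mod(r)^2 - 1 / length(pooled))),
               raw_sd = if (length(reps) > 1) sd(per_rep, na.rm = TRUE)
                        else NA_real_,
               phase = .wrap_pi(pi / 2 - Arg(r)),
               n_spikes = length(pooled), n_reps = length(reps))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$f), ]
  base <- if (debias) out$gain_deb else out$gain_raw
  ref <- base[out$f == 1][1]
  if (ref <= 0)
    stop("reference modulation at f = 1 cycle/s is at the noise floor")
  out$gain <- base / ref
  out$gain_sd <- out$raw_sd / ref
  out$gain_deb <- NULL
  out$raw_sd <- NULL
  rownames(out) <- NULL
  if (is.null(r0) && !is.null(rep_duration))
    r0 <- sum(out$n_spikes) / (sum(out$n_reps) * rep_duration)
  attr(out, "r0") <- r0
  class(out) <- c("gain_curve", "data.frame")
  out
}

#' Cutoff frequency of a normalized gain curve
#'
#' The cutoff (COF) is the frequency at which the normalized gain first
#' attenuates to \code{level} (default 0.70, about -3 dB), located by
#' monotone interpolation on a log-frequency axis: a decreasing isotonic
#' regression is applied to the measured curve (a no-op for curves that are
#' already monotone, so closed-form checks are unaffected) and the first
#' downward crossing of \code{level} is linearly interpolated in log f.
#'
#' @param curve A \code{\link{gain_curve}} (or data frame with \code{f},
#'   \code{gain}).
#' @param level Attenuation level defining the cutoff.
#' @param monotone Apply the decreasing isotonic projection before locating
#'   the crossing (recommended for noisy curves).
#' @return Cutoff frequency (cycle/s).
#' @export
cutoff_frequency <- function(curve, level = 0.70, monotone = TRUE) {
  g <- curve$gain
  f <- curve$f
  o <- order(f)
  g <- g[o]; f <- f[o]
  if (monotone && length(g) > 2)
    g <- -stats::isoreg(log10(f), -g)$yf
  if (g[1] < level)
    stop("gain already below ", level, " at the lowest frequency")
  cross <- which(g[-1] < level & g[-length(g)] >= level)
  if (length(cross) == 0)
    stop("no crossing of ", level, ": COF outside measured band")
  i <- cross[1] + 1L
  lf <- log10(f)
  10^(lf[i - 1] + (level - g[i - 1]) * (lf[i] - lf[i - 1]) /
        (g[i] - g[i - 1]))
}

.top_decade <- function(f) {
  fmax <- max(f)
  f >= fmax / 10
}

#' High-frequency power-law exponent of the gain
#'
#' Fits \eqn{\log(\mathrm{gain})} against \eqn{\log f} over the fit window
#' (default: the top measured frequency decade) and returns the negated
#' slope, i.e. the exponent \eqn{\alpha} of the \eqn{1/f^\alpha} decay.
#'
#' @param curve A \code{\link{gain_curve}}.
#' @param f_window Length-2 numeric: frequency window for the fit; default
#'   is the top decade of the measured grid.
#' @return The exponent \eqn{\alpha} (dimensionless).
#' @export
powerlaw_exponent <- function(curve, f_window = NULL) {
  sel <- if (is.null(f_window)) .top_decade(curve$f)
         else curve$f >= f_window[1] & curve$f <= f_window[2]
  sel <- sel & curve$gain > 0  # debiased points at the noise floor drop out
  if (sum(sel) < 3)
    stop("need at least 3 points in the power-law fit window")
  fit <- lm(log(gain) ~ log(f), data = curve[sel, ])
  -unname(coef(fit)[2])
}

#' Propagation delay from the high-frequency phase profile
#'
#' Unwraps the response phase \eqn{\Phi(f)} and fits a straight line over
#' the fit window (default: top measured decade); the delay is
#' \eqn{\delta t = -\mathrm{slope} / 2\pi}, returned in ms.
#'
#' @param curve A \code{\link{gain_curve}}.
#' @param f_window Length-2 numeric window; default the top decade.
#' @param max_resid Largest acceptable residual of the linear fit (rad);
#'   larger residuals indicate unresolved phase wrapping.
#' @return Propagation delay (ms).
#' @export
phase_delay <- function(curve, f_window = NULL, max_resid = 1) {
  o <- order(curve$f)
  f <- curve$f[o]
  phi <- signal::unwrap(curve$phase[o])
  sel <- if (is.null(f_window)) .top_decade(f)
         else f >= f_window[1] & f <= f_window[2]
  if (sum(sel) < 2) stop("need at least 2 points in the delay fit window")
  fit <- lm(phi[sel] ~ f[sel])
  if (sum(sel) > 2 && sqrt(mean(fit$residuals^2)) > max_resid)
    stop("phase-unwrapping ambiguity: linear fit residual too large")
  -unname(coef(fit)[2]) / (2 * pi) * 1000
}

#' Logistic fit of cutoff frequency versus AIS distance
#'
#' Fits \eqn{COF(d) = a / (1 + e^{-k (d - d_0)}) + b} by nonlinear least
#' squares with multi-start initialization.
#'
#' @param d AIS distances (um), at least 4 distinct values.
#' @param cof Cutoff frequencies (cycle/s).
#' @return An object of class \code{logistic_fit} with elements \code{a},
#'   \code{k}, \code{d0}, \code{b}, \code{residual} (RSS), \code{fitted} and
#'   a \code{degenerate} flag (near-constant input).
#' @export
fit_logistic <- function(d, cof) {
  if (length(unique(d)) < 4)
    stop("need at least 4 distinct distances for the logistic fit")
  df <- data.frame(d = d, cof = cof)
  spread <- diff(range(cof))
  starts <- expand.grid(k = c(0.02, 0.05, 0.1, 0.3),
                        d0 = quantile(d, c(0.25, 0.5, 0.75), names = FALSE))
  best <- NULL
  tried <- character(0)
  for (i in seq_len(nrow(starts))) {
    st <- list(a = max(spread, 1e-3), k = starts$k[i], d0 = starts$d0[i],
               b = min(cof))
    tried <- c(tried, paste0("k=", st$k, ",d0=", signif(st$d0, 3)))
    fit <- tryCatch(
      minpack.lm::nlsLM(cof ~ a / (1 + exp(-k * (d - d0))) + b,
                        data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("logistic fit did not converge; starts tried: ",
         paste(tried, collapse = "; "))
  cf <- coef(best$fit)
  degenerate <- spread < 1e-8 * max(abs(cof)) ||
    abs(cf["a"]) < 1e-3 * max(abs(cof), 1) || abs(cf["k"]) < 1e-6
  structure(list(a = unname(cf["a"]), k = unname(cf["k"]),
                 d0 = unname(cf["d0"]), b = unname(cf["b"]),
                 residual = best$rss,
                 fitted = stats::fitted(best$fit),
                 degenerate = degenerate),
            class = "logistic_fit")
}

#' Evaluate a logistic COF(d) curve
#'
#' @param fit A \code{\link{fit_logistic}} result, or a list with
#'   \code{a, k, d0, b}.
#' @param d Distances (um).
#' @return Predicted COF values (cycle/s).
#' @export
predict_logistic <- function(fit, d) {
  fit$a / (1 + exp(-fit$k * (d - fit$d0))) + fit$b
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: a = %.4g, k = %.4g 1/um, d0 = %.4g um, b = %.4g (RSS %.3g)%s\n",
              x$a, x$k, x$d0, x$b, x$residual,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
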