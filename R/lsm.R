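#' Short-term plasticity parameters
#'
#' Tsodyks-Markram depression/facilitation: at the n-th presynaptic spike
#' the synaptic efficacy is \eqn{w_n = w_0 R_n u_n}, where the utilization
#' \eqn{u} facilitates with time constant \code{F} and the recovery
#' resource \eqn{R} recovers from depression with time constant \code{D}:
#' \deqn{u_n = U + u_{n-1} (1 - U) e^{-\Delta t/F}}
#' \deqn{R_n = 1 + (R_{n-1} - R_{n-1} u_{n-1} - 1) e^{-\Delta t/D}}
#' with \eqn{R_1 = 1}, \eqn{u_1 = U}.
#'
#' @param U Utilization of synaptic resources per spike, in (0, 1].
#' @param D Depression recovery time constant (ms).
#' @param F Facilitation time constant (ms).
#' @param w0 Base synaptic weight (nA).
#' @return An object of class \code{stp_params}.
#' @export
stp_params <- function(U, D, F, w0 = 1) {
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (D <= 0 || F <= 0) stop("D and F must be positive")
  structure(list(U = U, D = D, F = F, w0 = w0), class = "stp_params")
}

#' Fresh short-term plasticity state
#'
#' @return A list with \code{R}, \code{u} (NA before the first spike).
#' @export
stp_state <- function() list(R = NA_real_, u = NA_real_)

#' Advance the short-term plasticity state by one presynaptic spike
#'
#' @param state A state from \code{\link{stp_state}} or a previous update.
#' @param dt Inter-spike interval since the previous presynaptic spike
#'   (ms); ignored for the first spike.
#' @param p An \code{\link{stp_params}}.
#' @return List with the updated \code{state} and the effective weight
#'   \code{w = w0 R_n u_n}.
#' @export
stp_update <- function(state, dt = NA, p) {
  stopifnot(inherits(p, "stp_params"))
  if (is.na(state$R)) {
    state <- list(R = 1, u = p$U)
  } else {
    if (is.na(dt) || dt <= 0)
      stop("dt must be a positive inter-spike interval")
    u_prev <- state$u
    R_prev <- state$R
    state <- list(
      R = 1 + (R_prev * (1 - u_prev) - 1) * exp(-dt / p$D),
      u = p$U + u_prev * (1 - p$U) * exp(-dt / p$F))
  }
  list(state = state, w = p$w0 * state$R * state$u)
}

#' Network configuration of the liquid state machine
#'
#' Defaults follow the connection-parameter table of the network model:
#' 1000 excitatory and 250 inhibitory eIF neurons; every neuron receives a
#' fixed in-degree of 28 excitatory and 48 inhibitory synapses; each of the
#' 10 input channels projects to a fixed out-degree of 70 excitatory
#' targets.  Recurrent weights are Normal(J, 0.7 J) per class (negative
#' draws truncated to zero), input weights Uniform(0.5 J, 1.5 J); delays
#' are Uniform(1, 10) ms for excitatory-source and input synapses and
#' Uniform(0.1, 2) ms for inhibitory-source synapses; synaptic currents
#' decay with 3 ms (excitatory) and 2 ms (inhibitory); every neuron gets an
#' independent 20 event/s, 2 nA excitatory Poisson background.
#'
#' @param n_exc,n_inh,n_input,n_readout Population sizes.
#' @param J Named weight means (nA) for classes \code{in, EE, EI, IE, II}
#'   (first letter = source population, second = target).
#' @param degree Named degrees per class (\code{in} is an out-degree, the
#'   rest are in-degrees).
#' @param U,D,F Named short-term plasticity parameters per recurrent class.
#' @param delay_exc,delay_inh Delay ranges (ms) for excitatory-source
#'   (and input) and inhibitory-source synapses.
#' @param tau_e,tau_i Synaptic current decay constants (ms).
#' @param noise_rate,J_noise Background Poisson rate (events/s) and
#'   amplitude (nA).
#' @param dt Network integration step (ms).
#' @param equal_delay Draw all delays from \code{delay_inh} (robustness
#'   variant).
#' @param epoch Pattern/epoch duration (ms).
#' @param state_tau Liquid-state filter time constant (ms).
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(n_exc = 1000, n_inh = 250, n_input = 10,
                           n_readout = 200,
                           J = c(`in` = 8.9, EE = 1.9, EI = 6.7,
                                 IE = 6.1, II = 4.9),
                           degree = c(`in` = 70, EE = 28, EI = 28,
                                      IE = 48, II = 48),
                           U = c(EE = 0.59, EI = 0.049, IE = 0.016,
                                 II = 0.25),
                           D = c(EE = 813, EI = 399, IE = 45, II = 706),
                           F = c(EE = 1, EI = 1790, IE = 376, II = 21),
                           delay_exc = c(1, 10), delay_inh = c(0.1, 2),
                           tau_e = 3, tau_i = 2,
                           noise_rate = 20, J_noise = 2,
                           dt = 0.1, equal_delay = FALSE,
                           epoch = 50, state_tau = 20) {
  if (any(degree[c("EE", "EI")] > n_exc) ||
      any(degree[c("IE", "II")] > n_inh) || degree["in"] > n_exc)
    stop("degrees cannot exceed the source/target population size")
  if (any(c(delay_exc, delay_inh) <= 0)) stop("delays must be positive")
  structure(list(n_exc = n_exc, n_inh = n_inh, n_input = n_input,
                 n_readout = n_readout, J = J, degree = degree,
                 U = U, D = D, F = F, delay_exc = delay_exc,
                 delay_inh = delay_inh, tau_e = tau_e, tau_i = tau_i,
                 noise_rate = noise_rate, J_noise = J_noise, dt = dt,
                 equal_delay = equal_delay, epoch = epoch,
                 state_tau = state_tau),
            class = "network_config")
}

# draw `deg` presynaptic partners from `pool` for each target, no autapses
.fixed_indegree <- function(pool, targets, deg) {
  pre <- integer(length(targets) * deg)
  k <- 1L
  for (tg in targets) {
    cand <- pool[pool != tg]
    pre[k:(k + deg - 1L)] <- sample(cand, deg)
    k <- k + deg
  }
  data.frame(pre = pre, post = rep(targets, each = deg))
}

#' Build a liquid-state-machine network
#'
#' Draws the random wiring, weights, delays and readout subset.  Neurons
#' \code{1..n_exc} are excitatory, \code{n_exc+1..n_exc+n_inh} inhibitory.
#'
#' @param cfg A \code{\link{network_config}}.
#' @param seed Integer seed; the same seed reproduces the identical network.
#' @return An object of class \code{lsm_network} with the recurrent edge
#'   table, input edge table, readout neuron ids and the configuration.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  ne <- cfg$n_exc
  ni <- cfg$n_inh
  exc <- seq_len(ne)
  inh <- ne + seq_len(ni)

  classes <- list(
    EE = .fixed_indegree(exc, exc, cfg$degree[["EE"]]),
    EI = .fixed_indegree(exc, inh, cfg$degree[["EI"]]),
    IE = .fixed_indegree(inh, exc, cfg$degree[["IE"]]),
    II = .fixed_indegree(inh, inh, cfg$degree[["II"]]))
  edges <- do.call(rbind, lapply(names(classes), function(cl) {
    e <- classes[[cl]]
    n <- nrow(e)
    jm <- cfg$J[[cl]]
    w <- pmax(rnorm(n, jm, 0.7 * jm), 0)  # truncate negative draws
    dl <- if (cfg$equal_delay || substr(cl, 1, 1) == "I")
      runif(n, cfg$delay_inh[1], cfg$delay_inh[2])
    else runif(n, cfg$delay_exc[1], cfg$delay_exc[2])
    data.frame(pre = e$pre, post = e$post, class = cl, w = w,
               delay = dl, U = cfg$U[[cl]], D = cfg$D[[cl]],
               F = cfg$F[[cl]])
  }))

  j_in <- cfg$J[["in"]]
  input_edges <- do.call(rbind, lapply(seq_len(cfg$n_input), function(ch) {
    post <- sample(exc, cfg$degree[["in"]])
    dl <- if (cfg$equal_delay) runif(length(post), cfg$delay_inh[1],
                                     cfg$delay_inh[2])
          else runif(length(post), cfg$delay_exc[1], cfg$delay_exc[2])
    data.frame(channel = ch, post = post,
               w = runif(length(post), 0.5 * j_in, 1.5 * j_in),
               delay = dl)
  }))
  readout <- sort(sample(exc, cfg$n_readout))
  structure(list(cfg = cfg, edges = edges, input_edges = input_edges,
                 readout = readout, seed = seed),
            class = "lsm_network")
}

#' @export
print.lsm_network <- function(x, ...) {
  cat(sprintf(
    "LSM network: %d exc + %d inh neurons, %d recurrent edges, %d input edges, %d readout neurons (seed %d)\n",
    x$cfg$n_exc, x$cfg$n_inh, nrow(x$edges), nrow(x$input_edges),
    length(x$readout), x$seed))
  invisible(x)
}

#' Simulate the liquid for a given input spike sequence
#'
#' Integrates the eIF network with delayed, short-term-plastic synaptic
#' current pulses and per-neuron Poisson background input.  Runs are
#' reproducible given the seed.  Runaway activity (mean rate above
#' \code{max_rate}) aborts the run and is flagged with a warning.
#'
#' @param net An \code{\link{build_network}} result.
#' @param eif An \code{\link{eif_params}} shared by all neurons.
#' @param input_spikes Data frame with columns \code{channel} (1-based) and
#'   \code{time} (ms), or NULL for no input.
#' @param duration Simulated time (ms).
#' @param seed Optional seed for the background noise.
#' @param max_rate Runaway threshold on the population mean rate
#'   (spikes/s per neuron).
#' @return An object of class \code{network_spikes}: data frame with
#'   \code{neuron} (1-based id) and \code{time} (ms), with attributes
#'   \code{duration}, \code{n_neurons} and \code{runaway}.
#' @export
simulate_network <- function(net, eif, input_spikes = NULL, duration,
                             seed = NULL, max_rate = 400) {
  stopifnot(inherits(net, "lsm_network"), inherits(eif, "eif_params"))
  cfg <- net$cfg
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_exc + cfg$n_inh
  dt <- cfg$dt

  e <- net$edges[order(net$edges$pre), ]
  edge_ptr <- cumsum(c(0, tabulate(e$pre, nbins = n)))
  delay_steps <- pmax(1L, as.integer(round(e$delay / dt)))

  ie <- net$input_edges[order(net$input_edges$channel), ]
  in_ptr <- cumsum(c(0, tabulate(ie$channel, nbins = cfg$n_input)))
  in_delay <- pmax(1L, as.integer(round(ie$delay / dt)))

  if (is.null(input_spikes) || nrow(input_spikes) == 0) {
    in_t <- numeric(0)
    in_ch <- integer(0)
  } else {
    o <- order(input_spikes$time)
    in_t <- input_spikes$time[o]
    in_ch <- as.integer(input_spikes$channel[o]) - 1L
  }

  res <- .lsm_simulate(n, cfg$n_exc,
                       as.integer(edge_ptr), as.integer(e$post - 1L),
                       e$w * 1000, delay_steps, e$U, e$D, e$F,
                       as.integer(in_ptr), as.integer(ie$post - 1L),
                       ie$w * 1000, in_delay,
                       in_t, in_ch,
                       eif$C_m, eif$g_L, eif$E_L, eif$V_T, eif$Delta_T,
                       eif$V_reset, eif$t_ref, eif$V_cut,
                       cfg$tau_e, cfg$tau_i,
                       cfg$noise_rate, cfg$J_noise * 1000,
                       duration, dt, max_rate)
  if (res$runaway)
    warning("runaway network activity: mean rate exceeded ", max_rate,
            " spikes/s; run aborted early")
  out <- data.frame(neuron = res$spike_id + 1L, time = res$spike_t_ms)
  attr(out, "duration") <- duration
  attr(out, "n_neurons") <- n
  attr(out, "runaway") <- res$runaway
  class(out) <- c("network_spikes", "data.frame")
  out
}

#' Extract liquid states at epoch boundaries
#'
#' Filters each readout neuron's spike train with an exponential kernel
#' (time constant \code{tau}) and samples the filtered values at the end of
#' every epoch.
#'
#' @param spikes A \code{\link{simulate_network}} result.
#' @param readout Readout neuron ids.
#' @param duration Total simulated time (ms); defaults to the spikes'
#'   attribute.
#' @param epoch Epoch length (ms).
#' @param tau Filter time constant (ms).
#' @return Matrix (epochs x readout neurons) of nonnegative state values.
#' @export
extract_states <- function(spikes, readout, duration = NULL, epoch = 50,
                           tau = 20) {
  if (is.null(duration)) duration <- attr(spikes, "duration")
  n_ep <- floor(duration / epoch)
  ends <- seq_len(n_ep) * epoch
  decay <- exp(-epoch / tau)
  nr <- length(readout)
  keep <- spikes$neuron %in% readout & spikes$time <= ends[n_ep]
  j <- match(spikes$neuron[keep], readout)
  t <- spikes$time[keep]
  ep <- pmax(pmin(ceiling(t / epoch), n_ep), 1L)
  # within-epoch contributions, accumulated per (epoch, neuron) cell
  own <- matrix(0, n_ep, nr)
  if (length(t) > 0) {
    cell <- (j - 1L) * n_ep + ep
    agg <- rowsum(exp(-(ends[ep] - t) / tau), cell)
    own[as.integer(rownames(agg))] <- agg
  }
  states <- own
  for (k in seq_len(n_ep)[-1])
    states[k, ] <- states[k - 1L, ] * decay + own[k, ]
  states
}

#' Train linear readouts on liquid states
#'
#' Regularized linear least squares (ridge) with a 0.5 decision threshold,
#' evaluated over repeated random train/test splits; the mean test accuracy
#' is the run's performance.
#'
#' @param states Matrix (epochs x features).
#' @param labels Binary labels (0/1), one per row of \code{states}.
#' @param n_splits Number of random splits.
#' @param train_frac Fraction of epochs used for training.
#' @param lambda_rel Ridge penalty relative to the mean feature second
#'   moment.
#' @param seed Optional seed for the splits.
#' @return Mean test accuracy (fraction in [0, 1]) with the per-split
#'   accuracies in \code{attr(, "splits")}.
#' @export
train_readout <- function(states, labels, n_splits = 100,
                          train_frac = 0.8, lambda_rel = 1e-2,
                          seed = NULL) {
  if (length(unique(labels)) < 2)
    stop("need both classes present to train a readout")
  stopifnot(nrow(states) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(states)
  p <- ncol(states)
  acc <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    tr <- sample(n, round(train_frac * n))
    Xtr <- states[tr, , drop = FALSE]
    ytr <- labels[tr]
    mu <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, mu)
    yb <- mean(ytr)
    G <- crossprod(Xc)
    lam <- lambda_rel * mean(diag(G))
    beta <- solve(G + diag(lam, p), crossprod(Xc, ytr - yb))
    Xte <- sweep(states[-tr, , drop = FALSE], 2, mu)
    pred <- as.numeric(Xte %*% beta) + yb >= 0.5
    acc[s] <- mean(pred == (labels[-tr] == 1))
  }
  out <- mean(acc)
  attr(out, "splits") <- acc
  out
}

# one LSM run: jittered pattern sequence -> liquid -> states -> readout
.lsm_run <- function(net, eif, templates, n_epochs, seed,
                     n_readout_splits, jitter_sd = 5) {
  cfg <- net$cfg
  set.seed(seed)
  ids <- sample(1:2, n_epochs, replace = TRUE)
  # jitter all presentations of each template in one vectorized draw
  parts <- lapply(1:2, function(tp) {
    eps <- which(ids == tp)
    if (length(eps) == 0) return(NULL)
    tpl <- templates[[tp]]
    base_t <- unlist(tpl$times)
    base_ch <- rep(seq_along(tpl$times), lengths(tpl$times))
    ns <- length(base_t)
    if (ns == 0) return(NULL)
    t_all <- rep(base_t, times = length(eps)) +
      rnorm(ns * length(eps), 0, jitter_sd)
    t_all <- pmin(pmax(t_all, 0), tpl$duration)  # clip to the window
    data.frame(channel = rep(base_ch, times = length(eps)),
               time = t_all + rep(eps - 1L, each = ns) * cfg$epoch)
  })
  input <- do.call(rbind, parts)
  duration <- n_epochs * cfg$epoch
  spikes <- simulate_network(net, eif, input, duration)
  states <- extract_states(spikes, net$readout, duration,
                           epoch = cfg$epoch, tau = cfg$state_tau)
  labels <- as.integer(xor(ids[-1] == 2, ids[-n_epochs] == 2))
  train_readout(states[-1, , drop = FALSE], labels,
                n_splits = n_readout_splits)
}

#' Delayed-XOR experiment across AIS distances
#'
#' For each AIS distance, evaluates every network on the delayed-XOR task
#' using the eIF parameters fitted at that distance: a random sequence of
#' jittered 50 ms spike templates drives the liquid, liquid states are read
#' at each pattern end, and linear readouts are trained to report the XOR
#' of the identities of the last two patterns.  The same set of randomly
#' generated networks is reused across distances; input sequences are
#' freshly jittered per run.
#'
#' @param distances AIS distances (um) to evaluate; each must have a row in
#'   \code{eif_table}.
#' @param eif_table Data frame with columns \code{d}, \code{tau_m},
#'   \code{E_L}, \code{V_T}, \code{Delta_T} (see
#'   \code{\link{eif_reference_params}}).
#' @param n_networks Number of independently wired networks.
#' @param train_duration Liquid run length per evaluation (s).
#' @param n_readout_splits Random 80/20 splits per run.
#' @param cfg A \code{\link{network_config}}.
#' @param seed Master seed.
#' @param delta_t_values If non-NULL, runs the sharpness-only variant: the
#'   eIF row at \code{delta_t_base_d} is used for every condition and only
#'   \code{Delta_T} takes these values; \code{distances} is ignored.
#' @param delta_t_base_d Base distance for the sharpness-only variant (um).
#' @param templates_per_network One fixed template pair for the whole
#'   experiment (\code{FALSE}, the reference protocol), or a fresh pair
#'   per network (\code{TRUE}), which marginalizes the accuracy estimate
#'   over template-pair difficulty.  Within a network the same pair is
#'   always used for every condition.
#' @return An object of class \code{xor_result}: data frame with columns
#'   \code{distance} (or \code{Delta_T} value for the variant),
#'   \code{network} and \code{accuracy}.
#' @export
run_xor_experiment <- function(distances = c(0, 25, 50),
                               eif_table = eif_reference_params(),
                               n_networks = 50, train_duration = 500,
                               n_readout_splits = 100,
                               cfg = network_config(), seed = 1,
                               delta_t_values = NULL,
                               delta_t_base_d = 25,
                               templates_per_network = FALSE) {
  eif_for <- function(row)
    eif_params(tau_m = row$tau_m, E_L = row$E_L, V_T = row$V_T,
               Delta_T = row$Delta_T)
  if (is.null(delta_t_values)) {
    miss <- setdiff(distances, eif_table$d)
    if (length(miss) > 0)
      stop("missing eIF parameter rows for distances: ",
           paste(miss, collapse = ", "))
    conds <- lapply(distances, function(d)
      list(label = d, eif = eif_for(eif_table[eif_table$d == d, ])))
  } else {
    base <- eif_table[eif_table$d == delta_t_base_d, ]
    if (nrow(base) == 0)
      stop("missing eIF parameter row for the base distance")
    conds <- lapply(delta_t_values, function(dT) {
      row <- base
      row$Delta_T <- dT
      list(label = dT, eif = eif_for(row))
    })
  }
  templates <- make_templates(seed * 13 + 5)
  n_epochs <- round(train_duration * 1000 / cfg$epoch)
  rows <- list()
  for (ni in seq_len(n_networks)) {
    net <- build_network(cfg, seed = seed + 7919L * ni)
    if (templates_per_network)
      templates <- make_templates(seed * 13 + 5 + 1000L * ni)
    for (ci in seq_along(conds)) {
      run_seed <- (seed + 104729L * ni + 1299709L * ci) %% .Machine$integer.max
      acc <- .lsm_run(net, conds[[ci]]$eif, templates, n_epochs,
                      seed = run_seed, n_readout_splits = n_readout_splits)
      rows[[length(rows) + 1L]] <- data.frame(
        distance = conds[[ci]]$label, network = ni,
        accuracy = as.numeric(acc))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("xor_result", "data.frame")
  out
}

#' Pairwise rank-sum comparison of XOR accuracies
#'
#' Wilcoxon rank-sum tests between the per-network accuracy vectors of each
#' pair of conditions.
#'
#' @param result An \code{\link{run_xor_experiment}} result.
#' @param alternative Passed to \code{\link[stats]{wilcox.test}}.
#' @return Symmetric matrix of p-values.
#' @export
xor_significance <- function(result, alternative = "two.sided") {
  ds <- unique(result$distance)
  p <- matrix(NA_real_, length(ds), length(ds),
              dimnames = list(ds, ds))
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i == j) next
    p[i, j] <- wilcox.test(
      result$accuracy[result$distance == ds[i]],
      result$accuracy[result$distance == ds[j]],
      alternative = alternative, exact = FALSE)$p.value
  }
  p
}

#' @export
print.xor_result <- function(x, ...) {
  agg <- aggregate(accuracy ~ distance, data = x,
                   FUN = function(a) c(mean = mean(a), sd = sd(a)))
  cat("delayed-XOR accuracy by condition:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-8s %.1f%% +- %.1f%% (n = %d)\n",
                agg$distance[i], 100 * agg$accuracy[i, "mean"],
                100 * agg$accuracy[i, "sd"],
                sum(x$distance == agg$distance[i])))
  invisible(x)
}
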