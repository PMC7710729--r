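#' Two-state channel gating configuration
#'
#' Parameters of `N` independent two-state (closed/open) Markov channels.
#' The implied single-channel open probability is
#' `Po = k_open / (k_open + k_close)` and the unitary current at the holding
#' potential is `i_u = g (V - E_rev) / 1000` pA (pS times mV; inward
#' currents are negative).
#'
#' @param n_channels number of channels N.
#' @param k_open,k_close opening / closing rates (per second, > 0).
#' @param g_ps unitary conductance in pS.
#' @param e_rev_mv reversal potential in mV.
#' @param v_mv holding potential in mV.
#' @param rate_hz sampling rate in Hz.
#' @param duration_s recording duration in seconds.
#' @param noise_sd_pa Gaussian noise standard deviation in pA.
#' @param seed integer seed.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(n_channels, k_open, k_close, g_ps = 150,
                          e_rev_mv = 0, v_mv = -80, rate_hz = 10000,
                          duration_s = 40, noise_sd_pa = 1, seed = 1) {
  if (k_open <= 0 || k_close <= 0) stop("rates must be > 0")
  if (rate_hz <= 0) stop("sampling rate must be > 0")
  po <- k_open / (k_open + k_close)
  if (po <= 0 || po >= 1) stop("implied open probability must lie in (0, 1)")
  structure(list(n_channels = n_channels, k_open = k_open,
                 k_close = k_close, g_ps = g_ps, e_rev_mv = e_rev_mv,
                 v_mv = v_mv, rate_hz = rate_hz, duration_s = duration_s,
                 noise_sd_pa = noise_sd_pa, seed = seed, po = po),
            class = "gating_config")
}

#' Sampled current recording
#'
#' @param current_pa numeric vector of current samples in pA.
#' @param rate_hz sampling rate.
#' @param voltage_mv command voltage associated with the trace.
#' @param cm_pf optional membrane capacitance (pF, > 0).
#' @param meta list of metadata (seed, generator truth, warnings).
#' @return An object of class `current_trace` with a `time_s` accessor
#'   field.
#' @export
current_trace <- function(current_pa, rate_hz, voltage_mv = NA,
                          cm_pf = NULL, meta = list()) {
  if (!is.null(cm_pf) && cm_pf <= 0) stop("capacitance must be > 0")
  structure(list(current_pa = as.numeric(current_pa), rate_hz = rate_hz,
                 voltage_mv = voltage_mv, cm_pf = cm_pf, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples at %g kHz (%.3g s)%s\n",
              length(x$current_pa), x$rate_hz / 1000,
              length(x$current_pa) / x$rate_hz,
              if (is.na(x$voltage_mv)) "" else
                sprintf(", V = %g mV", x$voltage_mv)))
  if (length(x$meta$warnings))
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  t <- seq_along(x$current_pa) / x$rate_hz
  plot(t, x$current_pa, type = "l", xlab = "time (s)",
       ylab = "current (pA)", ...)
  invisible(x)
}

#' Simulate a stochastic single-channel gating trace
#'
#' Advances `N` independent two-state Markov channels at the sampling
#' interval `dt = 1/rate`, with per-step transition probabilities
#' `1 - exp(-k dt)`, starting from the stationary occupancy. The sampled
#' current is `open_count * i_u + noise` with
#' `i_u = g (V - E_rev) / 1000` pA. If `max(k) * dt > 0.1` the
#' discretization is too coarse for the rates and a warning is recorded in
#' the trace metadata.
#'
#' @param config a [gating_config()].
#' @return a [current_trace()]; `meta$truth` carries `n_channels`, `po`,
#'   `npo` and `i_unit_pa`.
#' @export
simulate_gating_trace <- function(config) {
  dt <- 1 / config$rate_hz
  p_co <- 1 - exp(-config$k_open * dt)
  p_oc <- 1 - exp(-config$k_close * dt)
  warns <- character()
  if (max(config$k_open, config$k_close) * dt > 0.1)
    warns <- "k*dt > 0.1: sampling interval too coarse for the gating rates"
  n <- round(config$duration_s * config$rate_hz)
  i_u <- config$g_ps * (config$v_mv - config$e_rev_mv) / 1000
  cur <- gating_trace_cpp(config$n_channels, p_co, p_oc, config$po, n, i_u,
                          config$noise_sd_pa, as.integer(config$seed))
  current_trace(cur, config$rate_hz, voltage_mv = config$v_mv,
                meta = list(seed = config$seed, warnings = warns,
                            truth = list(n_channels = config$n_channels,
                                         po = config$po,
                                         npo = config$n_channels * config$po,
                                         i_unit_pa = i_u)))
}

#' Voltage-step protocol
#'
#' The standard activation protocol: a holding pre-pulse, test steps (by
#' default -100 to +160 mV in 10 mV increments, 400 ms) and a fixed
#' repolarizing post-pulse (-100 mV, 200 ms) in which tail currents are
#' measured.
#'
#' @param test_mv test voltages (strictly increasing).
#' @param test_ms test-pulse duration (ms).
#' @param post_mv,post_ms post-pulse voltage and duration.
#' @param pre_mv,pre_ms holding pre-pulse voltage and duration.
#' @param rate_hz sampling rate.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(test_mv = seq(-100, 160, by = 10), test_ms = 400,
                          post_mv = -100, post_ms = 200, pre_mv = 0,
                          pre_ms = 20, rate_hz = 10000) {
  if (any(diff(test_mv) <= 0)) stop("test voltages must be strictly increasing")
  if (test_ms <= 0 || post_ms <= 0 || pre_ms < 0)
    stop("durations must be positive")
  structure(list(test_mv = test_mv, test_ms = test_ms, post_mv = post_mv,
                 post_ms = post_ms, pre_mv = pre_mv, pre_ms = pre_ms,
                 rate_hz = rate_hz),
            class = "step_protocol")
}

#' Simulate a whole-cell voltage-step recording
#'
#' One trace per test voltage, with an outwardly rectifying steady-state
#' conductance `G(V) = g_max / (1 + exp(-(V - v_half)/slope))`,
#' mono-exponential activation during the step, an instantaneous tail at
#' repolarization decaying mono-exponentially with `tau_deact_ms`, brief
#' capacitive artifacts at the voltage transitions and additive white
#' Gaussian noise. `g_max = 0` yields flat (noise-only) traces.
#'
#' @param g_max_ns maximal conductance (nS).
#' @param protocol a [step_protocol()].
#' @param seed integer seed.
#' @param e_rev_mv reversal potential (mV).
#' @param v_half_mv,slope_mv Boltzmann activation midpoint and slope; set
#'   `v_half_mv = NULL` for a linear ohmic conductance (`G = g_max`).
#' @param tau_act_ms activation time constant during the step.
#' @param tau_deact_ms deactivation time constant of the tail.
#' @param cm_pf membrane capacitance stored on each trace.
#' @param noise_sd_pa white-noise standard deviation.
#' @param cap_artifact_pa amplitude of the capacitive spikes (decay 0.1 ms).
#' @return list of [current_trace()] objects (one per test voltage), each
#'   carrying the generator truth (`i_ss_pa`, `i_tail_pa`, `tau_deact_ms`)
#'   in `meta$truth`.
#' @export
simulate_iv_recording <- function(g_max_ns, protocol = step_protocol(),
                                  seed = 1, e_rev_mv = 0, v_half_mv = 60,
                                  slope_mv = 25, tau_act_ms = 30,
                                  tau_deact_ms = 20, cm_pf = 15,
                                  noise_sd_pa = 5, cap_artifact_pa = 300) {
  act <- function(v) if (is.null(v_half_mv)) rep(1, length(v))
                     else 1 / (1 + exp(-(v - v_half_mv) / slope_mv))
  dt <- 1000 / protocol$rate_hz                     # ms per sample
  n_pre <- round(protocol$pre_ms / dt)
  n_test <- round(protocol$test_ms / dt)
  n_post <- round(protocol$post_ms / dt)
  set.seed(seed)
  lapply(protocol$test_mv, function(v) {
    i_pre <- g_max_ns * act(protocol$pre_mv) * (protocol$pre_mv - e_rev_mv)
    i_ss <- g_max_ns * act(v) * (v - e_rev_mv)
    i_tail0 <- g_max_ns * act(v) * (protocol$post_mv - e_rev_mv)
    i_post_ss <- g_max_ns * act(protocol$post_mv) *
      (protocol$post_mv - e_rev_mv)
    t_test <- (seq_len(n_test) - 0.5) * dt
    t_post <- (seq_len(n_post) - 0.5) * dt
    seg_pre <- rep(i_pre, n_pre)
    seg_test <- i_ss + (i_pre - i_ss) * exp(-t_test / tau_act_ms)
    seg_post <- i_post_ss + (i_tail0 - i_post_ss) * exp(-t_post / tau_deact_ms)
    cap1 <- cap_artifact_pa * sign(v - protocol$pre_mv) *
      exp(-t_test / 0.1)
    cap2 <- cap_artifact_pa * sign(protocol$post_mv - v) *
      exp(-t_post / 0.1)
    cur <- c(seg_pre, seg_test + cap1, seg_post + cap2) +
      rnorm(n_pre + n_test + n_post, 0, noise_sd_pa)
    current_trace(cur, protocol$rate_hz, voltage_mv = v, cm_pf = cm_pf,
                  meta = list(seed = seed,
                              truth = list(i_ss_pa = i_ss,
                                           i_tail_pa = i_tail0,
                                           tau_deact_ms = tau_deact_ms)))
  })
}

#' Read / write a current trace as TSV
#'
#' Two tab-separated columns with header `time_s` and `current_pA`.
#'
#' @param trace a [current_trace()].
#' @param file path.
#' @return `write_trace_tsv`: invisibly `file`; `read_trace_tsv`: a
#'   [current_trace()] (sampling rate inferred from the time column).
#' @export
write_trace_tsv <- function(trace, file) {
  df <- data.frame(time_s = (seq_along(trace$current_pa) - 1) / trace$rate_hz,
                   current_pA = trace$current_pa)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trace_tsv
#' @param voltage_mv,cm_pf annotations attached to the trace on read.
#' @export
read_trace_tsv <- function(file, voltage_mv = NA, cm_pf = NULL) {
  df <- read.table(file, sep = "\t", header = TRUE)
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop("trace TSV needs columns time_s and current_pA")
  rate <- 1 / median(diff(df$time_s))
  current_trace(df$current_pA, rate, voltage_mv = voltage_mv, cm_pf = cm_pf)
}

#' Read / write a step protocol as YAML
#' @param protocol a [step_protocol()].
#' @param file path.
#' @return the protocol (read) or the path, invisibly (write).
#' @export
write_protocol_yaml <- function(protocol, file) {
  yaml::write_yaml(unclass(protocol), file)
  invisible(file)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  step_protocol(test_mv = as.numeric(y$test_mv), test_ms = y$test_ms,
                post_mv = y$post_mv, post_ms = y$post_ms, pre_mv = y$pre_mv,
                pre_ms = y$pre_ms, rate_hz = y$rate_hz)
}
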