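#' Capacitance-normalized I-V relation from a voltage-step family
#'
#' For each test voltage, the steady-state current is the mean over the
#' final fraction (`ss_frac`, default the last 10%) of the test pulse, and
#' the instantaneous tail current is the extremum (largest absolute value)
#' within `tail_window_ms` after repolarization, after discarding a
#' `blank_ms` capacitive blanking window. Both are divided by the membrane
#' capacitance to give current densities in pA/pF.
#'
#' @param traces list of [current_trace()] objects, one per test voltage of
#'   the protocol (missing steps are reported as an error; there is no
#'   silent reindexing).
#' @param protocol the [step_protocol()] used.
#' @param cm_pf membrane capacitance; defaults to the capacitance stored on
#'   the traces (must be present and positive).
#' @param ss_frac fraction of the test pulse averaged for the steady state.
#' @param blank_ms capacitive blanking window after repolarization.
#' @param tail_window_ms window searched for the instantaneous tail.
#' @return An object of class `iv_relation`: data.frame with `voltage_mv`,
#'   `i_ss` and `i_tail` (pA/pF), plus the parameters as attributes.
#' @export
extract_step_responses <- function(traces, protocol, cm_pf = NULL,
                                   ss_frac = 0.1, blank_ms = 0.5,
                                   tail_window_ms = 5) {
  if (length(traces) != length(protocol$test_mv))
    stop("got ", length(traces), " traces for ", length(protocol$test_mv),
         " protocol voltages; missing steps must be resolved explicitly")
  dt <- 1000 / protocol$rate_hz
  n_pre <- round(protocol$pre_ms / dt)
  n_test <- round(protocol$test_ms / dt)
  rows <- lapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    cm <- cm_pf %||% tr$cm_pf
    if (is.null(cm) || !is.finite(cm) || cm <= 0)
      stop("membrane capacitance must be supplied and > 0")
    cur <- tr$current_pa
    ss_idx <- (n_pre + n_test - round(ss_frac * n_test) + 1):(n_pre + n_test)
    i_ss <- mean(cur[ss_idx])
    t0 <- n_pre + n_test                       # last test-pulse sample
    tail_idx <- (t0 + round(blank_ms / dt) + 1):(t0 + round(tail_window_ms / dt))
    tail_idx <- tail_idx[tail_idx <= length(cur)]
    if (length(tail_idx) < 1) stop("tail window empty; check protocol")
    seg <- cur[tail_idx]
    i_tail <- seg[which.max(abs(seg))]
    data.frame(voltage_mv = protocol$test_mv[k], i_ss = i_ss / cm,
               i_tail = i_tail / cm)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(ss_frac = ss_frac, blank_ms = blank_ms,
                              tail_window_ms = tail_window_ms)
  class(out) <- c("iv_relation", "data.frame")
  out
}

#' @export
plot.iv_relation <- function(x, ...) {
  plot(x$voltage_mv, x$i_ss, type = "b", pch = 16,
       xlab = "voltage (mV)", ylab = "current density (pA/pF)", ...)
  points(x$voltage_mv, x$i_tail, type = "b", pch = 1)
  abline(h = 0, v = 0, lty = 3)
  legend("topleft", c("steady state", "instantaneous tail"),
         pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Area under an I-V curve
#'
#' Trapezoidal integral of current density over voltage. For steady-state
#' curves only positive voltages are integrated by default (the outward
#' limb); tail-current curves are integrated over the full voltage range and
#' may be negative. Units: pA/pF x mV.
#'
#' @param iv an [extract_step_responses()] result.
#' @param component `"steady"` or `"tail"`.
#' @param positive_only restrict to voltages > 0; defaults to `TRUE` for the
#'   steady-state component and `FALSE` for the tail.
#' @return numeric area; errors with fewer than two voltage points in range.
#' @export
iv_auc <- function(iv, component = c("steady", "tail"),
                   positive_only = NULL) {
  component <- match.arg(component)
  if (is.null(positive_only)) positive_only <- component == "steady"
  y <- if (component == "steady") iv$i_ss else iv$i_tail
  v <- iv$voltage_mv
  if (positive_only) { y <- y[v >= 0]; v <- v[v >= 0] }
  if (length(v) < 2) stop("need at least two voltage points in range")
  pracma::trapz(v, y)
}

#' Single-channel amplitude from a Gaussian amplitude histogram
#'
#' Fits a Gaussian mixture to the distribution of sampled current
#' amplitudes; the unitary amplitude is the peak-to-peak distance between
#' adjacent component means (their median when more than two components are
#' fitted). A trace whose amplitude histogram does not resolve distinct
#' components is an error (`"components not resolvable"`).
#'
#' @param trace a [current_trace()] (or numeric vector of samples).
#' @param components number of Gaussian components (closed level + open
#'   levels; default 2).
#' @param max_fit_samples at most this many samples enter the EM fit
#'   (deterministic decimation, every k-th sample).
#' @return An object of class `single_channel_fit`: `means_pa` (sorted),
#'   `sds_pa`, `weights`, `amplitude_pa`, `baseline_pa` (largest-weight
#'   component mean) and the fitted model's log-likelihood.
#' @export
fit_amplitude_histogram <- function(trace, components = 2,
                                    max_fit_samples = 50000) {
  cur <- if (inherits(trace, "current_trace")) trace$current_pa
         else as.numeric(trace)
  if (components < 2) stop("need at least two components")
  uni <- unique(cur)
  if (length(uni) <= components) {
    # degenerate noiseless case: the levels themselves are the components
    if (length(uni) < 2) stop("components not resolvable: single-level trace")
    means <- sort(uni)
    w <- vapply(means, function(m) mean(cur == m), numeric(1))
    fit <- list(means_pa = means, sds_pa = rep(0, length(means)),
                weights = w, loglik = NA_real_)
  } else {
    idx <- seq(1, length(cur), by = max(1L, floor(length(cur) / max_fit_samples)))
    init <- unique(round(seq(1, length(idx),
                             length.out = min(2000, length(idx)))))
    mc <- tryCatch(
      Mclust(cur[idx], G = components, modelNames = "V", verbose = FALSE,
             initialization = list(subset = init)),
      error = function(e) NULL)
    if (is.null(mc))
      stop("components not resolvable: Gaussian mixture fit did not converge")
    ord <- order(mc$parameters$mean)
    fit <- list(means_pa = unname(mc$parameters$mean[ord]),
                sds_pa = unname(sqrt(mc$parameters$variance$sigmasq))[
                  if (length(mc$parameters$variance$sigmasq) > 1) ord else 1],
                weights = unname(mc$parameters$pro[ord]),
                loglik = mc$loglik)
    sep <- diff(fit$means_pa)
    sd_pairs <- fit$sds_pa[-length(fit$sds_pa)] + fit$sds_pa[-1]
    if (any(sep < sd_pairs))
      stop("components not resolvable: fitted level separation below noise")
  }
  amp <- unname(median(diff(fit$means_pa)))
  if (amp <= 0) stop("components not resolvable: non-positive amplitude")
  structure(c(fit, list(amplitude_pa = amp,
                        baseline_pa = fit$means_pa[which.max(fit$weights)])),
            class = "single_channel_fit")
}

#' @export
print.single_channel_fit <- function(x, ...) {
  cat(sprintf("Single-channel fit: %d components, unitary amplitude %.2f pA\n",
              length(x$means_pa), x$amplitude_pa))
  cat("  level means (pA):", paste(sprintf("%.2f", x$means_pa),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Channel activity NPo from a gap-free recording
#'
#' `NPo = mean(|I - baseline|) / unitary amplitude`, with the baseline taken
#' as the dominant (largest-weight) closed-level component mean. `N` is the
#' number of channels and `Po` the single-channel open probability; the
#' product is what a stationary recording identifies.
#'
#' @param trace a [current_trace()] or numeric vector.
#' @param amplitude_pa unitary amplitude (> 0), e.g. from
#'   [fit_amplitude_histogram()] on the same trace.
#' @param baseline_pa closed-level current; default 0.
#' @param voltage_mv annotation.
#' @return An object of class `npo_record`: `npo`, `mean_current_pa`,
#'   `amplitude_pa`, `voltage_mv`, `duration_s`.
#' @export
compute_npo <- function(trace, amplitude_pa, baseline_pa = 0,
                        voltage_mv = NA) {
  if (inherits(trace, "current_trace")) {
    cur <- trace$current_pa
    dur <- length(cur) / trace$rate_hz
    if (is.na(voltage_mv)) voltage_mv <- trace$voltage_mv
  } else { cur <- as.numeric(trace); dur <- NA_real_ }
  if (!is.finite(amplitude_pa) || amplitude_pa <= 0)
    stop("unitary amplitude must be > 0")
  m <- mean(abs(cur - baseline_pa))
  structure(list(npo = m / amplitude_pa, mean_current_pa = m,
                 amplitude_pa = amplitude_pa, voltage_mv = voltage_mv,
                 duration_s = dur),
            class = "npo_record")
}

#' @export
print.npo_record <- function(x, ...) {
  cat(sprintf("NPo = %.3f (mean |I| %.2f pA / unitary %.2f pA%s)\n", x$npo,
              x$mean_current_pa, x$amplitude_pa,
              if (is.na(x$voltage_mv)) "" else
                sprintf(" at %g mV", x$voltage_mv)))
  invisible(x)
}

#' Slope conductance from unitary amplitudes at negative potentials
#'
#' Ordinary least squares of unitary current (pA) on voltage (mV) over at
#' least three points (conventionally -60, -80 and -100 mV); the slope in
#' pA/mV is reported as conductance in pS (x 1000). A non-zero reversal
#' potential is absorbed by the intercept.
#'
#' @param voltages_mv voltages (>= 3 distinct values).
#' @param amplitudes_pa unitary current amplitudes at those voltages.
#' @return An object of class `conductance_fit`: `conductance_ps`,
#'   `intercept_pa`, `r_squared`, and the input points.
#' @export
slope_conductance <- function(voltages_mv, amplitudes_pa) {
  if (length(voltages_mv) < 3 || length(unique(voltages_mv)) < 2)
    stop("need >= 3 (voltage, amplitude) pairs with distinct voltages")
  if (length(voltages_mv) != length(amplitudes_pa))
    stop("voltages and amplitudes must align")
  fit <- lm(amplitudes_pa ~ voltages_mv)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((amplitudes_pa - mean(amplitudes_pa))^2)
  structure(list(conductance_ps = unname(coef(fit)[2]) * 1000,
                 intercept_pa = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 voltages_mv = voltages_mv, amplitudes_pa = amplitudes_pa),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf("Slope conductance: %.1f pS (R2 = %.4f)\n", x$conductance_ps,
              x$r_squared))
  invisible(x)
}

#' Mono-exponential deactivation fit of a tail current
#'
#' Least-squares fit of `I(t) = A exp(-t/tau) + C` to a tail segment
#' (already past any blanking window), with `tau` bounded positive.
#' Starting values come from a log-linear regression on the
#' baseline-subtracted segment.
#'
#' @param time_s sample times (s), or a [current_trace()] in which case
#'   `current_pa` is ignored.
#' @param current_pa current samples (pA).
#' @return An object of class `deactivation_fit`: `tau_ms`, `a_pa`, `c_pa`,
#'   `rss` and the fitted values.
#' @export
fit_deactivation <- function(time_s, current_pa = NULL) {
  if (inherits(time_s, "current_trace")) {
    current_pa <- time_s$current_pa
    time_s <- (seq_along(current_pa) - 1) / time_s$rate_hz
  } else if (is.list(time_s) &&
             all(c("time_s", "current_pa") %in% names(time_s))) {
    current_pa <- time_s$current_pa   # a tail_segment() result
    time_s <- time_s$time_s
  }
  if (length(time_s) < 5) stop("tail segment too short to fit")
  t0 <- time_s - time_s[1]
  c0 <- mean(tail(current_pa, max(3, length(current_pa) %/% 10)))
  resid0 <- current_pa - c0
  s <- sign(resid0[1])
  usable <- s * resid0 > 0
  if (sum(usable) < 3 || sd(current_pa) == 0)
    stop("degenerate tail segment: no exponential decay to fit")
  lf <- lm(log(s * resid0[usable]) ~ t0[usable])
  tau0 <- unname(-1 / coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t0)) / 3
  a0 <- unname(s * exp(coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(current_pa ~ A * exp(-t0 / tau) + C,
                      start = list(A = a0, tau = tau0, C = c0),
                      lower = c(-Inf, 1e-9, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("deactivation fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  structure(list(tau_ms = unname(cf["tau"]) * 1000,
                 a_pa = unname(cf["A"]), c_pa = unname(cf["C"]),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit), time_s = time_s),
            class = "deactivation_fit")
}

#' @export
print.deactivation_fit <- function(x, ...) {
  cat(sprintf("Deactivation: tau = %.2f ms (A = %.1f pA, C = %.1f pA, RSS = %.3g)\n",
              x$tau_ms, x$a_pa, x$c_pa, x$rss))
  invisible(x)
}

#' Extract the tail segment of a step-protocol trace
#'
#' @param trace a [current_trace()] covering pre-pulse, test pulse and
#'   post-pulse.
#' @param protocol the [step_protocol()].
#' @param blank_ms capacitive blanking after repolarization.
#' @return a list `time_s`, `current_pa` ready for [fit_deactivation()].
#' @export
tail_segment <- function(trace, protocol, blank_ms = 0.5) {
  dt <- 1000 / protocol$rate_hz
  t0 <- round(protocol$pre_ms / dt) + round(protocol$test_ms / dt)
  idx <- (t0 + round(blank_ms / dt) + 1):length(trace$current_pa)
  list(time_s = (idx - 1) / protocol$rate_hz,
       current_pa = trace$current_pa[idx])
}
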