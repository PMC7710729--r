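proto_fast <- step_protocol(rate_hz = 5000)

test_that("a constant 100 pA trace at 10 pF gives a 10 pA/pF steady state", {
  proto <- step_protocol(test_mv = c(0, 10), rate_hz = 1000)
  n <- round((proto$pre_ms + proto$test_ms + proto$post_ms))
  traces <- lapply(proto$test_mv, function(v)
    current_trace(rep(100, n), 1000, voltage_mv = v, cm_pf = 10))
  iv <- extract_step_responses(traces, proto)
  expect_equal(iv$i_ss, c(10, 10))
  expect_equal(iv$i_tail, c(10, 10))
})

test_that("zero or missing capacitance is rejected", {
  proto <- step_protocol(test_mv = c(0), rate_hz = 1000)
  tr <- current_trace(rep(1, 620), 1000, voltage_mv = 0)
  expect_error(extract_step_responses(list(tr), proto), "capacitance")
  expect_error(current_trace(1:10, 1000, cm_pf = -1), "capacitance")
})

test_that("missing voltage steps are an explicit error, never reindexed", {
  proto <- step_protocol(test_mv = c(0, 10, 20), rate_hz = 1000)
  tr <- current_trace(rep(1, 620), 1000, cm_pf = 5)
  expect_error(extract_step_responses(list(tr, tr), proto), "missing steps")
})

test_that("steady-state and tail levels are recovered from synthetic recordings", {
  # slow deactivation keeps the post-blanking extremum near the true
  # instantaneous level (the blanking window costs exp(-blank/tau))
  traces <- simulate_iv_recording(0.8, proto_fast, seed = 12, cm_pf = 20,
                                  noise_sd_pa = 1, tau_deact_ms = 50)
  iv <- extract_step_responses(traces, proto_fast)
  for (k in seq_along(traces)) {
    truth <- traces[[k]]$meta$truth
    if (abs(truth$i_ss_pa) > 20)
      expect_lt(abs(iv$i_ss[k] - truth$i_ss_pa / 20) /
                  abs(truth$i_ss_pa / 20), 0.02)
    if (abs(truth$i_tail_pa) > 100)
      expect_lt(abs(iv$i_tail[k] - truth$i_tail_pa / 20) /
                  abs(truth$i_tail_pa / 20), 0.02)
  }
})

test_that("AUC of simple shapes is exact and restricted to positive voltages", {
  iv <- structure(data.frame(voltage_mv = seq(-100, 160, 10),
                             i_ss = 1, i_tail = 1),
                  class = c("iv_relation", "data.frame"))
  expect_equal(iv_auc(iv, "steady"), 160)            # 1 pA/pF over 0..160
  iv$i_ss <- iv$voltage_mv
  expect_equal(iv_auc(iv, "steady"), 12800)          # trapezoid exact on linear
  iv$i_tail <- -2
  expect_equal(iv_auc(iv, "tail"), -2 * 260)         # tail uses the full range
  expect_error(iv_auc(iv[1, ], "tail"), "two voltage")
})

test_that("AUC equals an independent trapezoid oracle and is linear", {
  set.seed(31)
  v <- seq(-100, 160, 10)
  for (i in 1:10) {
    a <- rnorm(length(v)); b <- rnorm(length(v))
    iv <- structure(data.frame(voltage_mv = v, i_ss = a, i_tail = b),
                    class = c("iv_relation", "data.frame"))
    expect_equal(iv_auc(iv, "steady"), oracle_trapz(v[v >= 0], a[v >= 0]),
                 tolerance = 1e-12)
    expect_equal(iv_auc(iv, "tail"), oracle_trapz(v, b), tolerance = 1e-12)
    # linearity on a shared grid
    iv2 <- iv; iv2$i_tail <- 3 * a - 2 * b
    expect_equal(iv_auc(iv2, "tail"),
                 3 * oracle_trapz(v, a) - 2 * oracle_trapz(v, b),
                 tolerance = 1e-10)
  }
})

test_that("capacitance normalization commutes with AUC", {
  proto <- step_protocol(rate_hz = 2000)
  traces <- simulate_iv_recording(0.6, proto, seed = 9, cm_pf = 10,
                                  noise_sd_pa = 0)
  iv10 <- extract_step_responses(traces, proto, cm_pf = 10)
  iv5 <- extract_step_responses(traces, proto, cm_pf = 5)
  expect_equal(iv_auc(iv5, "steady"), 2 * iv_auc(iv10, "steady"),
               tolerance = 1e-9)
})

test_that("a noiseless two-level trace gives the exact unitary amplitude", {
  tr <- current_trace(rep(c(0, -12), each = 500), 1000)
  fit <- fit_amplitude_histogram(tr, components = 2)
  expect_equal(fit$amplitude_pa, 12)
  expect_equal(fit$baseline_pa, -12)   # equal weights: first max taken
})

test_that("single-level traces are reported as unresolvable", {
  expect_error(fit_amplitude_histogram(rep(0, 1000), 2),
               "components not resolvable")
  set.seed(2)
  expect_error(fit_amplitude_histogram(rnorm(5000, 0, 1), 2),
               "components not resolvable|converge")
})

test_that("the unitary amplitude is recovered from a simulated gating trace", {
  cfg <- gating_config(1, k_open = 12.5, k_close = 50, g_ps = 150,
                       v_mv = -80, duration_s = 20, noise_sd_pa = 1,
                       seed = 14)
  tr <- simulate_gating_trace(cfg)
  fit <- fit_amplitude_histogram(tr, components = 2)
  expect_lt(abs(fit$amplitude_pa - 12) / 12, 0.05)
  expect_lt(abs(fit$baseline_pa), 0.5)
})

test_that("NPo is mean current over unitary amplitude", {
  r <- compute_npo(rep(-10, 1000), amplitude_pa = 5)
  expect_equal(r$npo, 2)
  expect_error(compute_npo(rep(1, 10), 0), "amplitude")
  closed <- compute_npo(rnorm(10000, 0, 0.01), amplitude_pa = 12)
  expect_lt(closed$npo, 0.01)
})

test_that("NPo of a simulated N=3, Po=0.2 trace is near 0.6 and improves with duration", {
  mk <- function(dur, seed) {
    cfg <- gating_config(3, k_open = 12.5, k_close = 50, g_ps = 150,
                         v_mv = -80, duration_s = dur, noise_sd_pa = 1,
                         seed = seed)
    tr <- simulate_gating_trace(cfg)
    # three components cover >99% of samples (the all-open level is rare)
    fit <- fit_amplitude_histogram(tr, components = 3)
    compute_npo(tr, fit$amplitude_pa, fit$baseline_pa)$npo
  }
  long <- mk(40, 3)
  expect_lt(abs(long - 0.6) / 0.6, 0.10)
  short <- vapply(1:5, function(s) mk(4, s), numeric(1))
  expect_lt(abs(long - 0.6), abs(mean(short) - 0.6) + 0.05)
})

test_that("slope conductance is exact on noiseless linear input", {
  v <- c(-100, -80, -60)
  fit <- slope_conductance(v, 0.15 * v)
  expect_equal(fit$conductance_ps, 150, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # non-zero reversal potential moves the intercept, not the slope
  fit2 <- slope_conductance(v, 0.2 * (v - 10))
  expect_equal(fit2$conductance_ps, 200, tolerance = 1e-9)
  expect_error(slope_conductance(c(-80, -80, -80), c(1, 2, 3)), "distinct")
})

test_that("slope conductance is recovered from simulated single-channel traces", {
  amps <- vapply(c(-100, -80, -60), function(v) {
    cfg <- gating_config(1, k_open = 12.5, k_close = 50, g_ps = 200,
                         v_mv = v, duration_s = 15, noise_sd_pa = 1,
                         seed = 40 + v)
    fit <- fit_amplitude_histogram(simulate_gating_trace(cfg), 2)
    # signed open-level mean relative to baseline
    fit$means_pa[1] - fit$baseline_pa
  }, numeric(1))
  fit <- slope_conductance(c(-100, -80, -60), amps)
  expect_lt(abs(fit$conductance_ps - 200) / 200, 0.10)
})

test_that("deactivation fitting recovers tau exactly without noise", {
  t <- seq(0, 0.2, by = 1e-4)
  I <- 80 * exp(-t / 0.02) + 5
  fit <- fit_deactivation(t, I)
  expect_lt(abs(fit$tau_ms - 20) / 20, 1e-6)
  expect_equal(fit$a_pa, 80, tolerance = 1e-4)
  expect_equal(fit$c_pa, 5, tolerance = 1e-4)
})

test_that("tau is recovered within 5% under 5% noise (median of seeded repeats)", {
  t <- seq(0, 0.2, by = 1e-4)
  taus <- vapply(1:100, function(s) {
    set.seed(s)
    I <- -80 * exp(-t / 0.02) + rnorm(length(t), 0, 4)  # 5% of amplitude
    fit_deactivation(t, I)$tau_ms
  }, numeric(1))
  expect_lt(abs(median(taus) - 20) / 20, 0.05)
})

test_that("constant tail segments produce a degenerate-fit error", {
  t <- seq(0, 0.1, 1e-3)
  expect_error(fit_deactivation(t, rep(3, length(t))), "degenerate")
})

test_that("the configured tail time constant survives the full pipeline", {
  traces <- simulate_iv_recording(0.8, proto_fast, seed = 6, cm_pf = 15,
                                  tau_deact_ms = 20, noise_sd_pa = 1)
  seg <- tail_segment(traces[[length(traces)]], proto_fast, blank_ms = 1)
  fit <- fit_deactivation(seg$time_s, seg$current_pa)
  expect_lt(abs(fit$tau_ms - 20) / 20, 0.05)
})
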