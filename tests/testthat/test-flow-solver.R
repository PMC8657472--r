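test_that("zero input gives zero flow; constant input ramps at the kernel origin", {
  t <- seq(0, 0.05, by = 0.001)
  zero <- tibble::tibble(t = t, P = 0)
  r0 <- flow_response(zero, segment = "aorta")
  expect_true(all(r0$data$Q == 0))

  # u = 1: for small t, i(t) ~ u * fa(0) * t = 0.16 t
  const <- tibble::tibble(t = t, P = 1)
  rc <- flow_response(const, segment = "aorta", C = 1, tau = 2.5)
  i_at <- function(tt) rc$data$Q[match(tt, rc$data$t)]
  expect_equal(i_at(0.01), 0.16 * 0.01, tolerance = 1e-2)
  expect_equal(i_at(0.05), 0.16 * 0.05, tolerance = 1e-2)
})

test_that("the response is exactly linear in input amplitude and compliance", {
  w <- aortic_wave(dt = 0.004, n_periods = 2)
  r1 <- flow_response(w, C = 1, tau = 2.5)
  w3 <- w
  w3$P <- 3 * w3$P
  r3 <- flow_response(w3, segment = "aorta", C = 1, tau = 2.5)
  expect_lt(max(abs(r3$data$Q - 3 * r1$data$Q)), 1e-10 * max(abs(r3$data$Q)))

  rC <- flow_response(w, C = 2, tau = 2.5)
  expect_lt(max(abs(rC$data$Q - 2 * r1$data$Q)), 1e-10 * max(abs(rC$data$Q)))
})

test_that("trapezoid + central differences converge at second order", {
  # smooth periodic input avoids the junction kinks of the pulse wave
  mk <- function(dt) {
    t <- seq(0, 2, by = dt)
    tibble::tibble(t = t, P = 10 + 3 * sin(2 * pi * t))
  }
  sol <- function(dt) flow_response(mk(dt), segment = "aorta",
                                    C = 1, tau = 2.5)$data
  d1 <- sol(0.008); d2 <- sol(0.004); d4 <- sol(0.002)
  on2 <- function(a, b) {
    ia <- match(b$t, a$t)
    keep <- !is.na(ia) & b$t > 0.05 & b$t < 1.95
    max(abs(a$Q[ia[keep]] - b$Q[keep]))
  }
  e1 <- on2(d1, d4)
  e2 <- on2(d2, d4)
  expect_gt(e1 / e2, 3)      # ~4 for an O(dt^2) scheme
  expect_lt(e1 / e2, 6)
})

test_that("reflux detection finds sign-change intervals by interpolation", {
  t <- seq(0, 1, by = 0.001)
  sine <- tibble::tibble(t = t, Q = sin(2 * pi * t))
  iv <- detect_reflux(sine)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$t_start, 0.5, tolerance = 1e-3)
  expect_equal(iv$t_end, 1.0, tolerance = 1e-3)

  none <- detect_reflux(tibble::tibble(t = t, Q = 1 + 0 * t))
  expect_equal(nrow(none), 0)
})

test_that("hysteresis analytics recover the degenerate and elliptic references", {
  t <- seq(0, 1, by = 1e-4)
  mkresp <- function(P, Q) {
    structure(list(data = tibble::tibble(t = t, P = P, Q = Q),
                   segment = "aorta", C = 1, tau = 2.5, sign = "+",
                   dt = 1e-4, period = 1),
              class = "flow_response")
  }
  prop <- hysteresis_loop(mkresp(sin(2 * pi * t), 2 * sin(2 * pi * t)),
                          n_transient_periods = 0)
  expect_equal(prop$area, 0, tolerance = 1e-8)
  expect_equal(prop$phase_lag, 0)

  ell <- hysteresis_loop(mkresp(sin(2 * pi * t), cos(2 * pi * t)),
                         n_transient_periods = 0)
  expect_equal(abs(ell$area), pi, tolerance = 1e-3)
  expect_equal(ell$phase_lag, 0.25, tolerance = 1e-3)   # quarter-period offset

  expect_error(hysteresis_loop(mkresp(t, t), n_transient_periods = 3),
               class = "fractalflow_domain_error")
})

test_that("pulse-driven responses reproduce reflux, closed loops and positive lag", {
  for (seg in c("aorta", "arteriole")) {
    w <- if (seg == "aorta") aortic_wave() else arteriolar_wave()
    r <- flow_response(w)
    iv <- detect_reflux(r)
    expect_gt(nrow(iv), 0)
    # at least one reflux interval inside the final period
    tail_iv <- iv[iv$t_start >= max(r$data$t) - 0.8, ]
    expect_gt(nrow(tail_iv), 0)

    loop <- hysteresis_loop(r)
    expect_gt(abs(loop$area), 0)
    expect_gt(loop$phase_lag, 0)
    # closed up to the residual transient
    expect_lt(loop$closure_gap, 0.05 * diff(range(loop$data$Q)))
    expect_s3_class(autoplot(loop), "ggplot")
    expect_s3_class(autoplot(r), "ggplot")
  }
})

test_that("net modulated flow decreases with characteristic time for both segments", {
  for (seg in c("aorta", "arteriole")) {
    w <- if (seg == "aorta") aortic_wave() else arteriolar_wave()
    taus <- c(1.5, 2.5, 3.5, 5)
    net <- vapply(taus, function(tv) {
      abs(glance(flow_response(w, tau = tv))$mean_flow)
    }, numeric(1))
    expect_true(all(diff(net) < 0))
  }
  # for the aorta the positive modulation also lowers the flow peak itself
  w <- aortic_wave()
  pk <- vapply(c(1.5, 2.5, 3.5, 5), function(tv) {
    glance(flow_response(w, tau = tv))$peak_flow
  }, numeric(1))
  expect_true(all(diff(pk) < 0))
})

test_that("stable-modulation sweep finds its threshold", {
  w <- aortic_wave(dt = 0.004, n_periods = 3)
  # with a null kernel the tau -> response map is constant, so the sweep
  # stabilises at the first grid point
  const_kernel <- function(t) rep(0, length(t))
  r1 <- flow_response(w, segment = "aorta", C = 1, tau = 1,
                      kernel = const_kernel)
  r2 <- flow_response(w, segment = "aorta", C = 1, tau = 3,
                      kernel = const_kernel)
  expect_identical(r1$data$Q, r2$data$Q)

  sweep <- stable_modulation_interval(w, "aorta",
                                      tau_grid = seq(0.5, 6, by = 0.5),
                                      accuracy_pct = 5)
  expect_true(sweep$reached)
  expect_true(sweep$tau_critical %in% seq(0.5, 6, by = 0.5))
  # consecutive differences shrink as tau grows
  rd <- sweep$sweep$rel_diff_from_prev_pct[-1]
  expect_true(all(diff(rd) < 0))
  # an impossible accuracy is reported as not reached
  never <- stable_modulation_interval(w, "aorta", tau_grid = c(0.5, 1, 1.5),
                                      accuracy_pct = 1e-8)
  expect_false(never$reached)
  expect_true(is.na(never$tau_critical))
})

test_that("frequency-gain diagnostic reports both calculi without asserting equality", {
  r <- flow_response(aortic_wave())
  cons <- fao_consistency(r, n_harmonics = 2)
  expect_named(cons, c("harmonic", "omega", "input_amplitude",
                       "gain_time_domain", "gain_operator", "rel_deviation"))
  expect_true(all(is.finite(cons$rel_deviation)))
  expect_true(all(cons$gain_operator > 0))
})

test_that("glance and tidy expose the response and its summary", {
  r <- flow_response(aortic_wave(dt = 0.004, n_periods = 3))
  td <- tidy(r)
  expect_named(td, c("t", "P", "Q", "Q_deriv_part", "Q_conv_part"))
  # decomposition invariant: Q = deriv part + sign * conv part
  expect_equal(td$Q, td$Q_deriv_part + td$Q_conv_part)
  g <- glance(r)
  expect_equal(g$segment, "aorta")
  expect_gt(g$peak_to_peak, 0)
  expect_gt(g$reflux_fraction, 0)
})
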