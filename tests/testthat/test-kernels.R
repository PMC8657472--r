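test_that("aortic kernel takes its series limit at the origin and decays", {
  expect_equal(gkf_qq(0, C = 1, tau = 2.5), 0.16)
  # the small-t Taylor branch joins the closed form continuously
  t_near <- c(1e-9, 1e-6, 1e-4)
  expect_equal(gkf_qq(t_near, C = 1, tau = 2.5),
               rep(0.16, 3), tolerance = 1e-7)
  # direct evaluation of the simplified reference curve
  expect_equal(gauss_family(1, "gauss_qq"), 1 - exp(-1))
  expect_lt(gkf_qq(100, C = 1, tau = 2.5), 1e-4)
})

test_that("arteriolar kernel matches its limit, recurrence oracle and tail bound", {
  expect_equal(bkf_nef(0, C = 0.1, tau = 5), 0.004)
  # independent Bessel recurrence: I0(x) - I2(x) = 2 I1(x) / x
  for (x in c(0.5, 1, 5)) {
    t <- x * 5 / 2                      # so that 2 t / tau = x with tau = 5
    direct <- bkf_nef(t, C = 0.1, tau = 5)
    via_recurrence <- 0.1 / 25 * exp(-x) * 2 * besselI(x, 1) / x
    expect_equal(direct, via_recurrence, tolerance = 1e-12)
  }
  v <- bkf_nef(500, C = 0.1, tau = 5)
  expect_true(is.finite(v) && v > 0)
  expect_lt(v, 1e-4)
  # scaled-Bessel contract: no overflow even at extreme times
  expect_true(is.finite(bkf_nef(1e6, C = 0.1, tau = 5)))
})

test_that("Gaussian reference family evaluates with its limits and flags", {
  expect_equal(gauss_family(0, "gauss_basic"), 1)
  expect_equal(gauss_family(0, "gauss_complement"), 0)
  expect_identical(gauss_family(0, "gauss_quotient"), Inf)
  expect_equal(gauss_family(0, "gauss_qq"), 1)
  expect_equal(gauss_family(1, "gauss_complement"), 1 - exp(-1))
  expect_lt(gauss_family(50, "gauss_qq"), 1e-3)
})

test_that("kernels are positive with monotone decay", {
  t <- seq(0, 50, by = 0.05)
  fa <- gkf_qq(t, C = 1, tau = 2.5)
  far <- bkf_nef(t, C = 0.1, tau = 5)
  expect_true(all(fa > 0))
  expect_true(all(far > 0))
  expect_true(all(diff(fa[t > 0]) < 0))
  tail_idx <- t >= 5 & t <= 50        # beyond the arteriolar plateau
  expect_true(all(diff(far[tail_idx]) <= 0))
})

test_that("inflection points land at the analytic locations", {
  t_gauss <- inflection_point(function(t) gauss_family(t, "gauss_basic"),
                              0.1, 1.5)
  expect_equal(t_gauss, 1 / sqrt(2), tolerance = 1e-4)
  t_qq <- inflection_point(function(t) gauss_family(t, "gauss_qq"), 0.1, 2)
  expect_equal(t_qq, 0.898, tolerance = 1e-2)
  expect_error(inflection_point(function(t) 2 * t + 1, 0.1, 2),
               class = "fractalflow_not_found_error")
})

test_that("kernel sweeps are linear in compliance with a C-invariant inflection", {
  t <- seq(0, 6, by = 0.1)
  sw <- kernel_sweep("gkf_qq", tau = 2.5, C = c(1, 2), t = t)
  v1 <- sw$value[sw$C == 1]
  v2 <- sw$value[sw$C == 2]
  expect_identical(2 * v1, v2)                      # exactly linear in C
  # t = 0 level falls as C / tau^2 when tau grows at fixed C
  sw_tau <- kernel_sweep("bkf_nef", tau = c(2, 4), C = 0.1, t = 0)
  expect_equal(sw_tau$value, 0.1 / c(2, 4)^2)
  # compliance does not move the inflection time
  infl <- vapply(c(0.5, 1, 2), function(Cv) {
    inflection_point(function(t) gkf_qq(t, C = Cv, tau = 2.5), 0.3, 5)
  }, numeric(1))
  expect_lt(max(abs(diff(infl))), 1e-9)
})

test_that("kernel builders and sweep plotting stay consistent", {
  f <- kernel_fun("gkf_qq", C = 2, tau = 3)
  expect_equal(f(c(0, 1)), gkf_qq(c(0, 1), C = 2, tau = 3))
  expect_error(gkf_qq(1, C = 1, tau = -2), class = "fractalflow_domain_error")
  expect_error(bkf_nef(-1, C = 1, tau = 1), class = "fractalflow_domain_error")
  sw <- kernel_sweep("gkf_qq", tau = 2.5, C = 1, t = seq(0, 2, 0.5))
  expect_s3_class(plot_kernel_sweep(sw), "ggplot")
})
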