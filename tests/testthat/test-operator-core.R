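test_that("scalar fixed point solves the hypercell quadratic", {
  f_plus <- fao_solve(op_scalar(1), op_scalar(1), branch = "+")
  f_minus <- fao_solve(op_scalar(1), op_scalar(1), branch = "-")
  expect_equal(Re(fao_frequency_response(f_plus, 1)), (1 + sqrt(5)) / 2)
  expect_equal(Re(fao_frequency_response(f_minus, 1)), (1 - sqrt(5)) / 2)
})

test_that("both roots satisfy the defining equation and Vieta's relations", {
  s <- random_s_grid(10, seed = 11)
  pairs <- list(
    aorta = list(op_differential(1), op_integral(1 / 6.25)),
    arteriole = list(op_differential(0.1), op_scalar(0.02)),
    scalars = list(op_scalar(2), op_scalar(0.5))
  )
  for (pr in pairs) {
    e1 <- eval_operator(pr[[1]], s)
    e2 <- eval_operator(pr[[2]], s)
    rp <- fao_frequency_response(fao_solve(pr[[1]], pr[[2]], "+"), s)
    rm <- fao_frequency_response(fao_solve(pr[[1]], pr[[2]], "-"), s)
    # residual of T^2 - T1 T - T1 T2 = 0
    expect_lt(max(Mod(rp^2 - e1 * rp - e1 * e2)), 1e-12 * max(1, Mod(rp)^2))
    # Vieta: sum = T1, product = -T1 T2
    expect_lt(max(Mod((rp + rm) - e1) / pmax(Mod(e1), 1e-30)), 1e-10)
    expect_lt(max(Mod(rp * rm + e1 * e2) / pmax(Mod(e1 * e2), 1e-30)), 1e-10)
  }
})

test_that("closed-form segment responses match direct evaluation and limits", {
  a <- fao("aorta", C = 1, tau = 2)
  expect_equal(Re(fao_frequency_response(a, 10)), (10 + sqrt(101)) / 2,
               tolerance = 1e-12)
  # the aortic inductor pole rejects s = 0
  expect_error(fao_frequency_response(a, 0),
               class = "fractalflow_domain_error")
  # asymptotically the basic capacitive term dominates: T(s) / (C s) -> 1
  s_big <- 10^seq(3, 6)
  ratio <- Re(fao_frequency_response(a, s_big)) / (1 * s_big)
  expect_equal(ratio[length(ratio)], 1, tolerance = 1e-6)
  expect_true(all(diff(abs(ratio - 1)) < 0))

  # arteriolar response vanishes as s -> 0+ along the real axis
  ar <- fao("arteriole", C = 0.1, tau = 5)
  vals <- Mod(fao_frequency_response(ar, 10^(-(3:6))))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-3)
})

test_that("passivity: the + root has non-negative real part in the right half-plane", {
  s <- random_s_grid(40, seed = 7, sigma_frac = 0.05)
  for (kind in c("aorta", "arteriole")) {
    f <- fao(kind, C = if (kind == "aorta") 1 else 0.1,
             tau = if (kind == "aorta") 2.5 else 5)
    expect_true(all(Re(fao_frequency_response(f, s)) >= -1e-12))
  }
})

test_that("finite ladder reproduces the worked continued-fraction values", {
  one <- op_scalar(1)
  expect_equal(Re(ladder_admittance(one, one, 1, n_levels = 1)), 5 / 3)
  expect_equal(Re(ladder_admittance(one, one, 1, n_levels = 4)),
               1.618182, tolerance = 1e-6)
  # open boundary seeds from T1 alone
  expect_equal(Re(ladder_admittance(one, one, 1, n_levels = 1,
                                    boundary = "open")), 1.5)
})

test_that("grounded-ladder truncation error decreases monotonically in depth", {
  one <- op_scalar(1)
  errs <- vapply(1:10, function(n) {
    ladder_relative_error(one, one, s = 1, n_levels = n)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[1], 100 * abs(5 / 3 - (1 + sqrt(5)) / 2) / ((1 + sqrt(5)) / 2),
               tolerance = 1e-10)   # ~2.98 %
})

test_that("deep ladders converge to the closed-form root for both segments", {
  s <- random_s_grid(20, seed = 3)
  pairs <- list(
    aorta = list(op_differential(1), op_integral(1 / 6.25)),
    arteriole = list(op_differential(0.1), op_scalar(0.02))
  )
  for (pr in pairs) {
    err <- ladder_relative_error(pr[[1]], pr[[2]], s = s, n_levels = 60)
    expect_lt(max(err) / 100, 1e-8)
  }
})

test_that("ladder_sweep tabulates both routes with their disagreement", {
  tbl <- ladder_sweep(op_scalar(1), op_scalar(1), s = c(1, 2i + 0.1),
                      n_levels = 4)
  expect_named(tbl, c("s_re", "s_im", "ladder_re", "ladder_im",
                      "fixedpoint_re", "fixedpoint_im", "rel_err_pct"))
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$rel_err_pct >= 0))
})
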