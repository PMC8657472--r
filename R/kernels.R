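# vector-safe validation shared by the two parameterised kernels
check_kernel_args <- function(t, C, tau) {
  if (any(!is.finite(C) | C <= 0)) {
    abort("`C` must be positive and finite.",
          class = "fractalflow_domain_error")
  }
  if (any(!is.finite(tau) | tau <= 0)) {
    abort("`tau` must be positive and finite.",
          class = "fractalflow_domain_error")
  }
  if (any(t < 0)) {
    abort("`t` must be non-negative.", class = "fractalflow_domain_error")
  }
  invisible(NULL)
}

#' Aortic Gaussian-type convolution kernel (quadratic quotient)
#'
#' The closed-form convolution kernel of the aortic ladder's modulation
#' term,
#' \deqn{f_a(t) = C \frac{1 - e^{-2 t^2 / \tau^2}}{2 t^2},}
#' a Gaussian-type kernel with quadratic quotient. The singularity at
#' `t = 0` is removable; the limit is `C / tau^2`, and for
#' `2 t^2 / tau^2 < 1e-8` a two-term Taylor series is used to avoid
#' catastrophic cancellation.
#'
#' @param t time (s), vectorised, `t >= 0`.
#' @param C compliance (cm mmHg^-1).
#' @param tau aortic characteristic time (s).
#' @return kernel values; strictly positive and decreasing in `t`.
#' @export
#' @examples
#' gkf_qq(0, C = 1, tau = 2.5)    # C / tau^2 = 0.16
gkf_qq <- function(t, C = 1, tau = 1) {
  check_kernel_args(t, C, tau)
  n <- max(length(t), length(C), length(tau))
  t <- rep_len(t, n); C <- rep_len(C, n); tau <- rep_len(tau, n)
  x <- 2 * t^2 / tau^2
  small <- x < 1e-8
  out <- numeric(n)
  # (1 - exp(-x)) / x = 1 - x/2 + O(x^2), so fa = C/tau^2 * (1 - x/2 + ...)
  out[small] <- (C / tau^2)[small] * (1 - x[small] / 2)
  out[!small] <- C[!small] * (1 - exp(-x[!small])) / (2 * t[!small]^2)
  out
}

#' Arteriolar Bessel-type convolution kernel (negative-exponential weight)
#'
#' The closed-form convolution kernel of the arteriolar ladder's modulation
#' term,
#' \deqn{f_{ar}(t) = \frac{C e^{-2t/\tau}}{\tau^2}
#'   \left[I_0(2t/\tau) - I_2(2t/\tau)\right],}
#' with `I_n` the modified Bessel function of the first kind. The product
#' is evaluated with exponentially scaled Bessel functions
#' (`besselI(..., expon.scaled = TRUE)`), so it never overflows: for large
#' `t` it decays algebraically like `t^(-3/2)`. At `t = 0` the value is
#' `C / tau^2`.
#'
#' @inheritParams gkf_qq
#' @param tau arteriolar characteristic time (s).
#' @return kernel values; positive, finite for arbitrarily large `t`.
#' @export
#' @examples
#' bkf_nef(0, C = 0.1, tau = 5)     # C / tau^2 = 0.004
#' bkf_nef(500, C = 0.1, tau = 5)   # ~1e-6, no overflow
bkf_nef <- function(t, C = 1, tau = 1) {
  check_kernel_args(t, C, tau)
  x <- 2 * t / tau
  C / tau^2 * (besselI(x, 0, expon.scaled = TRUE) -
                 besselI(x, 2, expon.scaled = TRUE))
}

#' Reference family of Gaussian-type kernels
#'
#' Pointwise evaluation of the four dimensionless Gaussian-type reference
#' curves used to situate the aortic kernel: the basic Gaussian
#' `exp(-t^2)`, its complement `1 - exp(-t^2)`, the quotient
#' `exp(-t^2)/t^2`, and the simplified quadratic-quotient form
#' `(1 - exp(-t^2))/t^2`. Removable limits at `t = 0` are substituted
#' (1, 0 and 1 respectively); the quotient form diverges there and returns
#' `Inf` rather than raising an error.
#'
#' @param t time (s), vectorised, `t >= 0`.
#' @param which one of `"gauss_basic"`, `"gauss_complement"`,
#'   `"gauss_quotient"`, `"gauss_qq"`.
#' @return kernel values.
#' @export
#' @examples
#' gauss_family(0, "gauss_basic")   # 1
#' gauss_family(1, "gauss_qq")      # 1 - exp(-1)
gauss_family <- function(t, which = c("gauss_basic", "gauss_complement",
                                      "gauss_quotient", "gauss_qq")) {
  which <- arg_match(which)
  if (any(t < 0)) abort("`t` must be non-negative.",
                        class = "fractalflow_domain_error")
  switch(which,
    gauss_basic = exp(-t^2),
    gauss_complement = 1 - exp(-t^2),
    gauss_quotient = ifelse(t == 0, Inf, exp(-t^2) / t^2),
    gauss_qq = {
      x <- t^2
      small <- x < 1e-8
      out <- numeric(length(t))
      out[small] <- 1 - x[small] / 2
      out[!small] <- (1 - exp(-x[!small])) / x[!small]
      out
    }
  )
}

#' Build a kernel as a function of time
#'
#' @param kind `"gkf_qq"`, `"bkf_nef"`, or one of the [gauss_family()]
#'   labels (which ignore `C` and `tau`).
#' @param C,tau kernel parameters for the two parameterised kernels.
#' @return a vectorised function of `t`.
#' @export
kernel_fun <- function(kind = c("gkf_qq", "bkf_nef", "gauss_basic",
                                "gauss_complement", "gauss_quotient",
                                "gauss_qq"),
                       C = 1, tau = 1) {
  kind <- arg_match(kind)
  switch(kind,
    gkf_qq = function(t) gkf_qq(t, C = C, tau = tau),
    bkf_nef = function(t) bkf_nef(t, C = C, tau = tau),
    function(t) gauss_family(t, which = kind)
  )
}

#' Locate an inflection point by bisection on the second derivative
#'
#' Finds a zero crossing of the second derivative of `f` inside a bracket,
#' using central finite differences of step `h` and plain bisection down to
#' `tol`. The basic Gaussian inflects at `1/sqrt(2) ~ 0.71 s`; the
#' simplified quadratic-quotient kernel inflects later, near `0.90 s` —
#' the gentler decline that makes it the better model of aortic flow
#' modulation.
#'
#' @param f a function of one variable, twice differentiable on the bracket.
#' @param lower,upper bracket within which the second derivative changes
#'   sign.
#' @param tol bisection half-width at termination (s).
#' @param h finite-difference step for the second derivative.
#' @return the inflection time (s).
#' @export
#' @examples
#' inflection_point(function(t) exp(-t^2), 0.1, 1.5)   # 1/sqrt(2)
inflection_point <- function(f, lower, upper, tol = 1e-6, h = 1e-4) {
  d2 <- function(t) (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  flo <- d2(lower); fhi <- d2(upper)
  # differencing noise floor: eps * |f| / h^2; a "sign change" within it is
  # roundoff, not curvature
  fscale <- max(abs(f(lower)), abs(f(upper)), 1)
  noise <- 100 * .Machine$double.eps * fscale / h^2
  if (!is.finite(flo) || !is.finite(fhi) ||
      abs(flo) <= noise || abs(fhi) <= noise || sign(flo) == sign(fhi)) {
    abort("second derivative does not change sign in [lower, upper]; no inflection found.",
          class = "fractalflow_not_found_error")
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- d2(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Sweep a kernel over characteristic times and compliances
#'
#' Long-format evaluation of a kernel on a grid of `tau` and `C` values —
#' the numerical counterpart of the kernel-family figures. Both kernels are
#' exactly linear in `C`, so compliance only rescales the amplitude; the
#' characteristic time moves the inflection and sets the starting level
#' `C / tau^2`.
#'
#' @param kind `"gkf_qq"` or `"bkf_nef"`.
#' @param tau,C numeric vectors of parameter values.
#' @param t time grid (s).
#' @return a tibble with columns `kind`, `C`, `tau`, `t`, `value`.
#' @export
#' @examples
#' kernel_sweep("gkf_qq", tau = c(1.5, 2.5), C = 1, t = seq(0, 5, 0.5))
kernel_sweep <- function(kind = c("gkf_qq", "bkf_nef"), tau, C, t) {
  kind <- arg_match(kind)
  if (!length(tau) || !length(C) || !length(t)) {
    abort("`tau`, `C` and `t` must be non-empty.",
          class = "fractalflow_domain_error")
  }
  f <- if (kind == "gkf_qq") gkf_qq else bkf_nef
  tidyr::expand_grid(kind = kind, C = C, tau = tau, t = t) |>
    dplyr::mutate(value = f(.data$t, C = .data$C, tau = .data$tau))
}

#' Plot a kernel sweep
#'
#' @param sweep a tibble from [kernel_sweep()].
#' @return a ggplot object, one line per (C, tau) combination.
#' @export
plot_kernel_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = interaction(.data$C, .data$tau, sep = ", "))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (s)", y = "kernel value", colour = "C, tau") +
    ggplot2::theme_minimal()
}
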