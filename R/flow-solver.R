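#' Flow response of a segment to a pressure input
#'
#' Computes the flow `i(t)` driven by a pressure input `u(t)` through the
#' convolution governing equation of the fractal ladder circuit:
#' \deqn{i(t) = \frac{C}{2} \frac{du}{dt} \pm \int_0^t f(t - s)\, u(s)\, ds,}
#' where `f` is the segment's closed-form kernel ([gkf_qq()] for the aorta,
#' [bkf_nef()] for the arteriole; the kernel carries its own compliance
#' factor). The derivative is taken by central differences (one-sided at
#' the ends) and the Volterra convolution by the trapezoid rule on the
#' uniform grid. The modulation sign follows the segment convention:
#' `+` for the aorta, `-` for the arteriole.
#'
#' @param waveform a `pulse_waveform` tibble (from [sample_waveform()] or
#'   [read_waveform_csv()]) or any data frame with uniform-grid columns
#'   `t`, `P`.
#' @param segment `"aorta"` or `"arteriole"`; defaults to the segment the
#'   waveform was generated for, if any.
#' @param C compliance (cm mmHg^-1); defaults to 1 (aorta) or 0.1
#'   (arteriole), the representative values used throughout.
#' @param tau characteristic time (s); defaults to 2.5 (ascending aorta) or
#'   5 (arm arteriole).
#' @param sign modulation sign, `"+"` or `"-"`; default per segment.
#' @param kernel optional kernel function of `t` overriding the segment
#'   default (must carry its own amplitude factor).
#' @return an object of class `flow_response` holding a tibble `data` with
#'   columns `t`, `P`, `Q`, `Q_deriv_part`, `Q_conv_part` and the run
#'   parameters. `Q` is in model flow units (mmHg cm s^-1).
#' @export
#' @examples
#' w <- sample_waveform(pulse_params("aorta"), dt = 0.004, n_periods = 3)
#' resp <- flow_response(w)
#' glance(resp)
flow_response <- function(waveform, segment = NULL, C = NULL, tau = NULL,
                          sign = NULL, kernel = NULL) {
  stopifnot(is.data.frame(waveform))
  if (!all(c("t", "P") %in% names(waveform))) {
    abort("`waveform` must have columns `t` and `P`.",
          class = "fractalflow_domain_error")
  }
  pars <- attr(waveform, "params")
  segment <- segment %||% (if (!is.null(pars)) pars$segment else NULL)
  if (is.null(segment)) {
    abort("`segment` must be given when the waveform does not carry one.",
          class = "fractalflow_domain_error")
  }
  segment <- match.arg(segment, c("aorta", "arteriole"))
  C <- C %||% if (segment == "aorta") 1 else 0.1
  tau <- tau %||% if (segment == "aorta") 2.5 else 5
  sign <- sign %||% if (segment == "aorta") "+" else "-"
  sign <- match.arg(sign, c("+", "-"))
  check_positive(C, "C")
  check_positive(tau, "tau")

  t <- waveform$t
  u <- waveform$P
  dt <- check_uniform_grid(t)
  n <- length(t)
  if (n < 3L) abort("waveform too short.", class = "fractalflow_domain_error")

  kfun <- kernel %||% kernel_fun(
    if (segment == "aorta") "gkf_qq" else "bkf_nef", C = C, tau = tau)
  kv <- kfun(t - t[1])

  dudt <- c((u[2] - u[1]) / dt,
            (u[3:n] - u[1:(n - 2)]) / (2 * dt),
            (u[n] - u[n - 1]) / dt)

  conv <- numeric(n)
  for (m in 2:n) {
    conv[m] <- dt * (sum(kv[m:1] * u[1:m]) -
                       0.5 * (kv[m] * u[1] + kv[1] * u[m]))
  }

  sgn <- if (sign == "+") 1 else -1
  deriv_part <- C / 2 * dudt
  data <- tibble(
    t = t, P = u,
    Q = deriv_part + sgn * conv,
    Q_deriv_part = deriv_part,
    Q_conv_part = conv
  )
  structure(
    list(data = data, segment = segment, C = C, tau = tau, sign = sign,
         dt = dt,
         period = if (!is.null(pars)) pars$t0 else NA_real_),
    class = "flow_response"
  )
}

#' @export
print.flow_response <- function(x, ...) {
  cat(sprintf(
    "<flow_response> %s, C = %g, tau = %g s, sign %s, %d samples (dt = %g s)\n",
    x$segment, x$C, x$tau, x$sign, nrow(x$data), x$dt))
  print(head(x$data, 4))
  invisible(x)
}

#' @export
tidy.flow_response <- function(x, ...) x$data

# one-row summary over the final period: extremes, peak-to-peak, the net
# (period-mean) flow — the quantity that shrinks as the characteristic time
# grows — and the fraction of the period spent in reflux
#' @export
glance.flow_response <- function(x, ...) {
  d <- last_period(x)
  tibble(
    segment = x$segment, C = x$C, tau = x$tau, sign = x$sign, dt = x$dt,
    n = nrow(x$data),
    peak_flow = max(d$Q),
    min_flow = min(d$Q),
    peak_to_peak = diff(range(d$Q)),
    mean_flow = mean(d$Q),
    reflux_fraction = mean(d$Q < 0)
  )
}

#' @export
autoplot.flow_response <- function(object, ...) {
  d <- object$data |>
    tidyr::pivot_longer(c("P", "Q"), names_to = "signal") |>
    dplyr::mutate(signal = dplyr::recode(.data$signal,
                                         P = "pressure (mmHg)",
                                         Q = "flow (model units)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "t (s)", y = NULL) +
    ggplot2::theme_minimal()
}

# samples of the final full period (falls back to the whole record when the
# period is unknown or the record is shorter than one period)
last_period <- function(resp, period = NULL) {
  period <- period %||% resp$period
  d <- resp$data
  if (is.null(period) || is.na(period)) return(d)
  t_end <- d$t[nrow(d)]
  if (t_end < period) return(d)
  d[d$t >= t_end - period - 1e-12, , drop = FALSE]
}

#' Detect reflux (negative-flow) intervals
#'
#' Returns the maximal intervals on which the flow is negative — the
#' back-flow episodes that accompany the reflected pressure component.
#' Interval endpoints are located by linear interpolation of the sign
#' changes of `Q`.
#'
#' @param resp a [flow_response()] object, or a data frame with columns
#'   `t` and `Q`.
#' @return a tibble with columns `t_start`, `t_end`, `duration`; zero rows
#'   when the flow never goes negative.
#' @export
detect_reflux <- function(resp) {
  d <- if (inherits(resp, "flow_response")) resp$data else resp
  stopifnot(all(c("t", "Q") %in% names(d)))
  t <- d$t; q <- d$Q
  neg <- q < 0
  if (!any(neg)) {
    return(tibble(t_start = double(), t_end = double(), duration = double()))
  }
  cross <- function(i) t[i] + (0 - q[i]) * (t[i + 1] - t[i]) / (q[i + 1] - q[i])
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- purrr::map_dfr(which(runs$values), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    t_start <- if (i0 == 1) t[1] else cross(i0 - 1)
    t_end <- if (i1 == length(t)) t[length(t)] else cross(i1)
    tibble(t_start = t_start, t_end = t_end)
  })
  dplyr::mutate(out, duration = .data$t_end - .data$t_start)
}

#' Pressure-flow hysteresis loop over one period
#'
#' Pairs the input pressure with the output flow over the final simulated
#' period (after discarding transient periods) and quantifies the
#' time-delayed modulation: the signed enclosed area (shoelace formula)
#' and the peak phase lag — the circular distance between the flow peak
#' and the pressure peak within the period, in seconds.
#'
#' @param resp a [flow_response()] object.
#' @param period cardiac period (s); defaults to the waveform's.
#' @param n_transient_periods periods that must precede the analysed one.
#' @return an object of class `hysteresis_loop` with the loop samples, the
#'   signed `area`, the `phase_lag` (s), and the `closure_gap` (flow
#'   mismatch between the loop ends, a transient-decay measure).
#' @export
hysteresis_loop <- function(resp, period = NULL, n_transient_periods = 2) {
  stopifnot(inherits(resp, "flow_response"))
  period <- period %||% resp$period
  if (is.null(period) || is.na(period)) {
    abort("`period` must be supplied for waveforms without pulse parameters.",
          class = "fractalflow_domain_error")
  }
  d <- resp$data
  t_end <- d$t[nrow(d)]
  if (t_end < (n_transient_periods + 1) * period - 1e-9) {
    abort(sprintf(
      "response spans %.3g s; need >= %d periods (%g s) for the loop.",
      t_end, n_transient_periods + 1, (n_transient_periods + 1) * period),
      class = "fractalflow_domain_error")
  }
  dd <- d[d$t >= t_end - period - 1e-12, , drop = FALSE]
  P <- dd$P; Q <- dd$Q; t <- dd$t
  n <- length(P)
  # signed shoelace area of the closed (P, Q) polygon
  area <- 0.5 * (sum(P[-n] * Q[-1] - P[-1] * Q[-n]) + P[n] * Q[1] - P[1] * Q[n])
  # circular distance between the flow and pressure peaks within the period
  raw <- (t[which.max(Q)] - t[which.max(P)]) %% period
  lag <- min(raw, period - raw)
  structure(
    list(data = tibble(t = t, P = P, Q = Q),
         area = area,
         phase_lag = lag,
         closure_gap = abs(Q[n] - Q[1]),
         period = period,
         segment = resp$segment, C = resp$C, tau = resp$tau),
    class = "hysteresis_loop"
  )
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf(
    "<hysteresis_loop> %s: |area| = %.4g, phase lag = %.4g s, closure gap = %.3g\n",
    x$segment %||% "?", abs(x$area), x$phase_lag, x$closure_gap))
  invisible(x)
}

#' @export
tidy.hysteresis_loop <- function(x, ...) x$data

#' @export
glance.hysteresis_loop <- function(x, ...) {
  tibble(segment = x$segment, C = x$C, tau = x$tau, period = x$period,
         area = x$area, abs_area = abs(x$area),
         phase_lag = x$phase_lag, closure_gap = x$closure_gap)
}

#' @export
autoplot.hysteresis_loop <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$P, y = .data$Q)) +
    ggplot2::geom_path(colour = "darkorange") +
    ggplot2::labs(x = "pressure (mmHg)", y = "flow (model units)") +
    ggplot2::theme_minimal()
}

#' Stable modulation interval of the characteristic time
#'
#' Sweeps the characteristic time over an ascending grid, computes the flow
#' response at each value, and finds the smallest grid value beyond which
#' consecutive responses differ by less than `accuracy_pct` percent (max
#' norm over the final period, relative to the peak magnitude of the later
#' response). Beyond this threshold the modulated flow is effectively
#' insensitive to further increases of the characteristic time. The
#' threshold depends on the input waveform and on the chosen accuracy.
#'
#' @param waveform the driving pressure waveform.
#' @param segment `"aorta"` or `"arteriole"`.
#' @param tau_grid ascending characteristic times (s).
#' @param accuracy_pct stabilisation tolerance in percent.
#' @param C compliance; segment default when `NULL`.
#' @param sign modulation sign; segment default when `NULL`.
#' @return a list with `tau_critical` (NA when never reached), `reached`,
#'   and `sweep`, a tibble of consecutive-pair differences and
#'   peak-to-peak amplitudes.
#' @export
stable_modulation_interval <- function(waveform, segment, tau_grid,
                                       accuracy_pct = 5, C = NULL,
                                       sign = NULL) {
  if (is.unsorted(tau_grid, strictly = TRUE)) {
    abort("`tau_grid` must be strictly ascending.",
          class = "fractalflow_domain_error")
  }
  check_positive(accuracy_pct, "accuracy_pct")
  resps <- purrr::map(tau_grid, function(tv) {
    flow_response(waveform, segment = segment, C = C, tau = tv, sign = sign)
  })
  qs <- purrr::map(resps, function(r) last_period(r)$Q)
  p2p <- purrr::map_dbl(qs, function(q) diff(range(q)))
  rel <- purrr::map_dbl(seq_len(length(qs) - 1), function(k) {
    100 * max(abs(qs[[k + 1]] - qs[[k]])) / max(abs(qs[[k + 1]]))
  })
  sweep <- tibble(
    tau = tau_grid,
    peak_to_peak = p2p,
    rel_diff_from_prev_pct = c(NA_real_, rel)
  )
  stable <- rel < accuracy_pct
  # smallest tau beyond which every later consecutive difference is stable
  idx <- NA_integer_
  for (j in seq_along(stable)) {
    if (all(stable[j:length(stable)])) { idx <- j; break }
  }
  list(
    tau_critical = if (is.na(idx)) NA_real_ else tau_grid[idx],
    reached = !is.na(idx),
    accuracy_pct = accuracy_pct,
    sweep = sweep
  )
}

#' Compare the time-domain response with the operator's frequency gain
#'
#' Diagnostic for the internal consistency of the operational calculus: the
#' steady-state gain of the time-domain convolution solution at the first
#' few harmonics of the input (estimated by discrete Fourier coefficients
#' over the final period) is compared with the magnitude of the closed-form
#' admittance root evaluated on the imaginary axis. The two calculi are not
#' asserted equal — the observed relative deviation is reported as data.
#'
#' @param resp a [flow_response()] object driven by a periodic input.
#' @param n_harmonics number of input harmonics to compare.
#' @return a tibble with columns `harmonic`, `omega`, `gain_time_domain`,
#'   `gain_operator`, `rel_deviation`.
#' @export
fao_consistency <- function(resp, n_harmonics = 3) {
  stopifnot(inherits(resp, "flow_response"))
  d <- last_period(resp)
  period <- resp$period
  if (is.null(period) || is.na(period)) {
    abort("waveform must carry a period.", class = "fractalflow_domain_error")
  }
  # drop the duplicated endpoint for the DFT
  n <- nrow(d) - 1L
  P <- d$P[seq_len(n)]; Q <- d$Q[seq_len(n)]
  op <- fao(resp$segment, C = resp$C, tau = resp$tau,
            branch = resp$sign)
  purrr::map_dfr(seq_len(n_harmonics), function(h) {
    w <- exp(-2i * pi * h * (seq_len(n) - 1) / n)
    cp <- sum(P * w) / n
    cq <- sum(Q * w) / n
    omega <- 2 * pi * h / period
    gain_td <- Mod(cq) / Mod(cp)
    gain_op <- Mod(fao_frequency_response(op, complex(real = 0, imaginary = omega)))
    tibble(harmonic = h, omega = omega,
           input_amplitude = Mod(cp),
           gain_time_domain = gain_td, gain_operator = gain_op,
           rel_deviation = abs(gain_td - gain_op) / gain_op)
  })
}
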