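#' Parameters of the two-harmonic pulse-pressure wave
#'
#' A full arterial pressure pulse is modelled as the superposition of a
#' primary systolic harmonic and a reflected (dicrotic) harmonic over one
#' cardiac period `t0`. The defaults are representative values for the two
#' segments: aorta `P0 = 22`, `P0sin = 20` mmHg, reflection weight
#' `k = 0.7`; arteriole `P0 = 20`, `P0sin = 35` mmHg, `k = 0.5`; cardiac
#' period `t0 = 0.8` s for both.
#'
#' @param segment `"aorta"` or `"arteriole"`; chooses the default set.
#' @param P0 baseline (diastolic) pressure, mmHg.
#' @param P0sin amplitude of the primary harmonic, mmHg.
#' @param k dimensionless reflection weight in `[0, 1]`.
#' @param t0 cardiac period (s).
#' @return a list of class `pulse_params`.
#' @export
#' @examples
#' pulse_params("aorta")
#' pulse_params("arteriole", t0 = 1.0)
pulse_params <- function(segment = c("aorta", "arteriole"),
                         P0 = NULL, P0sin = NULL, k = NULL, t0 = 0.8) {
  segment <- arg_match(segment)
  def <- switch(segment,
    aorta = list(P0 = 22, P0sin = 20, k = 0.7),
    arteriole = list(P0 = 20, P0sin = 35, k = 0.5)
  )
  P0 <- P0 %||% def$P0
  P0sin <- P0sin %||% def$P0sin
  k <- k %||% def$k
  check_positive(t0, "t0")
  if (!is.numeric(k) || k < 0 || k > 1) {
    abort("`k` must lie in [0, 1].", class = "fractalflow_domain_error")
  }
  structure(list(segment = segment, P0 = P0, P0sin = P0sin, k = k, t0 = t0),
            class = "pulse_params")
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf("<pulse_params> %s: P0 = %g mmHg, P0sin = %g mmHg, k = %g, t0 = %g s\n",
              x$segment, x$P0, x$P0sin, x$k, x$t0))
  invisible(x)
}

#' Piecewise two-harmonic pulse pressure
#'
#' Evaluates the pressure wave at time `t` (reduced modulo the period).
#' The period splits into three equal segments: the systolic upstroke
#' carries the primary harmonic alone, the middle segment superposes the
#' primary and the reflected harmonic, and the final segment carries the
#' reflected harmonic alone:
#' \deqn{P(t) = P_0 + P_{0sin}[\sin(3\pi t/t_0 - \pi/2) + 1]}
#' on the first third, with the `k`-weighted reflected term
#' `sin(3 pi t / t0 - 3 pi / 2)` joining on the middle third and standing
#' alone (weighted by `k`) on the last third.
#'
#' In `"continuous"` mode (the default) the middle-segment baseline is
#' `P0` and the wave is exactly continuous at both junctions, with
#' `P(0) = P(t0) = P0`. `"as_printed"` mode uses a `2 P0` baseline on the
#' middle segment, which introduces a jump of exactly `P0` at both
#' junctions; it is retained for comparison.
#'
#' @param t time(s), s; values outside `[0, t0]` are wrapped periodically.
#' @param params a [pulse_params()] object.
#' @param mode `"continuous"` or `"as_printed"`.
#' @return pressure in mmHg, one value per `t`.
#' @export
#' @examples
#' p <- pulse_params("aorta")
#' pulse_pressure(0, p)          # 22 (baseline)
#' pulse_pressure(0.8 / 3, p)    # 62 (systolic peak)
pulse_pressure <- function(t, params, mode = c("continuous", "as_printed")) {
  mode <- arg_match(mode)
  stopifnot(inherits(params, "pulse_params"))
  P0 <- params$P0; Ps <- params$P0sin; k <- params$k; t0 <- params$t0
  if (t0 <= 0) abort("`t0` must be positive.",
                     class = "fractalflow_domain_error")
  tm <- t %% t0
  # keep t = t0 (and multiples) on the closing segment, not wrapped to 0
  tm[t > 0 & tm == 0] <- t0
  th <- 3 * pi * tm / t0
  B <- if (mode == "continuous") P0 else 2 * P0
  seg1 <- P0 + Ps * (sin(th - pi / 2) + 1)
  seg2 <- B + Ps * (sin(th - pi / 2) + k * sin(th - 3 * pi / 2) + k + 1)
  seg3 <- P0 + k * Ps * (sin(th - 3 * pi / 2) + 1)
  ifelse(tm <= t0 / 3, seg1, ifelse(tm <= 2 * t0 / 3, seg2, seg3))
}

junction_jumps <- function(params, mode) {
  t0 <- params$t0
  eval_at <- function(t) pulse_pressure(t, params, mode = mode)
  # closed-form one-sided values at the junctions
  th1 <- pi; th2 <- 2 * pi
  P0 <- params$P0; Ps <- params$P0sin; k <- params$k
  B <- if (mode == "continuous") P0 else 2 * P0
  s1_end <- P0 + Ps * (sin(th1 - pi / 2) + 1)
  s2_start <- B + Ps * (sin(th1 - pi / 2) + k * sin(th1 - 3 * pi / 2) + k + 1)
  s2_end <- B + Ps * (sin(th2 - pi / 2) + k * sin(th2 - 3 * pi / 2) + k + 1)
  s3_start <- P0 + k * Ps * (sin(th2 - 3 * pi / 2) + 1)
  tibble(
    junction = c("t0/3", "2*t0/3", "period_wrap"),
    t = c(t0 / 3, 2 * t0 / 3, t0),
    jump = c(abs(s2_start - s1_end), abs(s3_start - s2_end),
             abs(eval_at(t0) - eval_at(0)))
  )
}

#' Sample a pulse waveform on a uniform grid
#'
#' Evaluates the pulse wave on `[0, n_periods * t0]` with step `dt`, and
#' attaches a continuity report: the closed-form jumps across the two
#' interior segment junctions and across the period wrap.
#'
#' @param params a [pulse_params()] object.
#' @param dt sampling step (s); a step coarser than `t0 / 10` triggers an
#'   under-resolution warning.
#' @param n_periods number of cardiac periods to cover (>= 1).
#' @param mode passed to [pulse_pressure()].
#' @return a tibble of class `pulse_waveform` with columns `t`, `P` and
#'   attributes `params`, `mode`, `dt`, `continuity` (the junction report).
#' @export
#' @examples
#' w <- sample_waveform(pulse_params("aorta"), dt = 0.005, n_periods = 2)
#' attr(w, "continuity")
sample_waveform <- function(params, dt = 0.001, n_periods = 3,
                            mode = c("continuous", "as_printed")) {
  mode <- arg_match(mode)
  stopifnot(inherits(params, "pulse_params"))
  check_positive(dt, "dt")
  if (n_periods < 1) abort("`n_periods` must be >= 1.",
                           class = "fractalflow_domain_error")
  if (dt > params$t0 / 10) {
    warn(sprintf("dt = %g s under-resolves the period t0 = %g s.",
                 dt, params$t0))
  }
  t <- seq(0, n_periods * params$t0, by = dt)
  out <- tibble(t = t, P = pulse_pressure(t, params, mode = mode))
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  attr(out, "dt") <- dt
  attr(out, "continuity") <- junction_jumps(params, mode)
  class(out) <- c("pulse_waveform", class(out))
  out
}

#' Read an external pressure waveform from a two-column CSV
#'
#' Accepts a table with time (s) and pressure (mmHg) columns and linearly
#' interpolates it onto a uniform grid so it can drive [flow_response()].
#'
#' @param path CSV file with columns `t` and `P` (header required).
#' @param dt target uniform step (s); defaults to the median input spacing.
#' @return a `pulse_waveform` tibble (without pulse parameters attached).
#' @export
read_waveform_csv <- function(path, dt = NULL) {
  raw <- utils::read.csv(path)
  if (!all(c("t", "P") %in% names(raw))) {
    abort("waveform CSV must have columns `t` and `P`.",
          class = "fractalflow_domain_error")
  }
  ord <- order(raw$t)
  tt <- raw$t[ord]; pp <- raw$P[ord]
  dt <- dt %||% stats::median(diff(tt))
  check_positive(dt, "dt")
  grid <- seq(min(tt), max(tt), by = dt)
  out <- tibble(t = grid - min(tt),
                P = stats::approx(tt, pp, xout = grid)$y)
  attr(out, "dt") <- dt
  class(out) <- c("pulse_waveform", class(out))
  out
}

#' @export
autoplot.pulse_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$P)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "t (s)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
}
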