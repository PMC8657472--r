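#' Describe an arterial vessel segment
#'
#' Builds a one-row tibble holding the physiological description of a
#' homogeneous arterial segment: lumen geometry, wall elasticity and blood
#' properties. These are the inputs of the mechanical-electrical analogy in
#' which pressure plays the role of voltage, flow of current, blood inertia
#' of inductance, wall compliance of capacitance and blood viscosity of
#' resistance.
#'
#' @param kind segment label, `"aorta"` or `"arteriole"`. In the aorta blood
#'   inertia dominates the flow regulation; in the arteriole viscosity does.
#' @param r lumen radius (cm).
#' @param h wall thickness (cm).
#' @param E wall elastic modulus (mmHg).
#' @param rho blood density (g cm^-3).
#' @param mu blood viscosity (poise).
#' @param cL,cR dimensionless inertia and viscosity shape coefficients.
#'   They are not fixed by the analogy itself and default to 1.
#'
#' @return a tibble of class `vessel_segment` with one row per segment
#'   (arguments are recycled by [tibble::tibble()]).
#' @seealso [map_vessel_to_circuit()]
#' @export
#' @examples
#' vessel_segment("aorta", r = 1.2, h = 0.2, E = 1200)
vessel_segment <- function(kind = c("aorta", "arteriole"), r, h, E,
                           rho = 1.05, mu = 0.04, cL = 1, cR = 1) {
  kind <- arg_match(kind)
  for (nm in c("r", "h", "E")) {
    v <- get(nm)
    if (any(!is.finite(v) | v <= 0)) {
      abort(sprintf("`%s` must be positive and finite.", nm),
            class = "fractalflow_domain_error")
    }
  }
  if (any(rho < 0) || any(mu < 0)) {
    abort("`rho` and `mu` must be non-negative.",
          class = "fractalflow_domain_error")
  }
  if (any(cL <= 0) || any(cR <= 0)) {
    abort("`cL` and `cR` must be positive.",
          class = "fractalflow_domain_error")
  }
  out <- tibble(kind = kind, r = r, h = h, E = E,
                rho = rho, mu = mu, cL = cL, cR = cR)
  class(out) <- c("vessel_segment", class(out))
  out
}

#' Map vessel segments to their analogous circuit parameters
#'
#' Converts the physiological description of one or more segments into the
#' per-unit-length electrical parameters of the analogous transmission-line
#' circuit:
#' \deqn{L = c_L \rho / (\pi r^2), \quad C = 3 \pi r^2 / (2 E h), \quad
#'       R = 8 c_R \mu / (\pi r^4),}
#' i.e. inductance proportional to blood inertia, capacitance inversely
#' proportional to the wall elastic modulus, and the Poiseuille-type
#' resistance proportional to viscosity. The characteristic time of the
#' segment is attached per kind (see [characteristic_time()]).
#'
#' @param segments a data frame as returned by [vessel_segment()] (columns
#'   `kind`, `r`, `h`, `E`, `rho`, `mu`, `cL`, `cR`).
#' @return a tibble of class `circuit_params` with columns `kind`, `L`, `C`,
#'   `R`, `tau`.
#' @export
#' @examples
#' vessel_segment("aorta", r = 1, h = 1, E = 3 * pi / 2) |>
#'   map_vessel_to_circuit()
map_vessel_to_circuit <- function(segments) {
  stopifnot(is.data.frame(segments))
  need <- c("kind", "r", "h", "E", "rho", "mu", "cL", "cR")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    abort(paste0("`segments` is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "fractalflow_domain_error")
  }
  for (nm in c("r", "h", "E")) {
    if (any(!is.finite(segments[[nm]]) | segments[[nm]] <= 0)) {
      abort(sprintf("`%s` must be positive and finite.", nm),
            class = "fractalflow_domain_error")
    }
  }
  out <- segments |>
    dplyr::mutate(
      L = .data$cL * .data$rho / (pi * .data$r^2),
      C = 3 * pi * .data$r^2 / (2 * .data$E * .data$h),
      R = 8 * .data$cR * .data$mu / (pi * .data$r^4),
      tau = characteristic_time(L = .data$L, C = .data$C, R = .data$R,
                                kind = .data$kind)
    ) |>
    dplyr::select("kind", "L", "C", "R", "tau")
  out <- as_tibble(out)
  class(out) <- c("circuit_params", class(out))
  out
}

#' Build circuit parameters directly
#'
#' Bypasses the physiological mapping and states the per-unit-length
#' electrical parameters of the ladder circuit directly. The characteristic
#' time is computed from them.
#'
#' @param kind `"aorta"` or `"arteriole"`.
#' @param L inductance per unit length (aorta; ignored for the arteriole).
#' @param C capacitance (compliance) per unit length, cm mmHg^-1.
#' @param R resistance per unit length (arteriole; ignored for the aorta).
#' @return a one-row tibble of class `circuit_params`.
#' @export
#' @examples
#' circuit_params("aorta", L = 6.25, C = 1)      # tau = 2.5 s
#' circuit_params("arteriole", C = 0.1, R = 50)  # tau = 5 s
circuit_params <- function(kind = c("aorta", "arteriole"),
                           L = NA_real_, C, R = NA_real_) {
  kind <- arg_match(kind)
  check_positive(C, "C", strict = FALSE)
  out <- tibble(kind = kind, L = L, C = C, R = R,
                tau = characteristic_time(L = L, C = C, R = R, kind = kind))
  class(out) <- c("circuit_params", class(out))
  out
}

#' Characteristic time of a circuit segment
#'
#' The aortic characteristic time combines blood inertia and wall
#' compliance, `tau = sqrt(L * C)` (seconds); the arteriolar one combines
#' viscosity and compliance, `tau = R * C`. These are the single time
#' scales that the closed-form convolution kernels depend on.
#'
#' @param L,C,R per-unit-length circuit parameters; `L` is required for the
#'   aorta, `R` for the arteriole, `C` always.
#' @param kind `"aorta"` or `"arteriole"`; vectorised along the parameters.
#' @return characteristic time(s) in seconds.
#' @export
#' @examples
#' characteristic_time(L = 6.25, C = 1, kind = "aorta")
#' characteristic_time(C = 0.1, R = 50, kind = "arteriole")
characteristic_time <- function(L = NA_real_, C, R = NA_real_, kind) {
  kind <- as.character(kind)
  if (!all(kind %in% c("aorta", "arteriole"))) {
    abort("`kind` must be \"aorta\" or \"arteriole\".",
          class = "fractalflow_domain_error")
  }
  n <- max(length(L), length(C), length(R), length(kind))
  L <- rep_len(L, n); C <- rep_len(C, n)
  R <- rep_len(R, n); kind <- rep_len(kind, n)
  ao <- kind == "aorta"
  if (any(ao & (!is.finite(L) | L <= 0 | !is.finite(C) | C <= 0))) {
    abort("aortic characteristic time needs positive `L` and `C`.",
          class = "fractalflow_domain_error")
  }
  if (any(!ao & (!is.finite(R) | R <= 0 | !is.finite(C) | C <= 0))) {
    abort("arteriolar characteristic time needs positive `R` and `C`.",
          class = "fractalflow_domain_error")
  }
  ifelse(ao, sqrt(L * C), R * C)
}
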