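## B0 (phase-difference) and B1 (double-angle) field mapping.

#' Compute a B0 off-resonance map from dual-echo complex data
#'
#' Per pixel, the off-resonance in Hz is the phase of the complex ratio
#' of the two echoes divided by `2 * pi * dTE`:
#' \deqn{\Delta f = \mathrm{arg}(S_2 \bar S_1) / (2 \pi \Delta TE).}
#' The estimate is unambiguous for `|delta_f| < 1/(2 dTE)`; larger
#' offsets alias by multiples of `1/dTE`. No spatial unwrapping is
#' performed.
#'
#' @param stack an `image_stack` with two complex frames at distinct
#'   echo times.
#' @param mag_threshold pixels whose magnitude at either echo falls at or
#'   below this are flagged undefined (`NA`).
#' @return a `field_map_result` with `delta_f_hz`, `ppm`, a `valid`
#'   mask, the echo spacing and field strength used.
#' @export
compute_b0_map <- function(stack, mag_threshold = 0) {
  stopifnot(inherits(stack, "image_stack"), is.complex(stack$frames),
            dim(stack$frames)[3] == 2)
  te <- stack$frame_parameter
  dte_s <- abs(te[2] - te[1]) / 1000
  if (dte_s == 0) stop("protocol error: echo times must differ")
  dims <- dim(stack$frames)[1:2]
  f1 <- array(stack$frames[, , 1], dims)
  f2 <- array(stack$frames[, , 2], dims)
  valid <- Mod(f1) > mag_threshold & Mod(f2) > mag_threshold
  delta_f <- Arg(f2 * Conj(f1)) / (2 * pi * dte_s)
  delta_f[!valid] <- NA_real_
  b0_t <- stack$protocol$field_strength_t
  if (is.null(b0_t)) b0_t <- NA_real_
  structure(list(delta_f_hz = delta_f,
                 ppm = if (is.na(b0_t)) NULL else
                   frequency_to_ppm(delta_f, b0_t),
                 valid = valid, dte_ms = abs(te[2] - te[1]),
                 aliasing_limit_hz = 1 / (2 * dte_s),
                 field_strength_t = b0_t,
                 gamma_mhz_per_t = GAMMA_MHZ_PER_T),
            class = "field_map_result")
}

#' Convert off-resonance frequency to parts per million
#'
#' `ppm = delta_f / (42.576 MHz/T * B0)`: the frequency offset as a
#' fraction of the proton Larmor frequency. `ppm_report()` rounds to one
#' significant figure, the display precision used when quoting phantom
#' uniformity (e.g. 1 Hz at 3 T reports as 0.008 ppm); stored maps are
#' never rounded.
#'
#' @param delta_f_hz off-resonance, Hz.
#' @param field_strength_t main field, tesla (> 0).
#' @return ppm (dimensionless x 1e-6).
#' @examples
#' frequency_to_ppm(1, 3)        # 0.00783...
#' ppm_report(frequency_to_ppm(1, 3))   # 0.008
#' @export
frequency_to_ppm <- function(delta_f_hz, field_strength_t) {
  stopifnot(field_strength_t > 0)
  delta_f_hz / (GAMMA_MHZ_PER_T * field_strength_t)
}

#' @rdname frequency_to_ppm
#' @param ppm ppm value(s) to round for display.
#' @export
ppm_report <- function(ppm) {
  signif(ppm, 1)
}

#' Compute a relative flip-angle (B1) map by the double-angle method
#'
#' With long-TR acquisitions at nominal angles alpha and 2 alpha, the
#' actual per-pixel flip angle is
#' \deqn{\alpha_{actual} = \arccos( S_{2\alpha} / (2 S_\alpha) )}
#' and the relative flip angle is `alpha_actual / alpha_nominal`. Pixels
#' whose signal ratio falls outside (0, 1] (arccos domain) are flagged
#' invalid rather than raising an error.
#'
#' @param stack an `image_stack` from a double-angle acquisition.
#' @return a `field_map_result` with `actual_fa_deg`, `relative_fa` and
#'   a `valid` mask.
#' @export
compute_b1_dam <- function(stack) {
  stopifnot(inherits(stack, "image_stack"),
            dim(stack$frames)[3] == 2)
  ang <- stack$frame_parameter
  if (abs(ang[2] - 2 * ang[1]) > 1e-9) {
    stop("protocol error: nominal angles must be in ratio 1:2")
  }
  dims <- dim(stack$frames)[1:2]
  s1 <- array(stack$frames[, , 1], dims)
  s2 <- array(stack$frames[, , 2], dims)
  ratio <- s2 / (2 * s1)
  valid <- is.finite(ratio) & ratio > 0 & ratio <= 1
  actual <- matrix(NA_real_, nrow(ratio), ncol(ratio))
  actual[valid] <- acos(ratio[valid]) * 180 / pi
  structure(list(actual_fa_deg = actual,
                 relative_fa = actual / ang[1],
                 nominal_fa_deg = ang[1], valid = valid),
            class = "field_map_result")
}

#' Displacement-to-conduction current ratio
#'
#' The ratio `Q = omega * epsilon / sigma` of displacement to conduction
#' current in a dielectric at angular frequency `omega`: the figure of
#' merit that motivates lowering the permittivity of the outer matrix
#' fill (e.g. by packing HDPE beads) to flatten the transmit field.
#'
#' @param omega angular frequency, rad/s (> 0).
#' @param permittivity permittivity, F/m (> 0).
#' @param conductivity conductivity, S/m (> 0).
#' @return dimensionless Q.
#' @export
displacement_current_ratio <- function(omega, permittivity,
                                       conductivity) {
  stopifnot(omega > 0, permittivity > 0)
  if (any(conductivity == 0)) stop("conductivity must be non-zero")
  if (any(conductivity < 0)) stop("conductivity must be positive")
  omega * permittivity / conductivity
}
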