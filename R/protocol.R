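## Acquisition protocols for the simulated sequences.

SEQUENCES <- c("IR_GRE", "SE", "MOLLI", "T2PREP_BSSFP",
               "DUAL_ECHO_GRE", "DOUBLE_ANGLE")

#' Construct an acquisition protocol
#'
#' A validated parameter bundle for one of the supported sequences. The
#' per-sequence helpers below carry the defaults used throughout:
#' timing lists are sorted ascending, times are in ms and angles in
#' degrees.
#'
#' @param sequence one of `"IR_GRE"`, `"SE"`, `"MOLLI"`,
#'   `"T2PREP_BSSFP"`, `"DUAL_ECHO_GRE"`, `"DOUBLE_ANGLE"`.
#' @param ... sequence parameters; see the helper constructors.
#' @return an `acquisition_protocol` list.
#' @export
acquisition_protocol <- function(sequence, ...) {
  sequence <- match.arg(sequence, SEQUENCES)
  p <- list(...)
  p$sequence <- sequence
  for (f in c("ti_list", "te_list", "teprep_list")) {
    if (!is.null(p[[f]])) p[[f]] <- sort(as.numeric(p[[f]]))
  }
  if (!is.null(p$rr) && p$rr <= 0) stop("protocol error: rr must be > 0")
  if (!is.null(p$readout_tr) && p$readout_tr <= 0) {
    stop("protocol error: readout_tr must be > 0")
  }
  structure(p, class = "acquisition_protocol")
}

#' Sequence protocol defaults
#'
#' Default protocols for the simulated acquisitions:
#' \describe{
#'   \item{`protocol_ir_gre()`}{reference T1: inversion-recovery gradient
#'     echo with 11 inversion times 20-2100 ms, 90 deg excitation,
#'     TR 10 s.}
#'   \item{`protocol_se()`}{reference T2: single-echo spin echo with 10
#'     echo times 10-150 ms, TR 10 s.}
#'   \item{`protocol_molli()`}{5(3)3 MOLLI at RR 900 ms, minimum TI
#'     100 ms, 35 deg (1.5 T) or 20 deg (3 T) bSSFP readout of 65 pulses
#'     at 2.8 ms spacing.}
#'   \item{`protocol_t2prep_bssfp()`}{T2-prepared bSSFP with preparation
#'     times 0/25/55 ms, 70 deg readout, 10-pulse linear ramp-up, 3
#'     recovery beats at RR 900 ms.}
#'   \item{`protocol_dual_echo_gre()`}{B0 mapping: gradient echo at two
#'     echo times 2.5 ms apart.}
#'   \item{`protocol_double_angle()`}{B1 mapping: 60/120 deg excitations
#'     with an 8 s TR so T1 weighting is negligible.}
#' }
#'
#' @param ti_list,te_list,teprep_list timing lists, ms.
#' @param flip_angle nominal excitation flip angle, degrees.
#' @param tr repetition time, ms.
#' @param rr simulated cardiac R-R interval, ms.
#' @param ti_min minimum inversion time of the first MOLLI image, ms.
#' @param readout_pulses number of bSSFP pulses per readout train.
#' @param readout_tr spacing of readout pulses, ms.
#' @param ramp_pulses linear ramp-up pulses preceding a bSSFP train.
#' @param recovery_beats free-recovery heartbeats between preparations.
#' @param echo_times_fieldmap two echo times for phase-difference B0
#'   mapping, ms.
#' @param nominal_angles two nominal flip angles in ratio 1:2, degrees.
#' @param field_strength_t main field, tesla.
#' @return an `acquisition_protocol`.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_ir_gre <- function(ti_list = c(20, 50, 100, 200, 400, 600, 800,
                                        1000, 1300, 1700, 2100),
                            flip_angle = 90, tr = 10000) {
  acquisition_protocol("IR_GRE", ti_list = ti_list,
                       flip_angle = flip_angle, tr = tr)
}

#' @rdname protocols
#' @export
protocol_se <- function(te_list = c(10, 20, 30, 40, 50, 60, 80, 100, 125,
                                    150),
                        flip_angle = 90, tr = 10000) {
  acquisition_protocol("SE", te_list = te_list, flip_angle = flip_angle,
                       tr = tr)
}

#' @rdname protocols
#' @export
protocol_molli <- function(field_strength_t = 1.5, rr = 900, ti_min = 100,
                           flip_angle = if (field_strength_t >= 2) 20 else 35,
                           readout_pulses = 65, readout_tr = 2.8) {
  acquisition_protocol("MOLLI", rr = rr, ti_min = ti_min,
                       flip_angle = flip_angle,
                       readout_pulses = readout_pulses,
                       readout_tr = readout_tr,
                       field_strength_t = field_strength_t)
}

#' @rdname protocols
#' @export
protocol_t2prep_bssfp <- function(teprep_list = c(0, 25, 55),
                                  flip_angle = 70, rr = 900,
                                  readout_pulses = 65, readout_tr = 2.8,
                                  ramp_pulses = 10, recovery_beats = 3,
                                  field_strength_t = 1.5) {
  if (length(teprep_list) < 2) {
    warning("fewer than 2 preparation times: T2 fit will be infeasible")
  }
  acquisition_protocol("T2PREP_BSSFP", teprep_list = teprep_list,
                       flip_angle = flip_angle, rr = rr,
                       readout_pulses = readout_pulses,
                       readout_tr = readout_tr, ramp_pulses = ramp_pulses,
                       recovery_beats = recovery_beats,
                       field_strength_t = field_strength_t)
}

#' @rdname protocols
#' @export
protocol_dual_echo_gre <- function(echo_times_fieldmap = c(2.5, 5.0),
                                   tr = 1000, flip_angle = 90) {
  if (length(echo_times_fieldmap) != 2 ||
      echo_times_fieldmap[1] == echo_times_fieldmap[2]) {
    stop("protocol error: need two distinct echo times for B0 mapping")
  }
  acquisition_protocol("DUAL_ECHO_GRE",
                       echo_times_fieldmap = sort(echo_times_fieldmap),
                       tr = tr, flip_angle = flip_angle)
}

#' @rdname protocols
#' @export
protocol_double_angle <- function(nominal_angles = c(60, 120), tr = 8000) {
  if (length(nominal_angles) != 2 ||
      abs(nominal_angles[2] - 2 * nominal_angles[1]) > 1e-9) {
    stop("protocol error: nominal angles must be in ratio 1:2")
  }
  acquisition_protocol("DOUBLE_ANGLE", nominal_angles = nominal_angles,
                       tr = tr)
}
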