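## Phantom geometry: a 3x3 array of 24 mm tubes inside a 100 x 100 mm body,
## rasterized to per-pixel compartment labels and ground-truth T1/T2 maps.

#' Construct a phantom layout
#'
#' @param tubes data frame with columns `id`, `x_mm`, `y_mm` (tube center
#'   coordinates) and truth columns `t1_1p5T_ms`, `t2_1p5T_ms`,
#'   `t1_3T_ms`, `t2_3T_ms`. May have zero rows.
#' @param tube_inner_diameter_mm inner diameter of each tube (mm).
#' @param body_mm body cross-section, length-2 (mm x mm).
#' @param outer_fill named list with `t1_ms`, `t2_ms`: truth for the outer
#'   gel matrix fill.
#' @return a `phantom_layout` object.
#' @export
phantom_layout <- function(tubes, tube_inner_diameter_mm = 24,
                           body_mm = c(100, 100),
                           outer_fill = list(t1_ms = 850, t2_ms = 140)) {
  stopifnot(is.data.frame(tubes), length(body_mm) == 2,
            tube_inner_diameter_mm > 0)
  r <- tube_inner_diameter_mm / 2
  n <- nrow(tubes)
  if (n > 0) {
    if (anyDuplicated(tubes$id)) stop("tube ids must be unique")
    # no two tube disks may overlap
    if (n > 1) {
      d <- as.matrix(dist(tubes[, c("x_mm", "y_mm")]))
      diag(d) <- Inf
      if (any(d < 2 * r)) stop("layout invalid: tube disks overlap")
    }
    inside <- tubes$x_mm - r >= 0 & tubes$x_mm + r <= body_mm[1] &
      tubes$y_mm - r >= 0 & tubes$y_mm + r <= body_mm[2]
    if (!all(inside)) stop("layout invalid: tube(s) outside the body")
  }
  structure(list(tubes = tubes,
                 tube_inner_diameter_mm = tube_inner_diameter_mm,
                 body_mm = body_mm, outer_fill = outer_fill),
            class = "phantom_layout")
}

#' Default nine-tube phantom layout
#'
#' The 3x3 arrangement used throughout: 24 mm tubes on a 30 mm grid inside
#' a 100 x 100 mm body cross-section, with the long-T1 tubes placed
#' centrally and the corner positions held by tubes A, B, F and I. The
#' per-tube truth at 1.5 T and 3 T comes from the packaged calibration
#' table; the outer matrix fill uses its bench-relaxometer values
#' (T1 850 ms, T2 140 ms) at both field strengths since no in-scanner
#' measurement of the fill exists.
#'
#' @return a `phantom_layout` with nine tubes `A`-`I`.
#' @export
default_phantom_layout <- function() {
  cal <- calibration_fixture()
  cal <- cal[cal$tube_id != "outer", ]
  # grid positions, mm; corners are A, B, F, I
  pos <- data.frame(
    id = c("A", "C", "B", "D", "G", "E", "F", "H", "I"),
    x_mm = rep(c(20, 50, 80), 3),
    y_mm = rep(c(20, 50, 80), each = 3)
  )
  idx <- match(pos$id, cal$tube_id)
  pos$t1_1p5T_ms <- cal$t1_1p5T_ms[idx]
  pos$t2_1p5T_ms <- cal$t2_1p5T_ms[idx]
  pos$t1_3T_ms <- cal$t1_3T_ms[idx]
  pos$t2_3T_ms <- cal$t2_3T_ms[idx]
  phantom_layout(pos)
}

#' Rasterize a phantom layout into ground-truth maps
#'
#' Point-samples the layout on a regular pixel grid: a pixel belongs to a
#' tube iff its center lies strictly inside the tube disk; all other
#' pixels are outer matrix fill. No partial-volume weighting is applied.
#'
#' @param layout a `phantom_layout`.
#' @param pixel_size pixel edge length, mm (> 0).
#' @param field `"1.5T"` or `"3T"`: which truth columns to rasterize.
#' @return a `ground_truth_maps` object: integer `label_map` (0 = outside
#'   body — absent for the default full-body grid, 1-9 = tubes in layout
#'   row order, 10 = outer fill), `t1_map`/`t2_map` in ms, `pixel_size`,
#'   and tube metadata used downstream for ROI placement.
#' @examples
#' truth <- rasterize_layout(default_phantom_layout(), pixel_size = 1)
#' table(truth$label_map)
#' @export
rasterize_layout <- function(layout, pixel_size = 1,
                             field = c("1.5T", "3T")) {
  stopifnot(inherits(layout, "phantom_layout"), pixel_size > 0)
  field <- match.arg(field)
  suffix <- if (field == "1.5T") "1p5T" else "3T"
  nx <- round(layout$body_mm[1] / pixel_size)
  ny <- round(layout$body_mm[2] / pixel_size)
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  label <- matrix(10L, nx, ny)
  t1 <- matrix(layout$outer_fill$t1_ms, nx, ny)
  t2 <- matrix(layout$outer_fill$t2_ms, nx, ny)
  r2 <- (layout$tube_inner_diameter_mm / 2)^2
  tubes <- layout$tubes
  for (i in seq_len(nrow(tubes))) {
    dsq <- outer((xc - tubes$x_mm[i])^2, (yc - tubes$y_mm[i])^2, `+`)
    hit <- dsq < r2
    if (any(label[hit] != 10L)) stop("layout invalid: overlapping tubes")
    label[hit] <- i
    t1[hit] <- tubes[[paste0("t1_", suffix, "_ms")]][i]
    t2[hit] <- tubes[[paste0("t2_", suffix, "_ms")]][i]
  }
  structure(list(label_map = label, t1_map = t1, t2_map = t2,
                 pixel_size = pixel_size, field = field,
                 tube_ids = tubes$id,
                 tube_centers_mm = tubes[, c("id", "x_mm", "y_mm")],
                 tube_radius_mm = layout$tube_inner_diameter_mm / 2),
            class = "ground_truth_maps")
}

#' Construct ground-truth maps directly from matrices
#'
#' Low-level constructor used for synthetic single-compartment scenes in
#' tests and examples.
#'
#' @param label_map integer matrix of compartment labels.
#' @param t1_map,t2_map relaxation-time matrices, ms.
#' @param pixel_size pixel edge length, mm.
#' @return a `ground_truth_maps` object.
#' @export
ground_truth_maps <- function(label_map, t1_map, t2_map, pixel_size = 1) {
  stopifnot(all(dim(label_map) == dim(t1_map)),
            all(dim(label_map) == dim(t2_map)))
  inside <- label_map > 0
  if (any(t1_map[inside] <= 0, na.rm = TRUE) ||
      any(t2_map[inside] <= 0, na.rm = TRUE)) {
    stop("truth invalid: non-positive T1/T2 inside compartments")
  }
  structure(list(label_map = label_map, t1_map = t1_map, t2_map = t2_map,
                 pixel_size = pixel_size, field = NA_character_,
                 tube_ids = NULL, tube_centers_mm = NULL,
                 tube_radius_mm = NA_real_),
            class = "ground_truth_maps")
}

#' Default per-compartment temperature coefficients
#'
#' Linear slopes of T1 and T2 versus temperature about the 22 degC
#' reference. T1 rises and T2 falls with temperature, and longer-T1/T2
#' compartments drift more, so the defaults are proportional to the
#' compartment's reference values: +1.0%/degC for T1 and -0.5%/degC for
#' T2.
#'
#' @param truth a `ground_truth_maps` object.
#' @return data frame with `label`, `dt1_dC` (ms/degC, >= 0) and
#'   `dt2_dC` (ms/degC, <= 0) for every compartment label present.
#' @export
default_temperature_coeffs <- function(truth) {
  stopifnot(inherits(truth, "ground_truth_maps"))
  labels <- sort(unique(truth$label_map[truth$label_map > 0]))
  t1_ref <- vapply(labels, function(l) {
    truth$t1_map[truth$label_map == l][1]
  }, numeric(1))
  t2_ref <- vapply(labels, function(l) {
    truth$t2_map[truth$label_map == l][1]
  }, numeric(1))
  data.frame(label = labels,
             dt1_dC = 0.010 * t1_ref,
             dt2_dC = -0.005 * t2_ref)
}

#' Apply a temperature offset to ground-truth maps
#'
#' Shifts each compartment's T1 up and T2 down linearly about the 22 degC
#' reference: `T1(temp) = T1_ref + dt1_dC * (temp - 22)` and analogously
#' for T2.
#'
#' @param truth a `ground_truth_maps` object (truth at 22 degC).
#' @param temperature_c target temperature, degC.
#' @param coeffs per-compartment slopes as returned by
#'   [default_temperature_coeffs()]; `dt1_dC` must be >= 0 and `dt2_dC`
#'   <= 0.
#' @return a new `ground_truth_maps` at `temperature_c`.
#' @export
apply_temperature <- function(truth, temperature_c,
                              coeffs = default_temperature_coeffs(truth)) {
  stopifnot(inherits(truth, "ground_truth_maps"))
  if (any(coeffs$dt1_dC < 0) || any(coeffs$dt2_dC > 0)) {
    stop("temperature coefficients must have dT1/dT >= 0 and dT2/dT <= 0")
  }
  dt <- temperature_c - 22
  out <- truth
  for (i in seq_len(nrow(coeffs))) {
    sel <- truth$label_map == coeffs$label[i]
    out$t1_map[sel] <- truth$t1_map[sel] + coeffs$dt1_dC[i] * dt
    out$t2_map[sel] <- truth$t2_map[sel] + coeffs$dt2_dC[i] * dt
  }
  inside <- out$label_map > 0
  if (any(out$t1_map[inside] <= 0) || any(out$t2_map[inside] <= 0)) {
    stop("temperature shift drives a relaxation time non-positive")
  }
  out
}

#' Field conditions: off-resonance and relative flip-angle maps
#'
#' `field_condition()` bundles a per-pixel B0 off-resonance map (Hz), a
#' per-pixel relative flip-angle (B1) map, the main field strength and
#' the temperature. `uniform_field_condition()` builds the design-target
#' condition (zero off-resonance, unit relative flip angle) and
#' `b1_droop_condition()` a smooth radial transmit-field droop preset
#' whose range mimics the stronger dielectric shading seen at 3 T
#' (relative flip angle 0.590-0.656 at 3 T vs 0.849-0.866 at 1.5 T).
#'
#' @param b0_offset_map matrix of off-resonance, Hz.
#' @param b1_relative_map matrix of relative flip angle (> 0).
#' @param field_strength_t main field, tesla.
#' @param temperature_c phantom temperature, degC.
#' @return a `field_condition` object.
#' @export
field_condition <- function(b0_offset_map, b1_relative_map,
                            field_strength_t = 1.5, temperature_c = 22) {
  stopifnot(all(dim(b0_offset_map) == dim(b1_relative_map)),
            field_strength_t > 0)
  if (any(b1_relative_map <= 0)) stop("b1_relative must be positive")
  structure(list(b0_offset_map = b0_offset_map,
                 b1_relative_map = b1_relative_map,
                 field_strength_t = field_strength_t,
                 temperature_c = temperature_c),
            class = "field_condition")
}

#' @rdname field_condition
#' @param truth a `ground_truth_maps` object fixing the map dimensions.
#' @param b0_hz constant off-resonance for the uniform condition, Hz.
#' @export
uniform_field_condition <- function(truth, field_strength_t = 1.5,
                                    b0_hz = 0) {
  dims <- dim(truth$label_map)
  field_condition(matrix(b0_hz, dims[1], dims[2]),
                  matrix(1, dims[1], dims[2]), field_strength_t)
}

#' @rdname field_condition
#' @export
b1_droop_condition <- function(truth, field_strength_t = 3) {
  dims <- dim(truth$label_map)
  rng <- if (field_strength_t >= 2) c(0.590, 0.656) else c(0.849, 0.866)
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  rmax2 <- (cx - 0.5)^2 + (cy - 0.5)^2
  d2 <- outer((seq_len(dims[1]) - cx)^2, (seq_len(dims[2]) - cy)^2, `+`)
  b1 <- rng[2] - (rng[2] - rng[1]) * d2 / rmax2
  field_condition(matrix(0, dims[1], dims[2]), b1, field_strength_t)
}
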