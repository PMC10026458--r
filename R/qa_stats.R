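## Phantom quality-assurance statistics: ROI extraction, bias vs
## spin-echo reference, coefficients of variation, reproducibility and
## temperature trends.

CORNER_TUBES <- c("A", "B", "F", "I")

as_tube_values <- function(x, arg = "values") {
  if (is.data.frame(x)) {
    stopifnot(all(c("tube_id", "value") %in% names(x)))
    setNames(x$value, x$tube_id)
  } else if (!is.null(names(x))) {
    x
  } else {
    stop(arg, " must be a named vector or a data frame with tube_id ",
         "and value columns")
  }
}

#' Place circular ROIs at the center of each tube
#'
#' ROI centers default to the tube-mask centroid (optionally shifted by
#' per-tube manual offsets) and the ROI radius is `shrink_fraction` of
#' the tube radius — the central 50% radius by default, i.e. 25% of the
#' tube area. An ROI that escapes its tube mask raises an error naming
#' the tube.
#'
#' @param truth a `ground_truth_maps` object from [rasterize_layout()].
#' @param shrink_fraction ROI radius as a fraction of the tube radius.
#' @param offsets optional data frame `tube_id`, `dx_mm`, `dy_mm` of
#'   manual center corrections.
#' @return a `tube_rois` list; each element has `tube_id`, `center_mm`,
#'   `radius_mm`, `pixels` (linear indices into the maps) and
#'   `pixel_count`.
#' @export
locate_tube_rois <- function(truth, shrink_fraction = 0.5,
                             offsets = NULL) {
  stopifnot(inherits(truth, "ground_truth_maps"),
            shrink_fraction > 0, shrink_fraction <= 1)
  ids <- truth$tube_ids
  if (is.null(ids) || length(ids) == 0) {
    return(structure(list(), class = "tube_rois"))
  }
  px <- truth$pixel_size
  dims <- dim(truth$label_map)
  xc <- (seq_len(dims[1]) - 0.5) * px
  yc <- (seq_len(dims[2]) - 0.5) * px
  radius_mm <- shrink_fraction * truth$tube_radius_mm
  rois <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- which(truth$label_map == i)
    if (length(sel) == 0) stop("tube ", ids[i], " has no pixels")
    rc <- arrayInd(sel, dims)
    center <- c(mean(xc[rc[, 1]]), mean(yc[rc[, 2]]))
    if (!is.null(offsets)) {
      j <- match(ids[i], offsets$tube_id)
      if (!is.na(j)) {
        center <- center + c(offsets$dx_mm[j], offsets$dy_mm[j])
      }
    }
    d2 <- outer((xc - center[1])^2, (yc - center[2])^2, `+`)
    pix <- which(d2 <= radius_mm^2)
    if (any(truth$label_map[pix] != i)) {
      stop("ROI for tube ", ids[i], " escapes its tube mask")
    }
    rois[[i]] <- list(tube_id = ids[i], center_mm = center,
                      radius_mm = radius_mm, pixels = pix,
                      pixel_count = length(pix))
  }
  structure(rois, class = "tube_rois")
}

#' Per-tube ROI statistics of a parameter map
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' converged pixels inside each ROI.
#'
#' @param map a `parameter_map`.
#' @param rois a `tube_rois` list from [locate_tube_rois()].
#' @return data frame `tube_id`, `mean`, `sd`, `n`. An ROI with no
#'   converged pixels yields an `NA` row with a warning.
#' @export
tube_statistics <- function(map, rois) {
  stopifnot(inherits(map, "parameter_map"))
  rows <- lapply(rois, function(roi) {
    v <- map$values[roi$pixels]
    if (!is.null(map$converged)) {
      v <- v[map$converged[roi$pixels] %in% TRUE]
    }
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warning("ROI for tube ", roi$tube_id, " has no converged pixels")
      return(data.frame(tube_id = roi$tube_id, mean = NA_real_,
                        sd = NA_real_, n = 0L))
    }
    data.frame(tube_id = roi$tube_id, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  })
  do.call(rbind, rows)
}

#' Bias of mapped T2 against the spin-echo reference
#'
#' Per-tube differences `mapped - reference` in ms and as a percentage of
#' the reference, plus group summaries over all tubes, the corner tubes
#' (`r paste(CORNER_TUBES, collapse = ", ")`) and the central tubes: the
#' mean absolute difference and the mean absolute difference expressed as
#' a percentage of the group's mean reference value.
#'
#' @param mapped,reference per-tube values (named numeric vectors or data
#'   frames with `tube_id`/`value`); ids must match.
#' @param corner_tubes ids forming the corner group.
#' @return list with `rows` (per-tube `tube_id`, `mapped`, `reference`,
#'   `diff`, `pct`) and `summary` (per-group `mean_abs_diff_ms`,
#'   `mean_pct`).
#' @examples
#' t2 <- table2_fixture()
#' t2 <- t2[t2$field_t == 1.5, ]
#' bias_table(setNames(t2$t2_bssfp_ms, t2$tube_id),
#'            setNames(t2$t2_se_ms, t2$tube_id))$summary
#' @export
bias_table <- function(mapped, reference, corner_tubes = CORNER_TUBES) {
  mapped <- as_tube_values(mapped, "mapped")
  reference <- as_tube_values(reference, "reference")
  if (!setequal(names(mapped), names(reference))) {
    stop("mapped and reference tube ids do not match")
  }
  reference <- reference[names(mapped)]
  rows <- data.frame(tube_id = names(mapped),
                     mapped = unname(mapped),
                     reference = unname(reference))
  rows$diff <- rows$mapped - rows$reference
  rows$pct <- 100 * rows$diff / rows$reference
  groups <- list(all = rows$tube_id,
                 corner = intersect(rows$tube_id, corner_tubes),
                 central = setdiff(rows$tube_id, corner_tubes))
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    sel <- rows$tube_id %in% groups[[g]]
    data.frame(group = g,
               n = sum(sel),
               mean_abs_diff_ms = mean(abs(rows$diff[sel])),
               mean_pct = 100 * mean(abs(rows$diff[sel])) /
                 mean(rows$reference[sel]))
  }))
  list(rows = rows, summary = summary)
}

#' Coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1 denominator) standard
#' deviation, including for two-point baseline/repeat pairs.
#'
#' @param values numeric vector of at least two values with non-zero
#'   mean.
#' @return CoV in percent.
#' @examples
#' coefficient_of_variation(c(56, 57))  # 1.25
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("CoV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CoV undefined: mean is zero")
  100 * sd(values) / m
}

#' Baseline vs repeat reproducibility table
#'
#' Per-tube absolute difference, percent difference (baseline
#' denominator) and two-point coefficient of variation between a baseline
#' and a repeat measurement.
#'
#' @param baseline,repeat_scan per-tube values (named vectors or
#'   `tube_id`/`value` data frames); ids must match.
#' @return data frame `tube_id`, `baseline`, `repeat_scan`, `abs_diff`,
#'   `pct_diff`, `cov`.
#' @export
reproducibility_table <- function(baseline, repeat_scan) {
  baseline <- as_tube_values(baseline, "baseline")
  repeat_scan <- as_tube_values(repeat_scan, "repeat_scan")
  if (!setequal(names(baseline), names(repeat_scan))) {
    stop("baseline and repeat tube ids do not match")
  }
  repeat_scan <- repeat_scan[names(baseline)]
  out <- data.frame(tube_id = names(baseline),
                    baseline = unname(baseline),
                    repeat_scan = unname(repeat_scan))
  out$abs_diff <- abs(out$repeat_scan - out$baseline)
  out$pct_diff <- 100 * out$abs_diff / out$baseline
  out$cov <- vapply(seq_len(nrow(out)), function(i) {
    coefficient_of_variation(c(out$baseline[i], out$repeat_scan[i]))
  }, numeric(1))
  out
}

#' Temperature trends of per-tube T1 and T2
#'
#' Least-squares slope of T1 and T2 versus temperature for each tube,
#' with sign flags. T1 is expected to rise and T2 to fall with
#' temperature.
#'
#' @param series data frame `tube_id`, `temperature_c`, `t1_ms`, `t2_ms`
#'   with at least three temperatures per tube.
#' @return data frame `tube_id`, `slope_t1_ms_per_c`,
#'   `slope_t2_ms_per_c`, `t1_increasing`, `t2_decreasing`.
#' @export
temperature_trend <- function(series) {
  stopifnot(all(c("tube_id", "temperature_c", "t1_ms", "t2_ms") %in%
                  names(series)))
  rows <- lapply(split(series, series$tube_id), function(df) {
    if (nrow(df) < 3) {
      stop("tube ", df$tube_id[1], ": need at least 3 temperatures")
    }
    s1 <- unname(coef(lm(t1_ms ~ temperature_c, data = df))[2])
    s2 <- unname(coef(lm(t2_ms ~ temperature_c, data = df))[2])
    data.frame(tube_id = df$tube_id[1],
               slope_t1_ms_per_c = s1, slope_t2_ms_per_c = s2,
               t1_increasing = s1 >= 0, t2_decreasing = s2 <= 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualify a phantom on its coefficients of variation
#'
#' A tube passes if its CoV does not exceed the threshold (boundary
#' inclusive, default 2.7%); the phantom passes if every tube passes.
#'
#' @param cov_values named numeric vector of per-tube CoV, percent.
#' @param threshold acceptance threshold, percent (> 0).
#' @return list with `per_tube` (data frame `tube_id`, `cov`, `pass`)
#'   and `overall_pass`.
#' @export
qualify_phantom <- function(cov_values, threshold = 2.7) {
  stopifnot(threshold > 0)
  per_tube <- data.frame(
    tube_id = if (is.null(names(cov_values)))
      as.character(seq_along(cov_values)) else names(cov_values),
    cov = unname(cov_values),
    pass = unname(cov_values <= threshold)
  )
  list(per_tube = per_tube, overall_pass = all(per_tube$pass),
       threshold = threshold)
}
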