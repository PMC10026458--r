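## Linear relaxivity model: ingredient concentrations -> relaxation rates.
##
## Rates are handled in 1/s from millisecond inputs (R = 1000/T), which keeps
## the fitted relaxivities near their literature magnitudes
## (~ 0.6-0.7 1/s/mM for Ni2+ on R1, ~ 10 1/s/% for agarose on R2).

#' Fit a linear relaxivity model from a calibration table
#'
#' Assumes relaxation \emph{rates} are linear in the ingredient
#' concentrations and fits, by ordinary least squares, the two planes
#' \deqn{R_1 = r_{1,0} + r_{1,Ni} [Ni^{2+}] + r_{1,ag} [agarose]}
#' \deqn{R_2 = r_{2,0} + r_{2,Ni} [Ni^{2+}] + r_{2,ag} [agarose]}
#' with rates in 1/s computed as \eqn{1000/T} from the millisecond T1/T2
#' columns at the requested field strength. Nickel chiefly drives
#' \eqn{R_1} and agarose chiefly drives \eqn{R_2}, but all four
#' relaxivities are estimated.
#'
#' @param calibration a `calibration_table` (see [calibration_fixture()]).
#' @param field one of `"1.4T"`, `"1.5T"`, `"3T"`: which measurement
#'   columns to fit.
#' @param include_outer logical; include the `outer` matrix-fill row when
#'   it has measurements at `field`. Defaults to `FALSE` (the outer fill
#'   contains HDPE beads and is not part of the tube recipe family).
#' @return a `relaxivity_model` list with intercept rates `r1_0`, `r2_0`
#'   (1/s), relaxivities `r1_ni`, `r2_ni` (1/s/mM), `r1_ag`, `r2_ag`
#'   (1/s/%), residual standard deviations `residual_sd_r1`,
#'   `residual_sd_r2` (1/s), and the number of calibration rows used.
#' @examples
#' model <- fit_relaxivity_model(calibration_fixture(), "1.4T")
#' model$r1_ni  # Ni relaxivity on R1, 1/s/mM
#' @export
fit_relaxivity_model <- function(calibration,
                                 field = c("1.4T", "1.5T", "3T"),
                                 include_outer = FALSE) {
  field <- match.arg(field)
  cols <- field_columns(field)
  df <- as.data.frame(calibration)
  if (!include_outer) df <- df[df$tube_id != "outer", , drop = FALSE]
  keep <- complete.cases(df[, c("agarose_pct", "ni_mM", cols)])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 3) {
    stop("need at least 3 complete calibration rows at ", field)
  }
  X <- cbind(1, df$ni_mM, df$agarose_pct)
  if (qr(X)$rank < 3) {
    stop("degenerate calibration: concentration rows are collinear")
  }
  r1 <- 1000 / df[[cols[["t1"]]]]
  r2 <- 1000 / df[[cols[["t2"]]]]
  fit1 <- lm(r1 ~ ni_mM + agarose_pct, data = df)
  fit2 <- lm(r2 ~ ni_mM + agarose_pct, data = df)
  model <- structure(list(
    field = field,
    temperature_c = if (field == "1.4T") 22 else NA_real_,
    r1_0 = unname(coef(fit1)[1]), r1_ni = unname(coef(fit1)[2]),
    r1_ag = unname(coef(fit1)[3]),
    r2_0 = unname(coef(fit2)[1]), r2_ni = unname(coef(fit2)[2]),
    r2_ag = unname(coef(fit2)[3]),
    residual_sd_r1 = sqrt(sum(resid(fit1)^2) / (nrow(df) - 3)),
    residual_sd_r2 = sqrt(sum(resid(fit2)^2) / (nrow(df) - 3)),
    n_rows = nrow(df),
    tube_ids = df$tube_id
  ), class = "relaxivity_model")
  if (any(!is.finite(unlist(model[c("r1_0", "r1_ni", "r1_ag",
                                    "r2_0", "r2_ni", "r2_ag")])))) {
    stop("relaxivity fit produced non-finite coefficients")
  }
  pred1 <- model$r1_0 + model$r1_ni * df$ni_mM + model$r1_ag * df$agarose_pct
  pred2 <- model$r2_0 + model$r2_ni * df$ni_mM + model$r2_ag * df$agarose_pct
  if (any(pred1 <= 0) || any(pred2 <= 0)) {
    warning("fitted model predicts non-positive rates for some ",
            "calibration rows")
  }
  model
}

#' @export
print.relaxivity_model <- function(x, ...) {
  cat(sprintf("Relaxivity model (%s, n = %d rows)\n", x$field, x$n_rows))
  cat(sprintf("  R1 [1/s] = %.4f + %.4f [Ni mM] + %.4f [agarose %%]  (sd %.4f)\n",
              x$r1_0, x$r1_ni, x$r1_ag, x$residual_sd_r1))
  cat(sprintf("  R2 [1/s] = %.4f + %.4f [Ni mM] + %.4f [agarose %%]  (sd %.4f)\n",
              x$r2_0, x$r2_ni, x$r2_ag, x$residual_sd_r2))
  invisible(x)
}

#' Predict T1/T2 from ingredient concentrations
#'
#' Forward evaluation of a fitted relaxivity model:
#' \eqn{T_1 = 1000 / (r_{1,0} + r_{1,Ni}[Ni] + r_{1,ag}[ag])} ms, and
#' analogously for T2.
#'
#' @param agarose_pct agarose mass fraction, % w/v (>= 0).
#' @param ni_mM NiCl2 concentration, mM (>= 0).
#' @param model a `relaxivity_model`.
#' @return list with elements `t1_ms` and `t2_ms`. A warning is issued if
#'   the prediction has T2 > T1 (unphysical for these gels).
#' @export
predict_relaxation <- function(agarose_pct, ni_mM, model) {
  stopifnot(inherits(model, "relaxivity_model"))
  if (any(agarose_pct < 0) || any(ni_mM < 0)) {
    stop("concentrations must be non-negative")
  }
  rate1 <- model$r1_0 + model$r1_ni * ni_mM + model$r1_ag * agarose_pct
  rate2 <- model$r2_0 + model$r2_ni * ni_mM + model$r2_ag * agarose_pct
  if (any(rate1 <= 0) || any(rate2 <= 0)) {
    stop("unphysical prediction: non-positive relaxation rate")
  }
  out <- list(t1_ms = 1000 / rate1, t2_ms = 1000 / rate2)
  if (any(out$t2_ms > out$t1_ms)) {
    warning("predicted T2 exceeds T1; outside the physical gel regime")
  }
  out
}

#' Design a tube recipe for target relaxation times
#'
#' Inverts the relaxivity model: solves the 2x2 linear system
#' \deqn{r_{1,Ni} x + r_{1,ag} y = 1000/T_1 - r_{1,0}}
#' \deqn{r_{2,Ni} x + r_{2,ag} y = 1000/T_2 - r_{2,0}}
#' for the nickel concentration \eqn{x} (mM) and agarose fraction \eqn{y}
#' (% w/v) that realize the target `t1_ms`/`t2_ms` pair.
#'
#' @param t1_ms,t2_ms target relaxation times in ms (> 0).
#' @param model a `relaxivity_model`.
#' @return list with `agarose_pct` and `ni_mM`.
#' @section Errors: a singular relaxivity slope matrix raises a
#'   non-invertible-model error; a solution with any negative
#'   concentration raises an infeasible-target error naming the violated
#'   ingredient bound.
#' @examples
#' model <- fit_relaxivity_model(calibration_fixture(), "1.4T")
#' design_recipe(600, 45, model)
#' @export
design_recipe <- function(t1_ms, t2_ms, model) {
  stopifnot(inherits(model, "relaxivity_model"), t1_ms > 0, t2_ms > 0)
  slopes <- matrix(c(model$r1_ni, model$r2_ni,
                     model$r1_ag, model$r2_ag), nrow = 2)
  scale <- max(abs(slopes))
  if (scale == 0 || abs(det(slopes)) < 1e-12 * scale^2) {
    stop("non-invertible model: relaxivity slope matrix is singular")
  }
  rhs <- c(1000 / t1_ms - model$r1_0, 1000 / t2_ms - model$r2_0)
  sol <- solve(slopes, rhs)
  ni <- sol[1]; ag <- sol[2]
  tol <- -1e-12
  if (ni < tol || ag < tol) {
    bad <- c(if (ni < tol) "nickel", if (ag < tol) "agarose")
    stop("infeasible target: solved ", paste(bad, collapse = " and "),
         " concentration is negative")
  }
  list(agarose_pct = max(ag, 0), ni_mM = max(ni, 0))
}

#' Leave-one-out prediction errors for a calibration table
#'
#' Refits the relaxivity model leaving each tube out in turn and reports
#' the prediction error on the held-out tube, a direct check of the
#' linear-rate assumption against the calibration measurements.
#'
#' @inheritParams fit_relaxivity_model
#' @return data frame with per-tube measured and predicted T1/T2 (ms) and
#'   their differences.
#' @export
loo_prediction_errors <- function(calibration,
                                  field = c("1.4T", "1.5T", "3T")) {
  field <- match.arg(field)
  cols <- field_columns(field)
  df <- as.data.frame(calibration)
  df <- df[df$tube_id != "outer", , drop = FALSE]
  df <- df[complete.cases(df[, c("agarose_pct", "ni_mM", cols)]), ,
           drop = FALSE]
  rows <- lapply(seq_len(nrow(df)), function(i) {
    m <- fit_relaxivity_model(df[-i, , drop = FALSE], field)
    p <- predict_relaxation(df$agarose_pct[i], df$ni_mM[i], m)
    data.frame(tube_id = df$tube_id[i],
               t1_meas = df[[cols[["t1"]]]][i], t1_pred = p$t1_ms,
               t2_meas = df[[cols[["t2"]]]][i], t2_pred = p$t2_ms)
  })
  out <- do.call(rbind, rows)
  out$t1_err <- out$t1_pred - out$t1_meas
  out$t2_err <- out$t2_pred - out$t2_meas
  out
}
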