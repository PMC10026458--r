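## Pixel-wise parameter-map reconstruction.

#' Construct a parameter map
#'
#' Per-pixel fitted parameter values with fit diagnostics. Pixels outside
#' the fitted mask or that failed to converge are `NA` with
#' `converged = FALSE`.
#'
#' @param values matrix of fitted parameter values (ms for T1/T2).
#' @param parameter_name name of the fitted parameter.
#' @param aux named list of auxiliary per-pixel matrices (amplitudes,
#'   apparent T1*, flip indices, ...).
#' @param rss matrix of residual sums of squares.
#' @param converged logical matrix of per-pixel convergence flags.
#' @param units units of `values`.
#' @param method name of the fitting method.
#' @param pixel_size pixel edge length, mm.
#' @return a `parameter_map` object.
#' @export
parameter_map <- function(values, parameter_name, aux = list(),
                          rss = NULL, converged = NULL, units = "ms",
                          method = NA_character_, pixel_size = 1) {
  structure(list(values = values, parameter_name = parameter_name,
                 aux = aux, rss = rss, converged = converged,
                 units = units, method = method,
                 pixel_size = pixel_size),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Parameter map: %s [%s], %d x %d pixels, %d converged\n",
              x$parameter_name, x$units, d[1], d[2],
              sum(x$converged, na.rm = TRUE)))
  invisible(x)
}

stack_matrix <- function(stack, mask) {
  dims <- dim(stack$frames)
  idx <- which(mask)
  Y <- matrix(NA_real_, dims[3], length(idx))
  for (k in seq_len(dims[3])) {
    fr <- stack$frames[, , k]
    Y[k, ] <- fr[idx]
  }
  list(Y = Y, idx = idx, dims = dims[1:2])
}

default_mask <- function(stack, threshold = 0) {
  peak <- apply(abs(stack$frames), c(1, 2), max)
  peak > threshold
}

fill_map <- function(dims, idx, vals) {
  m <- matrix(NA_real_, dims[1], dims[2])
  m[idx] <- vals
  m
}

order_frames <- function(stack) {
  ord <- order(stack$frame_parameter)
  stack$frames <- stack$frames[, , ord, drop = FALSE]
  stack$frame_parameter <- stack$frame_parameter[ord]
  stack
}

#' Fit a mono-exponential T2 decay pixel-wise
#'
#' Fits `S(t) = A * exp(-t / T2)` per pixel to a spin-echo (t = TE) or
#' T2-prepared (t = TEprep) stack by nonlinear least squares with a
#' deterministic global initialization (variable projection over a
#' log-spaced T2 grid, then Brent refinement). An optional three-parameter
#' variant `S(t) = A * exp(-t / T2) + C` is available but off by default:
#' the two-parameter model is the conventional product fit.
#'
#' @param stack an `image_stack` with sequence `SE` or `T2PREP_BSSFP` and
#'   at least two frames.
#' @param model `"2param"` (default) or `"3param"` (adds a constant
#'   offset).
#' @param mask logical matrix of pixels to fit; default: pixels with any
#'   positive signal.
#' @return a `parameter_map` of T2 (ms). Pixels whose signal is
#'   non-positive at every frame are marked unconverged, not errors.
#' @export
fit_t2_monoexponential <- function(stack, model = c("2param", "3param"),
                                   mask = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            stack$protocol$sequence %in% c("SE", "T2PREP_BSSFP"))
  model <- match.arg(model)
  stack <- order_frames(stack)
  if (dim(stack$frames)[3] < 2) stop("need at least 2 frames to fit T2")
  if (is.null(mask)) mask <- default_mask(stack)
  sm <- stack_matrix(stack, mask)
  fit <- fit_exp_core(sm$Y, stack$frame_parameter,
                      offset = (model == "3param"))
  parameter_map(
    values = fill_map(sm$dims, sm$idx,
                      ifelse(fit$converged, fit$tc, NA_real_)),
    parameter_name = "T2",
    aux = list(amplitude = fill_map(sm$dims, sm$idx, fit$amplitude),
               offset = fill_map(sm$dims, sm$idx, fit$offset)),
    rss = fill_map(sm$dims, sm$idx, fit$rss),
    converged = fill_map(sm$dims, sm$idx, as.numeric(fit$converged)) > 0,
    method = paste0("monoexp_", model),
    pixel_size = stack$pixel_size
  )
}

#' Fit a three-parameter inversion recovery pixel-wise
#'
#' Fits `|A - B * exp(-TI / T1)|` to magnitude IR data with polarity
#' restoration: every candidate flip index k (frames 1..k negated, frames
#' ordered by TI) is fitted and the candidate with the smallest residual
#' sum of squares wins, ties broken toward the smaller flip index.
#'
#' @param stack an `image_stack` with sequence `IR_GRE` and at least four
#'   frames.
#' @param mask logical matrix of pixels to fit.
#' @return a `parameter_map` of T1 (ms) with auxiliary `A`, `B` and
#'   `flip_index` maps.
#' @export
fit_t1_inversion_recovery <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            stack$protocol$sequence == "IR_GRE")
  stack <- order_frames(stack)
  if (dim(stack$frames)[3] < 4) stop("need at least 4 frames to fit IR T1")
  if (is.null(mask)) mask <- default_mask(stack)
  sm <- stack_matrix(stack, mask)
  fit <- fit_ir_core(sm$Y, stack$frame_parameter)
  parameter_map(
    values = fill_map(sm$dims, sm$idx,
                      ifelse(fit$converged, fit$tc, NA_real_)),
    parameter_name = "T1",
    aux = list(A = fill_map(sm$dims, sm$idx, fit$A),
               B = fill_map(sm$dims, sm$idx, fit$B),
               flip_index = fill_map(sm$dims, sm$idx, fit$flip_index)),
    rss = fill_map(sm$dims, sm$idx, fit$rss),
    converged = fill_map(sm$dims, sm$idx, as.numeric(fit$converged)) > 0,
    method = "ir_3param",
    pixel_size = stack$pixel_size
  )
}

#' Fit MOLLI T1 with Look-Locker correction pixel-wise
#'
#' Three-parameter fit `|A - B * exp(-TI / T1*)|` (with polarity
#' restoration, as for inversion recovery) followed by the Look-Locker
#' correction `T1 = T1* * (B/A - 1)`, which compensates the apparent
#' acceleration of recovery caused by the readout pulses. Pixels with
#' `B/A <= 1` have an undefined correction: they are flagged and keep
#' `NA` in `values`, while the apparent `t1_star` is always retained in
#' `aux`.
#'
#' @param stack an `image_stack` with sequence `MOLLI`.
#' @param mask logical matrix of pixels to fit.
#' @return a `parameter_map` of corrected T1 (ms) with auxiliary
#'   `t1_star`, `A`, `B` and `ll_valid` maps.
#' @export
fit_molli_t1 <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            stack$protocol$sequence == "MOLLI")
  stack <- order_frames(stack)
  if (is.null(mask)) mask <- default_mask(stack)
  sm <- stack_matrix(stack, mask)
  fit <- fit_ir_core(sm$Y, stack$frame_parameter)
  ratio <- fit$B / fit$A
  ll_valid <- is.finite(ratio) & ratio > 1 & fit$converged
  t1_corr <- ifelse(ll_valid, fit$tc * (ratio - 1), NA_real_)
  parameter_map(
    values = fill_map(sm$dims, sm$idx, t1_corr),
    parameter_name = "T1",
    aux = list(t1_star = fill_map(sm$dims, sm$idx, fit$tc),
               A = fill_map(sm$dims, sm$idx, fit$A),
               B = fill_map(sm$dims, sm$idx, fit$B),
               ll_valid = fill_map(sm$dims, sm$idx,
                                   as.numeric(ll_valid))),
    rss = fill_map(sm$dims, sm$idx, fit$rss),
    converged = fill_map(sm$dims, sm$idx, as.numeric(ll_valid)) > 0,
    method = "molli_ll",
    pixel_size = stack$pixel_size
  )
}

#' Reconstruct a parameter map from an image stack
#'
#' Dispatches to the fitter matching the stack's sequence. Background
#' pixels (label 0 in `truth`, if given, or signal never above
#' `threshold`) are excluded from fitting and flagged, not fitted.
#'
#' @param stack an `image_stack`.
#' @param method `"auto"` (dispatch on the protocol sequence) or one of
#'   `"t2_monoexp"`, `"ir"`, `"molli"`.
#' @param truth optional `ground_truth_maps`; pixels with label 0 are
#'   masked out.
#' @param threshold signal threshold for the default mask when no truth
#'   is given.
#' @return a `parameter_map`.
#' @export
reconstruct_map <- function(stack, method = c("auto", "t2_monoexp", "ir",
                                              "molli"),
                            truth = NULL, threshold = 0) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- switch(stack$protocol$sequence,
                     SE = "t2_monoexp", T2PREP_BSSFP = "t2_monoexp",
                     IR_GRE = "ir", MOLLI = "molli",
                     stop("no fitter for sequence ",
                          stack$protocol$sequence))
  }
  expected <- switch(method,
                     t2_monoexp = c("SE", "T2PREP_BSSFP"),
                     ir = "IR_GRE", molli = "MOLLI")
  if (!stack$protocol$sequence %in% expected) {
    stop("method ", method, " does not match sequence ",
         stack$protocol$sequence)
  }
  mask <- if (!is.null(truth)) {
    truth$label_map > 0
  } else {
    default_mask(stack, threshold)
  }
  switch(method,
         t2_monoexp = fit_t2_monoexponential(stack, mask = mask),
         ir = fit_t1_inversion_recovery(stack, mask = mask),
         molli = fit_molli_t1(stack, mask = mask))
}
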