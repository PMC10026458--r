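## NIfTI-1 + JSON-sidecar persistence for image stacks and parameter
## maps. One 3-D volume per stack (frames along the third axis); complex
## stacks store real and imaginary parts as consecutive volumes flagged
## in the sidecar. The sidecar carries everything needed to re-run the
## producing step: protocol, frame parameters, seed and noise level.

sidecar_path <- function(prefix) paste0(prefix, ".json")
volume_path <- function(prefix) paste0(prefix, ".nii")

protocol_to_list <- function(protocol) {
  unclass(protocol)
}

protocol_from_list <- function(p) {
  do.call(acquisition_protocol,
          c(list(sequence = p$sequence),
            p[setdiff(names(p), "sequence")]))
}

#' Write / read an image stack as NIfTI-1 plus JSON sidecar
#'
#' `write_stack()` writes `<prefix>.nii` (frames along the third axis;
#' complex data as real then imaginary volumes) and `<prefix>.json`
#' (protocol, frame parameters, seed, noise SD, units). The round trip
#' through `read_stack()` is lossless.
#'
#' @param stack an `image_stack`.
#' @param prefix output path prefix (no extension).
#' @return `write_stack()` returns `prefix` invisibly; `read_stack()`
#'   returns an `image_stack`.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "image_stack"))
  cplx <- is.complex(stack$frames)
  vol <- if (cplx) {
    d <- dim(stack$frames)
    arr <- array(0, c(d[1], d[2], 2 * d[3]))
    arr[, , seq_len(d[3])] <- Re(stack$frames)
    arr[, , d[3] + seq_len(d[3])] <- Im(stack$frames)
    arr
  } else {
    stack$frames
  }
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"),
                     volume_path(prefix))
  meta <- list(format = "phantomqa-stack", version = 1L,
               complex = cplx,
               n_frames = dim(stack$frames)[3],
               frame_parameter = stack$frame_parameter,
               frame_parameter_name = stack$frame_parameter_name,
               frame_parameter_units =
                 if (stack$frame_parameter_name == "nominal_angle")
                   "deg" else "ms",
               protocol = protocol_to_list(stack$protocol),
               noise_sd = stack$noise_sd,
               seed = stack$seed,
               pixel_size_mm = stack$pixel_size)
  jsonlite::write_json(meta, sidecar_path(prefix), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  sc <- sidecar_path(prefix)
  if (!file.exists(sc)) stop("format error: missing sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  vol <- as.array(RNifti::readNifti(volume_path(prefix)))
  vol <- array(as.vector(vol), dim(vol))   # drop NIfTI attributes
  if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1L)
  nf <- meta$n_frames
  if (isTRUE(meta$complex)) {
    if (dim(vol)[3] != 2 * nf) {
      stop("consistency error: frame count mismatch between volume and ",
           "sidecar")
    }
    frames <- array(complex(real = vol[, , seq_len(nf)],
                            imaginary = vol[, , nf + seq_len(nf)]),
                    c(dim(vol)[1:2], nf))
  } else {
    if (dim(vol)[3] != nf) {
      stop("consistency error: frame count mismatch between volume and ",
           "sidecar")
    }
    frames <- vol
  }
  if (length(meta$frame_parameter) != nf) {
    stop("consistency error: frame_parameter length does not match ",
         "frame count")
  }
  image_stack(frames, as.numeric(meta$frame_parameter),
              meta$frame_parameter_name,
              protocol_from_list(meta$protocol),
              noise_sd = meta$noise_sd,
              seed = if (is.null(meta$seed)) NULL else meta$seed,
              pixel_size = meta$pixel_size_mm)
}

#' Write / read a parameter map as NIfTI-1 plus JSON sidecar
#'
#' The volume stacks the value map, the residual sum of squares, the
#' convergence flags and every auxiliary map; the sidecar records the
#' volume order, parameter name, units and fit method.
#'
#' @param map a `parameter_map`.
#' @param prefix output path prefix (no extension).
#' @return `write_parameter_map()` returns `prefix` invisibly;
#'   `read_parameter_map()` returns a `parameter_map`.
#' @export
write_parameter_map <- function(map, prefix) {
  stopifnot(inherits(map, "parameter_map"))
  layers <- c(list(values = map$values,
                   rss = map$rss,
                   converged = map$converged * 1),
              map$aux)
  layers <- Filter(Negate(is.null), layers)
  vol <- array(NA_real_, c(dim(map$values), length(layers)))
  for (i in seq_along(layers)) vol[, , i] <- layers[[i]]
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"),
                     volume_path(prefix))
  meta <- list(format = "phantomqa-map", version = 1L,
               layers = names(layers),
               parameter_name = map$parameter_name,
               units = map$units, method = map$method,
               pixel_size_mm = map$pixel_size)
  jsonlite::write_json(meta, sidecar_path(prefix), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_parameter_map
#' @export
read_parameter_map <- function(prefix) {
  sc <- sidecar_path(prefix)
  if (!file.exists(sc)) stop("format error: missing sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  vol <- as.array(RNifti::readNifti(volume_path(prefix)))
  vol <- array(as.vector(vol), dim(vol))   # drop NIfTI attributes
  if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1L)
  if (dim(vol)[3] != length(meta$layers)) {
    stop("consistency error: layer count mismatch")
  }
  layers <- setNames(lapply(seq_along(meta$layers),
                            function(i) vol[, , i]), meta$layers)
  parameter_map(values = layers$values,
                parameter_name = meta$parameter_name,
                aux = layers[setdiff(names(layers),
                                     c("values", "rss", "converged"))],
                rss = layers$rss,
                converged = if (!is.null(layers$converged))
                  layers$converged > 0 else NULL,
                units = meta$units, method = meta$method,
                pixel_size = meta$pixel_size_mm)
}
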