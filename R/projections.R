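#' Orthogonally stack the line-scan frames into a volume
#'
#' Stacks the `n_positions` frames along x to form the oblique stack
#' volume (axes: stage position x, detector offset as depth proxy,
#' along-line y), the direct 3-D rendering of the raw acquisition. The
#' registered source-line (leakage) column is masked to zero. With
#' `shear_correct = TRUE` each offset row is re-indexed along x by
#' `offset * cot(oblique_deg)` to map the oblique sampling onto orthogonal
#' axes (useful for visualization; the MIP comparator uses the raw stack).
#'
#' @param stack a `flot_stack` with a registered source line.
#' @param shear_correct apply the oblique-to-orthogonal shear.
#' @param oblique_deg effective oblique angle of the stack, degrees.
#' @return A `flot_stackvol`: `$volume` of shape
#'   `(n_positions, n_offset, n_along)` plus axis metadata.
#' @export
orthogonal_stack <- function(stack, shear_correct = FALSE,
                             oblique_deg = 30) {
  stopifnot(inherits(stack, "flot_stack"))
  if (is.null(stack$source_col))
    stop("stack has no registered source line", call. = FALSE)
  v <- stack$frames
  v[, stack$source_col, ] <- 0
  if (shear_correct) {
    n1 <- dim(v)[1]; n3 <- dim(v)[3]
    shift_per_offset <- stack$acq$detector_pitch_mm /
      tan(oblique_deg * pi / 180) / stack$acq$stage_step
    for (d in seq_len(dim(v)[2])) {
      k <- as.integer(round((d - 1) * shift_per_offset))
      if (k == 0) next
      plane <- matrix(v[, d, ], n1, n3)
      newp <- matrix(0, n1, n3)
      if (k < n1) newp[(k + 1):n1, ] <- plane[1:(n1 - k), , drop = FALSE]
      v[, d, ] <- newp
    }
  }
  structure(list(volume = v, acq = stack$acq,
                 axes = c(x = "stage position", zproxy = "detector offset",
                          y = "along-line"),
                 shear_corrected = shear_correct,
                 oblique_deg = oblique_deg),
            class = "flot_stackvol")
}

#' @exportS3Method print flot_stackvol
print.flot_stackvol <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<flot_stackvol> %d x %d x %d%s\n", d[1], d[2], d[3],
              if (x$shear_corrected) " (shear-corrected)" else ""))
  invisible(x)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum of a nonnegative volume along the requested axes.
#' For a stack volume the axes are (x, z-proxy, y); for a reconstruction
#' volume (x, y, z). Projecting along "y" yields the XZ view; along "x"
#' the YZ view.
#'
#' @param volume a `flot_stackvol`, `flot_recon`, or 3-D array.
#' @param axes axes to project along; default both `"x"` and `"y"`.
#' @return Named list of projection matrices, one per requested axis.
#' @export
mip <- function(volume, axes = c("x", "y")) {
  v <- if (inherits(volume, "flot_stackvol")) volume$volume
       else if (inherits(volume, "flot_recon")) volume$volume
       else volume
  if (!is.array(v) || length(dim(v)) != 3 || length(v) == 0)
    stop("mip needs a non-empty 3-D volume", call. = FALSE)
  if (any(v < 0)) stop("mip needs a nonnegative volume", call. = FALSE)
  axes <- match.arg(axes, c("x", "y"), several.ok = TRUE)
  # axis layout: stackvol = (x, zproxy, y); recon = (x, y, z)
  is_stack <- inherits(volume, "flot_stackvol")
  out <- list()
  for (ax in axes) {
    marg <- if (is_stack) {
      if (ax == "y") c(1, 2) else c(2, 3)  # drop along-line / stage axis
    } else {
      if (ax == "y") c(1, 3) else c(2, 3)
    }
    out[[ax]] <- apply(v, marg, max)
  }
  out
}
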