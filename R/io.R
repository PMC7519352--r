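#' Write a measurement stack to multi-page TIFF with a JSON sidecar
#'
#' One 16-bit grayscale page per stage position (the container holds the
#' 12-bit data losslessly); the acquisition spec, source-line column and
#' metadata go to `<path>.json`.
#'
#' @param stack a `flot_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flot_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[1]), function(i)
    matrix(stack$frames[i, , ] / 65535, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(acq = unclass(stack$acq),
                  source_col = stack$source_col,
                  noiseless = stack$noiseless,
                  meta = stack$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a measurement stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar is `<path>.json`. A missing
#'   sidecar falls back to default acquisition parameters with a warning.
#' @return A `flot_stack` (bit-identical to what was written for integer
#'   data).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- lapply(pages, dim)
  ref <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], ref))
      stop("page ", i, " has size ", paste(dims[[i]], collapse = "x"),
           ", expected ", paste(ref, collapse = "x"), call. = FALSE)
  }
  frames <- array(0, c(length(pages), ref[1], ref[2]))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    acq <- do.call(acquisition_spec, side$acq[
      intersect(names(side$acq),
                names(formals(acquisition_spec)))])
    new_stack(frames, acq, source_col = side$source_col,
              noiseless = isTRUE(side$noiseless),
              meta = as.list(side$meta))
  } else {
    warning("missing sidecar ", side_path,
            ": using default acquisition parameters")
    acq <- acquisition_spec(n_positions = length(pages),
                            n_offset = ref[1], n_along = ref[2])
    new_stack(frames, acq)
  }
}

#' Write a reconstruction (or any volume) to multi-page TIFF (z pages)
#'
#' Values are scaled to the 16-bit range; the scale, lambda and grid go
#' to the JSON sidecar.
#' @param recon a `flot_recon` or 3-D array (x, y, z).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(recon, path) {
  v <- if (inherits(recon, "flot_recon")) recon$volume else recon
  vmax <- max(v, 1e-300)
  pages <- lapply(seq_len(dim(v)[3]), function(iz)
    matrix(v[, , iz] / vmax, dim(v)[1], dim(v)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(scale = vmax, dims = dim(v))
  if (inherits(recon, "flot_recon"))
    meta <- c(meta, list(lambda = recon$lambda, gamma = recon$gamma,
                         voxel_size_mm = recon$grid$voxel_size))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a decay curve as CSV (depth_um, intensity)
#' @param curve a `flot_decay`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve[c("depth_um", "intensity")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a decay curve CSV
#' @param path CSV with columns depth_um, intensity.
#' @param normalized whether the stored curve is already normalized.
#' @return A `flot_decay`.
#' @export
read_curve <- function(path, normalized = TRUE) {
  df <- utils::read.csv(path)
  new_decay_curve(df$depth_um, df$intensity, source = path,
                  normalized = normalized)
}
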