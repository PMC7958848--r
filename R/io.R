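#' Write / read a multichannel slide as TIFF plus JSON sidecar
#'
#' Channels are stored as pages of one 32-bit float TIFF, scaled into the
#' unit range by a factor recorded in the sidecar (`<path>.json`) together
#' with the channel names, pixel scale and slide id.
#'
#' @param slide a `slide_image`.
#' @param path TIFF file path.
#' @return `write_slide_tiff` returns `path` invisibly; `read_slide_tiff`
#'   returns a `slide_image`.
#' @export
write_slide_tiff <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  sf <- max(vapply(slide$channels, max, 0), 1)
  pages <- lapply(slide$channels, function(ch) pmax(ch, 0) / sf)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(
      slide_id = slide$slide_id,
      pixel_scale_um = slide$pixel_scale_um,
      channels = names(slide$channels),
      scale_factor = sf
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_slide_tiff
#' @export
read_slide_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == length(meta$channels))
  channels <- lapply(pages, function(p) p * meta$scale_factor)
  names(channels) <- meta$channels
  structure(
    list(
      channels = channels,
      pixel_scale_um = meta$pixel_scale_um,
      slide_id = meta$slide_id
    ),
    class = "slide_image"
  )
}

#' Write / read an IMC ROI stack as TIFF plus JSON sidecar
#'
#' Ion-count channels (one page per channel, the DNA intercalator last) and
#' the object/WBC masks are stored in one multipage TIFF; the sidecar names
#' the channels and carries the ROI annotations. Counts are recovered exactly
#' on read (integer ion counts well below the float-32 mantissa limit).
#'
#' @param roi an ROI stack (see [render_imc_rois()]).
#' @param path TIFF file path.
#' @return `write_imc_roi` returns `path` invisibly; `read_imc_roi` returns
#'   the ROI stack.
#' @export
write_imc_roi <- function(roi, path) {
  sf <- max(vapply(roi$channels, max, 0), 1)
  pages <- c(
    lapply(roi$channels, function(ch) ch / sf),
    list(object_mask = roi$object_mask * 1, wbc_mask = roi$wbc_mask * 1)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(
      roi_id = roi$roi_id, klass = roi$klass, patient_id = roi$patient_id,
      channels = names(roi$channels), scale_factor = sf,
      pixel_scale_um = roi$pixel_scale_um %||% 1, n_wbc = roi$n_wbc %||% NA
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_imc_roi
#' @export
read_imc_roi <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  stopifnot(length(pages) == nch + 2)
  channels <- lapply(pages[seq_len(nch)], function(p) {
    matrix(as.integer(round(p * meta$scale_factor)), nrow(p), ncol(p))
  })
  names(channels) <- meta$channels
  list(
    roi_id = meta$roi_id, klass = meta$klass, patient_id = meta$patient_id,
    object_mask = pages[[nch + 1]] > 0.5,
    wbc_mask = pages[[nch + 2]] > 0.5,
    channels = channels,
    pixel_scale_um = meta$pixel_scale_um,
    n_wbc = meta$n_wbc
  )
}
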