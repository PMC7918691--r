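#' Acquisition geometry of a live-imaging readout window
#'
#' Describes the camera field and sampling used for two-channel time-lapse
#' movies of axonal organelles in microfluidic channels. Defaults reproduce
#' the standard setup: a 512 x 512 px EMCCD at 229.55 nm/px imaged at
#' 3.3 frames per second per channel for 400 frames, viewing 117.53 um of a
#' 900 um microchannel.
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_size_nm Physical size of one pixel (nm).
#' @param frame_interval_s Time between consecutive frames of one channel (s).
#' @param n_frames Number of frames per channel.
#' @param channel_length_um Full microchannel length (um).
#' @param field_length_um Extent of the viewing field along the channel axis
#'   (um). Defaults to `width_px * pixel_size_nm / 1000`, rounded to 2
#'   decimals; if supplied it must agree with that product to within 0.01.
#'
#' @return An object of class `acquisition_geometry`: a list with the above
#'   fields plus `field_height_um`.
#' @examples
#' g <- acquisition_geometry()
#' g$field_length_um # 117.53
#' @export
acquisition_geometry <- function(width_px = 512L,
                                 height_px = 512L,
                                 pixel_size_nm = 229.55,
                                 frame_interval_s = 1 / 3.3,
                                 n_frames = 400L,
                                 channel_length_um = 900,
                                 field_length_um = NULL) {
  derived <- round(width_px * pixel_size_nm / 1000, 2)
  if (is.null(field_length_um)) {
    field_length_um <- derived
  } else if (abs(field_length_um - derived) > 0.01 + 1e-9) {
    stop("field_length_um (", field_length_um,
         ") inconsistent with width_px * pixel_size_nm (", derived, " um)")
  }
  vals <- c(width_px = width_px, height_px = height_px,
            pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s,
            n_frames = n_frames, channel_length_um = channel_length_um,
            field_length_um = field_length_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition geometry fields must be strictly positive")
  }
  structure(
    list(width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         pixel_size_nm = pixel_size_nm,
         pixel_size_um = pixel_size_nm / 1000,
         frame_interval_s = frame_interval_s,
         n_frames = as.integer(n_frames),
         channel_length_um = channel_length_um,
         field_length_um = field_length_um,
         field_height_um = round(height_px * pixel_size_nm / 1000, 2)),
    class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry> ", x$width_px, "x", x$height_px, " px, ",
      x$pixel_size_nm, " nm/px, ", round(1 / x$frame_interval_s, 2),
      " fps, ", x$n_frames, " frames; field ", x$field_length_um, " x ",
      x$field_height_um, " um of a ", x$channel_length_um,
      " um channel\n", sep = "")
  invisible(x)
}
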