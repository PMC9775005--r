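# Trace-to-image encoders: the merged three-trace grayscale chart and the
# per-channel binary RGB synthesis. Rasterization is an integer polyline
# (Bresenham-style) so every emitted plane is exactly two-valued, which is
# what lets a CNN see waveform geometry rather than grey-level artifacts.

#' Raster specification for trace images
#'
#' @param width,height Canvas size in pixels (minimum 32 each; default
#'   224 x 224, the input size the default backbone expects).
#' @param line_value Intensity of trace pixels (default 0, black).
#' @param background_value Intensity elsewhere (default 255, white).
#' @param draw_axes Draw a 1-pixel border frame (default `FALSE`).
#' @param antialias Placeholder for a smoothed rasterizer; only `FALSE` is
#'   supported, keeping every plane exactly two-valued.
#' @return An object of class `raster_spec`.
#' @export
raster_spec <- function(width = 224L, height = 224L, line_value = 0L,
                        background_value = 255L, draw_axes = FALSE,
                        antialias = FALSE) {
  if (width < 32 || height < 32) stop_invalid("canvas must be at least 32 x 32")
  if (line_value == background_value) {
    stop_invalid("line_value must differ from background_value")
  }
  for (v in c(line_value, background_value)) {
    if (v < 0 || v > 255) stop_invalid("intensities must lie in [0, 255]")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         line_value = as.integer(line_value),
         background_value = as.integer(background_value),
         draw_axes = isTRUE(draw_axes), antialias = isTRUE(antialias)),
    class = "raster_spec"
  )
}

# All pixel coordinates a 1-px polyline through (xs, ys) visits: for each
# segment, max(|dx|,|dy|)+1 evenly spaced steps rounded half-up. Integer
# endpoints in, integer pixels out; fully vectorized over segments.
.polyline_pixels <- function(xs, ys) {
  n_seg <- length(xs) - 1L
  if (n_seg < 1L) return(cbind(x = xs, y = ys))
  dx <- diff(xs); dy <- diff(ys)
  steps <- pmax(abs(dx), abs(dy))
  npts <- steps + 1L
  seg <- rep.int(seq_len(n_seg), npts)
  t_step <- sequence(npts) - 1L
  denom <- pmax(steps, 1L)
  px <- xs[seg] + floor(t_step * dx[seg] / denom[seg] + 0.5)
  py <- ys[seg] + floor(t_step * dy[seg] / denom[seg] + 0.5)
  cbind(x = as.integer(px), y = as.integer(py))
}

#' Rasterize one normalized trace into a binary bitmap
#'
#' Maps sample index linearly onto columns `0..width-1` and value onto rows
#' (1 at the top row, 0 at the bottom row), then draws a 1-pixel connected
#' polyline. Pixels on the polyline take `line_value`, all others
#' `background_value`, so the plane is exactly two-valued.
#'
#' @param trace Numeric vector of length >= 2 with values in \[0, 1\].
#' @param spec A [raster_spec()].
#' @return height x width integer matrix.
#' @export
render_trace_bitmap <- function(trace, spec = raster_spec()) {
  if (spec$antialias) stop_invalid("antialiased rasterization is not supported")
  if (length(trace) < 2L) stop_invalid("trace must have at least 2 samples")
  if (anyNA(trace) || any(!is.finite(trace))) {
    stop_invalid("trace contains NA or non-finite values")
  }
  if (min(trace) < -1e-9 || max(trace) > 1 + 1e-9) {
    stop_invalid("trace values must lie in [0, 1]")
  }
  trace <- pmin(pmax(trace, 0), 1)
  L <- length(trace)
  xs <- as.integer(floor((seq_len(L) - 1) * (spec$width - 1L) / (L - 1L) + 0.5))
  ys <- as.integer(floor((1 - trace) * (spec$height - 1L) + 0.5))
  img <- matrix(spec$background_value, nrow = spec$height, ncol = spec$width)
  px <- .polyline_pixels(xs, ys)
  img[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- spec$line_value
  if (spec$draw_axes) {
    img[c(1L, spec$height), ] <- spec$line_value
    img[, c(1L, spec$width)] <- spec$line_value
  }
  img
}

.encoded_image <- function(pixels, encoding, subject_id, label, window_index,
                           extra = list()) {
  structure(
    c(list(pixels = pixels, encoding = encoding, subject_id = subject_id,
           label = label, window_index = window_index), extra),
    class = "encoded_image"
  )
}

#' @export
print.encoded_image <- function(x, ...) {
  d <- dim(x$pixels)
  planes <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<encoded_image> %s %dx%dx%d (%s, window %s)\n",
              x$encoding, d[1], d[2], planes,
              x$subject_id, x$window_index))
  invisible(x)
}

#' Encode a window as the merged three-trace grayscale chart
#'
#' Draws the three channel traces in one grayscale plane, all at
#' `line_value`: per-channel colors are deliberately absent so a classifier
#' cannot key on color rather than waveform geometry.
#'
#' @param window 3 x L matrix with values in \[0, 1\].
#' @param spec A [raster_spec()].
#' @param subject_id,label,window_index Provenance metadata.
#' @return An `encoded_image` with a single plane.
#' @export
encode_merged_chart <- function(window, spec = raster_spec(),
                                subject_id = NA_character_,
                                label = NA_character_, window_index = NA_integer_) {
  if (!is.matrix(window) || nrow(window) != 3L) {
    stop_invalid("`window` must be a 3 x L matrix")
  }
  img <- matrix(spec$background_value, nrow = spec$height, ncol = spec$width)
  for (ch in 1:3) {
    plane <- render_trace_bitmap(window[ch, ], spec)
    img[plane == spec$line_value] <- spec$line_value
  }
  if (spec$draw_axes) {
    img[c(1L, spec$height), ] <- spec$line_value
    img[, c(1L, spec$width)] <- spec$line_value
  }
  .encoded_image(img, "merged_chart", subject_id, label, window_index)
}

#' Encode a window as the three-layer binary RGB synthesis
#'
#' Renders each channel into its own binary plane and stacks the planes as
#' R, G, B according to `channel_map`. A pixel covered by no trace is white
#' (255, 255, 255); a pixel covered only by the R-assigned channel is
#' (0, 255, 255), and so on. Axes are forbidden here: the coordinate frame
#' would contaminate all three planes identically.
#'
#' @param window 3 x L matrix with values in \[0, 1\] (rows Fp1, Fpz, Fp2).
#' @param spec A [raster_spec()] with `draw_axes = FALSE`.
#' @param channel_map Integer permutation of 1:3; `channel_map[p]` is the
#'   window row rendered into color plane p (R, G, B). Default `c(1, 2, 3)`:
#'   Fp1 to R, Fpz to G, Fp2 to B.
#' @param subject_id,label,window_index Provenance metadata.
#' @return An `encoded_image` with three planes and the channel map recorded.
#' @export
encode_rgb <- function(window, spec = raster_spec(), channel_map = c(1L, 2L, 3L),
                       subject_id = NA_character_, label = NA_character_,
                       window_index = NA_integer_) {
  if (!is.matrix(window) || nrow(window) != 3L) {
    stop_invalid("`window` must be a 3 x L matrix")
  }
  if (spec$draw_axes) {
    stop_invalid("RGB synthesis requires draw_axes = FALSE")
  }
  if (length(channel_map) != 3L || !setequal(channel_map, 1:3)) {
    stop_invalid("`channel_map` must be a permutation of 1:3")
  }
  pixels <- array(0L, dim = c(spec$height, spec$width, 3L))
  for (p in 1:3) {
    pixels[, , p] <- render_trace_bitmap(window[channel_map[p], ], spec)
  }
  .encoded_image(pixels, "rgb_synthesis", subject_id, label, window_index,
                 extra = list(channel_map = as.integer(channel_map),
                              line_value = spec$line_value,
                              background_value = spec$background_value))
}

#' Recover the per-channel trace masks from an RGB synthesis
#'
#' Inverse of the plane stacking in [encode_rgb()]: returns the three binary
#' planes in the original channel order (Fp1, Fpz, Fp2), bit-identical to
#' the [render_trace_bitmap()] outputs they came from.
#'
#' @param image An `encoded_image` with `encoding = "rgb_synthesis"`.
#' @return List of three height x width integer matrices.
#' @export
decode_rgb <- function(image) {
  if (!inherits(image, "encoded_image") || image$encoding != "rgb_synthesis") {
    stop_invalid("`image` must be an rgb_synthesis encoded_image")
  }
  lv <- image$line_value
  bv <- image$background_value
  vals <- unique(as.vector(image$pixels))
  if (!all(vals %in% c(lv, bv))) {
    stop_invalid("image planes are not strictly binary")
  }
  planes <- vector("list", 3L)
  for (p in 1:3) {
    planes[[image$channel_map[p]]] <- matrix(image$pixels[, , p],
                                             nrow = dim(image$pixels)[1])
  }
  names(planes) <- CHANNEL_NAMES
  planes
}

# Rescale a window per channel into [0, 1] for rendering. A channel that is
# constant within one window (no waveform to draw) maps to the mid row.
rescale_window <- function(window) {
  out <- window
  for (ch in seq_len(nrow(window))) {
    x <- window[ch, ]
    rng <- range(x)
    out[ch, ] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0.5
  }
  out
}

#' Encode a window set into images
#'
#' Rescales each filtered window per channel to \[0, 1\] (rendering needs
#' the full canvas height regardless of the window's absolute amplitude) and
#' encodes it with the chosen encoder.
#'
#' @param ws A `window_set` from [preprocess_recording()].
#' @param encoding `"merged"` or `"rgb"`.
#' @param spec A [raster_spec()].
#' @param channel_map Passed to [encode_rgb()].
#' @return List of `encoded_image` objects.
#' @export
encode_window_set <- function(ws, encoding = c("merged", "rgb"),
                              spec = raster_spec(), channel_map = c(1L, 2L, 3L)) {
  encoding <- match.arg(encoding)
  lapply(seq_along(ws$windows), function(k) {
    w <- rescale_window(ws$windows[[k]])
    if (encoding == "merged") {
      encode_merged_chart(w, spec, ws$subject_id, ws$label, k)
    } else {
      encode_rgb(w, spec, channel_map, ws$subject_id, ws$label, k)
    }
  })
}

#' Write an encoded image as a lossless 8-bit PNG
#'
#' @param image An `encoded_image`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a PNG back as pixel intensities in 0..255
#'
#' @param path PNG file path.
#' @return Integer matrix (grayscale) or height x width x 3 array (RGB).
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  round(px * 255)
}
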