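# Synthetic fluorescence stack generation and the image-analysis pipeline:
# illumination flattening, Scharr channel detection, width-averaged profile
# extraction, repeated Savitzky-Golay smoothing and main-channel
# normalization. Frames are plain numeric matrices [row, col]; the dead-end
# channel runs horizontally with its inlet on the left.

#' Time-stamped image stack
#'
#' @param frames List of 2D numeric matrices, all the same shape.
#' @param times Acquisition times, s; strictly increasing (one per frame).
#'   Acquisitions are log-spaced in time in the measurement protocol to limit
#'   photobleaching, but any increasing spacing is accepted.
#' @param pixel_size Pixel size, m/px.
#' @param channel_axis Orientation of the dead-end in the image; only
#'   `"horizontal"` (inlet left, closed end right) is supported.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, times, pixel_size,
                        channel_axis = "horizontal") {
  if (!length(frames)) stop("frames must be nonempty", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same shape", call. = FALSE)
  }
  if (length(times) != length(frames) || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame", call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (!identical(channel_axis, "horizontal")) {
    stop("only horizontal channel orientation is supported", call. = FALSE)
  }
  structure(list(frames = frames, times = times, pixel_size = pixel_size,
                 channel_axis = channel_axis),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.3g um/px, t = %.3g..%.3g s\n",
              length(x$frames), d[1], d[2], x$pixel_size * 1e6,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Optical settings for synthetic stack generation
#'
#' Describes the virtual UV autofluorescence microscope used by
#' [synthesize_stack()]: frame geometry, a smooth multiplicative illumination
#' bias, an ambient fluorescence baseline, per-frame photobleaching and
#' additive Gaussian read noise.
#'
#' @param n_rows Image height, px.
#' @param channel_rows Integer pair: first and last image row inside the
#'   dead-end channel.
#' @param inlet_col First image column of the dead-end; columns to its left
#'   image the main channel.
#' @param pixel_size Pixel size, m/px.
#' @param background_coef Six coefficients `(1, cx, cy, cx^2, cx*cy, cy^2)` of
#'   the second-order illumination surface on coordinates normalized to
#'   \[-1, 1\]; multiplies the whole frame.
#' @param base Ambient fluorescence level (arbitrary units) present
#'   everywhere, inside and outside the channel.
#' @param signal Fluorescence per unit relative protein concentration.
#' @param noise_sigma Additive Gaussian noise s.d. If `snr` is given instead,
#'   `noise_sigma = signal/snr` (noise relative to the main-channel protein
#'   signal).
#' @param snr Optional signal-to-noise ratio; overrides `noise_sigma`.
#' @param bleach_rate Photobleaching decay per frame exposure: frame k is
#'   attenuated by `exp(-bleach_rate * (k - 1))` (equal exposures; the
#'   log-spaced acquisition times keep the number of exposures small).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(n_rows = 120, channel_rows = c(36, 85),
                          inlet_col = 21, pixel_size = 1e-6,
                          background_coef = c(1, 0.15, -0.1, 0.08, 0.06, -0.12),
                          base = 0.08, signal = 0.4,
                          noise_sigma = 0, snr = NULL, bleach_rate = 0) {
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be positive", call. = FALSE)
    noise_sigma <- signal / snr
  }
  if (length(background_coef) != 6) {
    stop("background_coef must have 6 coefficients", call. = FALSE)
  }
  if (channel_rows[1] >= channel_rows[2]) {
    stop("channel_rows must be an increasing pair", call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows),
                 channel_rows = as.integer(channel_rows),
                 inlet_col = as.integer(inlet_col), pixel_size = pixel_size,
                 background_coef = background_coef, base = base,
                 signal = signal, noise_sigma = noise_sigma,
                 bleach_rate = bleach_rate),
            class = "optics_config")
}

.background_surface <- function(n_rows, n_cols, coef) {
  cy <- if (n_rows > 1) (seq_len(n_rows) - (n_rows + 1) / 2) / ((n_rows - 1) / 2) else 0
  cx <- if (n_cols > 1) (seq_len(n_cols) - (n_cols + 1) / 2) / ((n_cols - 1) / 2) else 0
  CY <- matrix(cy, n_rows, n_cols)
  CX <- matrix(cx, n_rows, n_cols, byrow = TRUE)
  coef[1] + coef[2] * CX + coef[3] * CY +
    coef[4] * CX^2 + coef[5] * CX * CY + coef[6] * CY^2
}

#' Render simulated states into a synthetic fluorescence stack
#'
#' Emulates the UV autofluorescence measurement: each simulated concentration
#' field is painted into the dead-end channel pixels (the main-channel strip
#' left of the inlet is held at the main-channel concentration), multiplied by
#' the illumination surface, attenuated by per-frame photobleaching, and
#' corrupted with additive Gaussian noise. Deterministic for a fixed seed.
#'
#' Frame value model:
#' `I = background(x, y) * (base + signal * N * exp(-bleach_rate * (k - 1))) + noise`.
#'
#' @param states List of `sim_state` (from [simulate_channel()] or
#'   [similarity_states()]); frame times are the state times.
#' @param optics An [optics_config].
#' @param seed Integer seed for the noise (required for determinism).
#' @param n_main Relative protein concentration in the main-channel strip;
#'   defaults to the value carried by `states`.
#' @return A `frame_stack`. The generator ground truth (channel rows, inlet
#'   column, per-frame profiles) is attached as attribute `"truth"`.
#' @export
synthesize_stack <- function(states, optics = optics_config(), seed = 1,
                             n_main = NULL) {
  if (!length(states)) stop("states must be nonempty", call. = FALSE)
  if (is.null(n_main)) {
    n_main <- attr(states, "n_main")
    if (is.null(n_main)) n_main <- 1
  }
  geom <- attr(states, "geometry")
  chan_len <- if (!is.null(geom)) geom$length else max(states[[1]]$x_centers)
  n_chan <- round(chan_len / optics$pixel_size)
  n_cols <- optics$inlet_col - 1L + n_chan
  n_rows <- optics$n_rows
  if (optics$channel_rows[2] > n_rows || n_cols < optics$inlet_col + 10) {
    stop("channel geometry exceeds frame bounds", call. = FALSE)
  }
  rows <- optics$channel_rows[1]:optics$channel_rows[2]
  x_px <- (seq_len(n_chan) - 0.5) * optics$pixel_size
  bg <- .background_surface(n_rows, n_cols, optics$background_coef)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  profiles <- matrix(NA_real_, length(states), n_chan)
  frames <- vector("list", length(states))
  for (k in seq_along(states)) {
    st <- states[[k]]
    Nx <- stats::approx(st$x_centers, st$protein, x_px, rule = 2)$y
    profiles[k, ] <- Nx
    conc <- matrix(0, n_rows, n_cols)
    # the main channel runs perpendicular to the dead-end: full image height
    conc[, seq_len(optics$inlet_col - 1L)] <- n_main
    conc[rows, optics$inlet_col - 1L + seq_len(n_chan)] <-
      matrix(Nx, length(rows), n_chan, byrow = TRUE)
    bleach <- exp(-optics$bleach_rate * (k - 1))
    frame <- bg * (optics$base + optics$signal * conc * bleach)
    if (optics$noise_sigma > 0) {
      frame <- frame + matrix(stats::rnorm(n_rows * n_cols, 0, optics$noise_sigma),
                              n_rows, n_cols)
    }
    frames[[k]] <- frame
  }
  stack <- frame_stack(frames, vapply(states, `[[`, numeric(1), "time"),
                       optics$pixel_size)
  attr(stack, "truth") <- list(channel_rows = optics$channel_rows,
                               inlet_col = optics$inlet_col,
                               x = x_px, profiles = profiles,
                               n_main = n_main, optics = optics)
  stack
}

# Scharr 3x3 derivative kernels (normalized)
.scharr_y <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3) / 32,
                    nrow = 3, byrow = TRUE)
.scharr_x <- t(.scharr_y)

#' Detect the dead-end channel in a frame
#'
#' Locates the two channel walls as the two strongest parallel responses of
#' the Scharr derivative across the channel, and the inlet as the strongest
#' along-channel edge inside the channel band (sub-pixel position by
#' parabolic interpolation; for the inlet this is the step between the bright
#' main-channel strip and the initially empty dead-end, so the frame should
#' be an early one).
#'
#' @param frame 2D numeric matrix.
#' @param min_separation Minimum wall separation, px.
#' @param min_confidence Detection fails (error) if the wall edge response is
#'   below `min_confidence` times the median row response.
#' @return An object of class `channel_detection`: `side_low`, `side_high`
#'   (first/last row inside the channel), `inlet` (first column of the
#'   dead-end, possibly fractional), `confidence`.
#' @export
detect_channel <- function(frame, min_separation = 5, min_confidence = 5) {
  stopifnot(is.matrix(frame))
  gy <- EBImage::filter2(frame, .scharr_y, boundary = "replicate")
  # signed average along the wall: incoherent noise cancels while the
  # coherent edge response survives
  row_resp <- abs(rowMeans(gy))
  med <- stats::median(row_resp)
  e1 <- .subpixel_max(row_resp)
  masked <- row_resp
  masked[pmax(1, round(e1$pos) - min_separation):
           pmin(length(masked), round(e1$pos) + min_separation)] <- -Inf
  e2 <- .subpixel_max(masked, values = row_resp)
  if (!is.finite(e2$value) ||
      min(e1$value, e2$value) < min_confidence * max(med, .Machine$double.eps)) {
    stop("channel detection failed: no channel-like edge response",
         call. = FALSE)
  }
  edges <- sort(c(e1$pos, e2$pos))
  # an edge response peaks on the boundary between the outside row and the
  # first in-channel row; the in-channel rows lie strictly between the edges
  side_low <- as.integer(round(edges[1] + 0.5))
  side_high <- as.integer(round(edges[2] - 0.5))
  conf <- min(e1$value, e2$value) / max(med, .Machine$double.eps)

  # inlet: strongest along-channel edge OUTSIDE the channel band, where the
  # perpendicular main channel ends against plain background; inside the band
  # the protein peak itself would bias the edge position
  out_rows <- setdiff(seq_len(nrow(frame)),
                      max(1L, side_low - 2L):min(nrow(frame), side_high + 2L))
  band <- frame[out_rows, , drop = FALSE]
  gx <- EBImage::filter2(band, .scharr_x, boundary = "replicate")
  col_resp <- abs(colMeans(gx))
  inlet <- .subpixel_max(col_resp)$pos + 0.5
  structure(list(side_low = side_low,
                 side_high = side_high,
                 inlet = inlet, confidence = conf),
            class = "channel_detection")
}

# position of the maximum of a response curve with parabolic sub-pixel
# refinement; `values` supplies the unmasked curve for the refinement
.subpixel_max <- function(resp, values = resp) {
  j <- which.max(resp)
  pos <- as.numeric(j)
  if (j > 1 && j < length(values)) {
    den <- values[j - 1] - 2 * values[j] + values[j + 1]
    if (den < 0) {
      shift <- 0.5 * (values[j - 1] - values[j + 1]) / den
      pos <- j + max(-0.5, min(0.5, shift))
    }
  }
  list(pos = pos, value = values[j])
}

#' @export
print.channel_detection <- function(x, ...) {
  cat(sprintf("<channel_detection> rows %d..%d, inlet col %.1f, confidence %.1f\n",
              x$side_low, x$side_high, x$inlet, x$confidence))
  invisible(x)
}

#' Flatten non-uniform illumination
#'
#' Fits a second-order two-dimensional polynomial to the pixels outside the
#' channel (the channel band plus a guard margin is excluded) and divides the
#' frame by the fitted surface, removing the multiplicative illumination
#' bias. If the in-channel intensity is much brighter than the outside
#' (median ratio above `fallback_ratio`) the background cannot be estimated
#' reliably and the frame is returned unmodified, with the fallback recorded
#' in the output attributes rather than raised as an error.
#'
#' @param frame 2D numeric matrix.
#' @param detection A [channel_detection] for this stack.
#' @param fallback_ratio In-channel/outside median ratio above which
#'   flattening is skipped.
#' @param margin Guard rows excluded around the channel, px.
#' @param mode `"divide"` (multiplicative bias, default) or `"subtract"`.
#' @return The flattened matrix with attributes `flattened` (logical),
#'   `fallback` (logical) and, when fitted, `background_fit` (the 6
#'   coefficients).
#' @export
flatten <- function(frame, detection, fallback_ratio = 10, margin = 2,
                    mode = c("divide", "subtract")) {
  stopifnot(is.matrix(frame), inherits(detection, "channel_detection"))
  mode <- match.arg(mode)
  n_rows <- nrow(frame); n_cols <- ncol(frame)
  guard_rows <- max(1L, detection$side_low - margin):
    min(n_rows, detection$side_high + margin)
  outside_rows <- setdiff(seq_len(n_rows), guard_rows)
  # the full-height main-channel band left of the inlet is fluorescent, not
  # background: exclude those columns from the fit region as well
  bg_cols <- seq_len(n_cols) >= ceiling(detection$inlet) + margin
  if (length(outside_rows) * sum(bg_cols) < 60) {
    stop("not enough outside-channel pixels for a 6-coefficient fit",
         call. = FALSE)
  }
  # protein brightness gauged on the main-channel strip, where protein is
  # always present; the dead-end itself is mostly empty at early times
  strip_cols <- seq_len(max(1L, floor(detection$inlet) - margin))
  inside <- frame[detection$side_low:detection$side_high, strip_cols,
                  drop = FALSE]
  ratio <- stats::median(inside) /
    max(stats::median(frame[outside_rows, bg_cols]), .Machine$double.eps)
  if (ratio > fallback_ratio) {
    out <- frame
    attr(out, "flattened") <- FALSE
    attr(out, "fallback") <- TRUE
    return(out)
  }
  cy <- (seq_len(n_rows) - (n_rows + 1) / 2) / ((n_rows - 1) / 2)
  cx <- (seq_len(n_cols) - (n_cols + 1) / 2) / ((n_cols - 1) / 2)
  CY <- matrix(cy, n_rows, n_cols)
  CX <- matrix(cx, n_rows, n_cols, byrow = TRUE)
  dat <- data.frame(I = as.vector(frame[outside_rows, bg_cols]),
                    cx = as.vector(CX[outside_rows, bg_cols]),
                    cy = as.vector(CY[outside_rows, bg_cols]))
  fit <- stats::lm(I ~ cx + cy + I(cx^2) + I(cx * cy) + I(cy^2), data = dat)
  surface <- matrix(stats::predict(fit, data.frame(cx = as.vector(CX),
                                                   cy = as.vector(CY))),
                    n_rows, n_cols)
  out <- if (mode == "divide") frame / surface else frame - surface + mean(surface)
  attr(out, "flattened") <- TRUE
  attr(out, "fallback") <- FALSE
  attr(out, "background_fit") <- stats::coef(fit)
  out
}

#' One-dimensional intensity profile along the dead-end
#'
#' @param x Positions along the channel from the inlet, m; strictly increasing.
#' @param intensity Intensity values (arbitrary units), finite.
#' @param time Acquisition time, s.
#' @param normalized Whether the profile has been normalized to the
#'   main-channel concentration scale.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(x, intensity, time, normalized = FALSE) {
  if (length(x) != length(intensity)) stop("x/intensity length mismatch", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (!all(is.finite(intensity))) stop("intensity must be finite", call. = FALSE)
  structure(list(x = x, intensity = intensity, time = time,
                 normalized = normalized),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> t = %g s, %d points over %.0f um%s\n",
              x$time, length(x$x), diff(range(x$x)) * 1e6,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Extract the width-averaged intensity profile
#'
#' Averages the intensity over the central fraction of the detected channel
#' width (wall-adjacent rows are excluded to avoid wall effects), for each
#' column from the inlet to the closed end, and subtracts the ambient
#' background level estimated from the outside-channel pixels so that the
#' profile is proportional to protein concentration.
#'
#' @param frame 2D numeric matrix (typically flattened).
#' @param detection A [channel_detection].
#' @param pixel_size Pixel size, m/px.
#' @param time Acquisition time attached to the profile, s.
#' @param center_fraction Fraction of the channel width averaged, centered.
#' @param background `"auto"` (median of outside-channel pixels), a number,
#'   or `NULL` to skip subtraction.
#' @return An [intensity_profile] with x = 0 at the inlet.
#' @export
extract_profile <- function(frame, detection, pixel_size, time = NA_real_,
                            center_fraction = 0.6, background = "auto") {
  stopifnot(is.matrix(frame), inherits(detection, "channel_detection"))
  width <- detection$side_high - detection$side_low + 1L
  n_center <- floor(width * center_fraction)
  if (n_center < 3) stop("central region narrower than 3 px", call. = FALSE)
  mid <- (detection$side_low + detection$side_high) / 2
  rows <- seq.int(ceiling(mid - n_center / 2 + 0.5),
                  length.out = n_center)
  first_col <- max(1L, as.integer(ceiling(detection$inlet)))
  cols <- first_col:ncol(frame)
  prof <- colMeans(frame[rows, cols, drop = FALSE])
  if (identical(background, "auto")) {
    outside <- setdiff(seq_len(nrow(frame)),
                       (detection$side_low - 2):(detection$side_high + 2))
    background <- stats::median(frame[outside, ])
  }
  if (!is.null(background)) prof <- prof - background
  x <- (cols - detection$inlet + 0.5) * pixel_size
  intensity_profile(x, prof, time)
}

#' Smooth a profile with a repeated Savitzky-Golay filter
#'
#' Local polynomial least-squares smoothing preserves peak shape while
#' suppressing pixel noise; repeating the filter strengthens the noise
#' reduction with little extra peak distortion.
#'
#' @param profile An [intensity_profile].
#' @param window Odd filter window length, points.
#' @param order Polynomial order, < window.
#' @param passes Number of filter applications (>= 1).
#' @return The smoothed [intensity_profile].
#' @export
smooth_profile <- function(profile, window = 11, order = 3, passes = 3) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (window %% 2 != 1 || order >= window || passes < 1) {
    stop("require odd window, order < window, passes >= 1", call. = FALSE)
  }
  y <- profile$intensity
  for (i in seq_len(passes)) y <- signal::sgolayfilt(y, p = order, n = window)
  out <- profile
  out$intensity <- y
  out
}

#' Main-channel reference intensity of a frame
#'
#' Median (background-subtracted) intensity in the main-channel strip: the
#' in-channel rows left of the inlet, where the protein concentration equals
#' the main-channel value. Used as the per-frame normalization reference.
#'
#' @inheritParams extract_profile
#' @param guard Columns next to the inlet excluded from the strip.
#' @return A single reference intensity.
#' @export
main_channel_reference <- function(frame, detection, guard = 2,
                                   background = "auto") {
  stopifnot(is.matrix(frame), inherits(detection, "channel_detection"))
  last_col <- floor(detection$inlet) - guard
  if (last_col < 1) stop("no main-channel columns left of the inlet", call. = FALSE)
  rows <- detection$side_low:detection$side_high
  ref <- stats::median(frame[rows, 1:last_col])
  if (identical(background, "auto")) {
    outside <- setdiff(seq_len(nrow(frame)),
                       (detection$side_low - 2):(detection$side_high + 2))
    background <- stats::median(frame[outside, ])
  }
  if (!is.null(background)) ref <- ref - background
  ref
}

#' Normalize profiles to the main-channel concentration scale
#'
#' Divides every profile by the median of the last five frames' main-channel
#' reference intensities. Using late frames makes the reference robust to the
#' initial flow transient, and the median is robust to a single outlier
#' frame.
#'
#' @param profiles List of [intensity_profile].
#' @param references Numeric vector of per-frame main-channel reference
#'   intensities (from [main_channel_reference()]), same length.
#' @return List of normalized profiles; the normalization constant is
#'   attached as attribute `"normalization"`.
#' @export
normalize_stack <- function(profiles, references) {
  if (length(profiles) < 5 || length(references) != length(profiles)) {
    stop("need >= 5 frames and one reference per profile", call. = FALSE)
  }
  ref <- stats::median(utils::tail(references, 5))
  if (!is.finite(ref) || ref <= 0) {
    stop("normalization reference is zero or negative", call. = FALSE)
  }
  out <- lapply(profiles, function(p) {
    p$intensity <- p$intensity / ref
    p$normalized <- TRUE
    p
  })
  attr(out, "normalization") <- ref
  out
}

#' Run the full image-analysis pipeline on a stack
#'
#' Channel and inlet detection on the first frame (sides re-checked on every
#' frame), per-frame flattening, width-averaged profile extraction, repeated
#' Savitzky-Golay smoothing, and normalization by the late-frame main-channel
#' reference.
#'
#' @param stack A [frame_stack].
#' @param center_fraction Passed to [extract_profile()].
#' @param window,order,passes Passed to [smooth_profile()].
#' @param fallback_ratio Passed to [flatten()].
#' @param flatten_mode Passed to [flatten()].
#' @return List of normalized [intensity_profile]s with attribute
#'   `"metadata"`: detection, filter settings, normalization constant and
#'   per-frame flattening fallback flags.
#' @export
analyze_stack <- function(stack, center_fraction = 0.6, window = 11,
                          order = 3, passes = 3, fallback_ratio = 10,
                          flatten_mode = "divide") {
  stopifnot(inherits(stack, "frame_stack"))
  detection <- detect_channel(stack$frames[[1]])
  fallbacks <- logical(length(stack$frames))
  profiles <- vector("list", length(stack$frames))
  references <- numeric(length(stack$frames))
  for (k in seq_along(stack$frames)) {
    fl <- flatten(stack$frames[[k]], detection, fallback_ratio = fallback_ratio,
                  mode = flatten_mode)
    fallbacks[k] <- isTRUE(attr(fl, "fallback"))
    p <- extract_profile(fl, detection, stack$pixel_size,
                         time = stack$times[k],
                         center_fraction = center_fraction)
    profiles[[k]] <- smooth_profile(p, window = window, order = order,
                                    passes = passes)
    references[k] <- main_channel_reference(fl, detection)
  }
  out <- normalize_stack(profiles, references)
  attr(out, "metadata") <- list(
    detection = detection,
    filter = list(window = window, order = order, passes = passes),
    center_fraction = center_fraction,
    normalization = attr(out, "normalization"),
    flatten_fallback = fallbacks)
  out
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are affinely mapped into \[0, 1\] for 32-bit TIFF storage; the
#' offset and scale are recorded in the sidecar (keys `times_s`,
#' `pixel_size_m`, `offset`, `scale`) and undone on reading.
#'
#' @param stack A [frame_stack].
#' @param tiff_path Output TIFF path.
#' @param sidecar_path Output JSON path (default: TIFF path with `.json`).
#' @return `tiff_path`, invisibly (write); a [frame_stack] (read).
#' @export
write_stack <- function(stack, tiff_path,
                        sidecar_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stack, "frame_stack"))
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  scale <- max(hi - lo, .Machine$double.eps)
  scaled <- lapply(stack$frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(scaled, tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(list(times_s = stack$times,
                            pixel_size_m = stack$pixel_size,
                            offset = lo, scale = scale,
                            channel_axis = stack$channel_axis),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_stack
#' @export
read_stack <- function(tiff_path, sidecar_path = paste0(tiff_path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  frames <- lapply(pages, function(f) f * meta$scale + meta$offset)
  frame_stack(frames, meta$times_s, meta$pixel_size_m)
}

#' Export profiles as CSV with a JSON metadata block
#'
#' CSV columns: `time_s, x_m, intensity`; the metadata (detection, filter
#' settings, normalization constant, fallback flags) goes to a JSON file.
#'
#' @param profiles List of [intensity_profile] (e.g. from [analyze_stack()]).
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path (default: CSV path with `.json`).
#' @return `csv_path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, csv_path,
                               json_path = paste0(csv_path, ".json")) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(time_s = p$time, x_m = p$x, intensity = p$intensity)
  }))
  utils::write.csv(df, csv_path, row.names = FALSE)
  meta <- attr(profiles, "metadata")
  if (!is.null(meta)) {
    meta$detection <- unclass(meta$detection)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Read profiles back from CSV
#'
#' @param csv_path CSV written by [write_profiles_csv()].
#' @param normalized Whether the stored intensities are normalized.
#' @return List of [intensity_profile].
#' @export
read_profiles_csv <- function(csv_path, normalized = TRUE) {
  df <- utils::read.csv(csv_path)
  lapply(split(df, df$time_s), function(d) {
    intensity_profile(d$x_m, d$intensity, d$time_s[1], normalized = normalized)
  })
}
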