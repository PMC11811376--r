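#' Heatmap channel and stack containers
#'
#' A channel holds one landmark's nonnegative response grid together with the
#' affine mapping to the image frame: \code{image = origin_offset +
#' channel_pos / scale}. The response matrix is indexed \code{[y + 1, x + 1]}
#' (rows = y, columns = x, both 0-based in coordinates).
#'
#' @param response numeric H x W matrix, finite and nonnegative, H, W >= 3.
#' @param origin_offset image-frame coordinates (x0, y0) of channel pixel
#'   (0, 0).
#' @param scale channel pixels per image pixel (positive, isotropic).
#' @param landmark_index integer 1..22.
#' @param sigma_hint optional: the Gaussian width the channel was rendered
#'   with, if known.
#' @return an object of class \code{"heatmap_channel"}.
#' @export
heatmap_channel <- function(response, origin_offset = c(0, 0), scale = 1,
                            landmark_index = 1L, sigma_hint = NULL) {
  response <- as.matrix(response)
  if (nrow(response) < 3L || ncol(response) < 3L)
    stop("channel grid must be at least 3 x 3", call. = FALSE)
  if (!all(is.finite(response)) || any(response < 0))
    stop("channel responses must be finite and nonnegative", call. = FALSE)
  stopifnot(is.numeric(origin_offset), length(origin_offset) == 2L,
            is.numeric(scale), length(scale) == 1L, scale > 0,
            length(landmark_index) == 1L, landmark_index %in% 1:N_LANDMARKS)
  structure(list(response = response,
                 origin_offset = as.numeric(origin_offset),
                 scale = as.numeric(scale),
                 landmark_index = as.integer(landmark_index),
                 sigma_hint = sigma_hint),
            class = "heatmap_channel")
}

#' @rdname heatmap_channel
#' @param channels list of 22 \code{heatmap_channel}s covering landmark
#'   indices 1..22 (any order; they are slotted by index).
#' @param image_id identifier string.
#' @param pixel_spacing_mm optional mm per image pixel.
#' @export
heatmap_stack <- function(channels, image_id = "image",
                          pixel_spacing_mm = NULL) {
  stopifnot(is.list(channels), length(channels) == N_LANDMARKS)
  idx <- vapply(channels, function(ch) ch$landmark_index, 1L)
  if (!setequal(idx, 1:N_LANDMARKS))
    stop("stack must contain exactly one channel per landmark index 1..22",
         call. = FALSE)
  structure(list(channels = channels[order(idx)],
                 image_id = image_id,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "heatmap_stack")
}

#' @export
print.heatmap_stack <- function(x, ...) {
  dims <- vapply(x$channels, function(ch) paste(dim(ch$response), collapse = "x"), "")
  cat(sprintf("Heatmap stack '%s': 22 channels (%s)\n",
              x$image_id, paste(unique(dims), collapse = ", ")))
  invisible(x)
}

#' Render an isotropic Gaussian response
#'
#' \code{response(x, y) = exp(-((x - cx)^2 + (y - cy)^2) / (2 sigma^2))},
#' peak amplitude 1, evaluated at the channel grid nodes.
#'
#' @param center channel-frame coordinates (cx, cy) of the peak.
#' @param sigma Gaussian width in channel pixels, positive.
#' @param height,width grid dimensions.
#' @param ... passed to [heatmap_channel()] (offset, scale, landmark index).
#' @return a \code{heatmap_channel}; \code{sigma_hint} is recorded.
#' @export
render_gaussian <- function(center, sigma, height, width, ...) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar", call. = FALSE)
  stopifnot(length(center) == 2L, all(is.finite(center)))
  xs <- 0:(width - 1L)
  ys <- 0:(height - 1L)
  r <- outer((ys - center[2L])^2, (xs - center[1L])^2, `+`)
  heatmap_channel(exp(-r / (2 * sigma^2)), sigma_hint = sigma, ...)
}

# replicate-padded 3x3 Sobel, kernels scaled by 1/8 so the result
# approximates the true partial derivatives on the grid spacing
sobel_gradients <- function(r) {
  p <- rbind(r[1L, , drop = FALSE], r, r[nrow(r), , drop = FALSE])
  p <- cbind(p[, 1L, drop = FALSE], p, p[, ncol(p), drop = FALSE])
  H <- nrow(r); W <- ncol(r)
  sh <- function(dy, dx) p[(2L + dy):(H + 1L + dy), (2L + dx):(W + 1L + dx)]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L) -
         sh(-1L, -1L) - 2 * sh(0L, -1L) - sh(1L, -1L)) / 8
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L) -
         sh(-1L, -1L) - 2 * sh(-1L, 0L) - sh(-1L, 1L)) / 8
  list(gx = gx, gy = gy)
}

#' Sobel gradient magnitude and orientation of a heatmap channel
#'
#' Computes the gradient field that drives the landmark update step. The
#' channel is optionally max-normalized first (making the field invariant to
#' the channel's overall response amplitude), then 3x3 Sobel kernels scaled
#' by 1/8 are applied with replicated borders. Orientation points toward
#' increasing response, in radians in (-pi, pi], measured in the channel
#' array frame (x = columns rightward, y = rows downward).
#'
#' @param channel a \code{heatmap_channel}.
#' @param normalize divide the response by its maximum first (default TRUE;
#'   a no-op for an all-zero channel).
#' @return an object of class \code{"gradient_field"} with matrices \code{M}
#'   (magnitudes, >= 0) and \code{O} (orientations).
#' @export
compute_gradient_field <- function(channel, normalize = TRUE) {
  r <- channel$response
  if (normalize) {
    mx <- max(r)
    if (mx > 0) r <- r / mx
  }
  g <- sobel_gradients(r)
  structure(list(M = sqrt(g$gx^2 + g$gy^2), O = atan2(g$gy, g$gx),
                 gx = g$gx, gy = g$gy),
            class = "gradient_field")
}

#' Sample a gradient field at a subpixel position
#'
#' Bilinearly interpolates the Cartesian gradient components
#' \code{(M cos O, M sin O)} at \code{pos} and converts back to magnitude and
#' orientation. Angles are never interpolated directly (ill-defined across
#' the +/- pi cut).
#'
#' @param field a \code{gradient_field}.
#' @param pos channel-frame coordinates (x, y) within
#'   \code{[0, W-1] x [0, H-1]}.
#' @return named numeric vector \code{c(m_h = ..., o_h = ...)}.
#' @export
sample_gradient <- function(field, pos) {
  H <- nrow(field$M); W <- ncol(field$M)
  x <- pos[1L]; y <- pos[2L]
  if (!is.finite(x) || !is.finite(y) ||
      x < 0 || x > W - 1L || y < 0 || y > H - 1L)
    stop("position outside channel bounds", call. = FALSE)
  x0 <- min(floor(x), W - 2L); y0 <- min(floor(y), H - 2L)
  fx <- x - x0; fy <- y - y0
  ix <- x0 + 1L; iy <- y0 + 1L  # matrix indices
  wts <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  # cached Cartesian components if the field carries them, else from (M, O)
  gx <- if (!is.null(field$gx)) field$gx else field$M * cos(field$O)
  gy <- if (!is.null(field$gy)) field$gy else field$M * sin(field$O)
  vx <- sum(wts * c(gx[iy, ix], gx[iy, ix + 1L],
                    gx[iy + 1L, ix], gx[iy + 1L, ix + 1L]))
  vy <- sum(wts * c(gy[iy, ix], gy[iy, ix + 1L],
                    gy[iy + 1L, ix], gy[iy + 1L, ix + 1L]))
  c(m_h = sqrt(vx^2 + vy^2), o_h = atan2(vy, vx))
}

#' Map between channel-frame and image-frame coordinates
#'
#' \code{image = origin_offset + channel_pos / scale} and its inverse.
#'
#' @param pos length-2 coordinates (x, y).
#' @param channel a \code{heatmap_channel}.
#' @return length-2 coordinates in the other frame.
#' @export
channel_to_image <- function(pos, channel) {
  channel$origin_offset + pos / channel$scale
}

#' @rdname channel_to_image
#' @export
image_to_channel <- function(pos, channel) {
  (pos - channel$origin_offset) * channel$scale
}

# grid argmax of one channel, channel-frame 0-based coordinates;
# ties broken by the smallest row-major index (scan rows first)
channel_argmax <- function(channel) {
  r <- channel$response
  H <- nrow(r); W <- ncol(r)
  mx <- max(r)
  hits <- which(r == mx)            # column-major linear indices
  ys <- (hits - 1L) %% H            # 0-based row
  xs <- (hits - 1L) %/% H           # 0-based column
  j <- which.min(ys * W + xs)       # row-major rank
  c(xs[j], ys[j])
}

#' Initial landmark detection by per-channel argmax
#'
#' Each landmark starts at the grid point with the highest response of its
#' channel, mapped into the image frame. Ties are broken by the smallest
#' row-major index. An all-zero channel yields the channel center and is
#' flagged undetected.
#'
#' @param stack a \code{heatmap_stack}.
#' @return a \code{landmarks} object with a logical attribute
#'   \code{"undetected"} of length 22.
#' @export
detect_initial <- function(stack) {
  stopifnot(inherits(stack, "heatmap_stack"))
  pts <- matrix(NA_real_, N_LANDMARKS, 2L)
  undetected <- logical(N_LANDMARKS)
  for (k in seq_len(N_LANDMARKS)) {
    ch <- stack$channels[[k]]
    if (max(ch$response) == 0) {
      undetected[k] <- TRUE
      ctr <- c(ncol(ch$response) - 1L, nrow(ch$response) - 1L) / 2
      pts[k, ] <- channel_to_image(ctr, ch)
    } else {
      pts[k, ] <- channel_to_image(channel_argmax(ch), ch)
    }
  }
  out <- landmarks(pts, pixel_spacing_mm = stack$pixel_spacing_mm)
  attr(out, "undetected") <- undetected
  out
}
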