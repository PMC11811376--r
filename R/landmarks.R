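#' hasm: heatmap-based active shape model for lumbar spine landmarks
#'
#' The package corrects the 22 standard lumbar-spine landmarks (the four
#' corners of each vertebra L1-L5 plus the two endpoints of the sacral upper
#' endplate) from per-landmark heatmap responses. See
#' \code{vignette("hasm-methods")} for the model and its assumptions.
#'
#' @section Coordinate convention:
#' All coordinates are continuous pixels in a 0-based grid with pixel centers
#' at integer coordinates; x increases rightward (columns) and y increases
#' downward (rows). Heatmap channels live on their own grid related to the
#' image frame by an affine offset and isotropic scale.
#'
#' @docType package
#' @name hasm-package
#' @aliases hasm
#' @keywords internal
#' @importFrom stats coef predict simulate
#' @importFrom graphics plot
"_PACKAGE"

N_LANDMARKS <- 22L

#' Construct a landmark set
#'
#' A landmark set is an ordered 22 x 2 matrix of subpixel image coordinates in
#' the canonical order: for vertebra j in 1..5 (L1..L5), rows 4(j-1)+1..4j are
#' upper-left, upper-right, lower-left, lower-right; rows 21 and 22 are the
#' left and right endpoints of the S1 upper endplate.
#'
#' @param points numeric 22 x 2 matrix (columns x, y), or anything coercible.
#' @param pixel_spacing_mm optional positive scalar, millimeters per pixel.
#' @param label optional, one of \code{"normal"} or \code{"spondylolisthesis"}.
#' @return an object of class \code{"landmarks"}.
#' @export
landmarks <- function(points, pixel_spacing_mm = NULL, label = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != N_LANDMARKS || ncol(points) != 2L)
    stop("'points' must be a numeric ", N_LANDMARKS, " x 2 matrix", call. = FALSE)
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  if (!is.null(pixel_spacing_mm)) {
    stopifnot(is.numeric(pixel_spacing_mm), length(pixel_spacing_mm) == 1L,
              pixel_spacing_mm > 0)
  }
  if (!is.null(label))
    label <- match.arg(label, c("normal", "spondylolisthesis"))
  structure(points, class = "landmarks",
            pixel_spacing_mm = pixel_spacing_mm, label = label)
}

#' @export
print.landmarks <- function(x, ...) {
  lab <- attr(x, "label")
  sp <- attr(x, "pixel_spacing_mm")
  cat("Lumbar landmark set (22 points",
      if (!is.null(lab)) paste0(", ", lab),
      if (!is.null(sp)) sprintf(", %.3f mm/px", sp), ")\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

is_landmarks <- function(x) inherits(x, "landmarks")

#' Row indices of the landmarks belonging to one vertebral element
#'
#' @param v integer 1..6; 1..5 select the four corners of L1..L5, 6 selects
#'   the two S1 endplate endpoints.
#' @return integer vector of row indices into a landmark set.
#' @export
vertebra_indices <- function(v) {
  stopifnot(length(v) == 1L, v %in% 1:6)
  if (v <= 5L) (4L * (v - 1L) + 1L):(4L * v) else 21:22
}

#' Flatten a landmark set into a 44-element shape vector
#'
#' Layout is (x1, ..., x22, y1, ..., y22).
#'
#' @param lm a \code{landmarks} object (or 22 x 2 matrix).
#' @return numeric vector of length 44.
#' @seealso [as_landmarks()]
#' @export
as_shape_vector <- function(lm) {
  m <- unclass(lm)
  if (!is.matrix(m) || nrow(m) != N_LANDMARKS || ncol(m) != 2L)
    stop("expected a 22 x 2 landmark matrix", call. = FALSE)
  c(m[, 1L], m[, 2L])
}

#' Reshape a 44-element shape vector into a landmark set
#'
#' @param v numeric vector of length 44, layout (x1..x22, y1..y22).
#' @param pixel_spacing_mm,label passed to [landmarks()].
#' @return a \code{landmarks} object.
#' @export
as_landmarks <- function(v, pixel_spacing_mm = NULL, label = NULL) {
  if (!is.numeric(v) || length(v) != 2L * N_LANDMARKS)
    stop("shape vector must have length 44", call. = FALSE)
  landmarks(cbind(v[1:N_LANDMARKS], v[(N_LANDMARKS + 1L):(2L * N_LANDMARKS)]),
            pixel_spacing_mm = pixel_spacing_mm, label = label)
}

# shape-vector helpers used throughout: a shape vector is (x..., y...)
sv_xy <- function(v) {
  n <- length(v) / 2L
  cbind(v[seq_len(n)], v[n + seq_len(n)])
}

sv_centroid <- function(v) {
  n <- length(v) / 2L
  c(mean(v[seq_len(n)]), mean(v[n + seq_len(n)]))
}

sv_center <- function(v) {
  n <- length(v) / 2L
  ctr <- sv_centroid(v)
  v - rep(ctr, each = n)
}
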