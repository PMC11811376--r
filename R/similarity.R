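#' Similarity transforms in the plane
#'
#' A similarity transform maps a point p to \code{s * R(theta) p + t}, with
#' positive scale and no reflection (anatomical lateral views have a fixed
#' chirality).
#'
#' @param scale positive scalar.
#' @param angle rotation in radians, counter-clockwise in the (x right,
#'   y down) frame.
#' @param translation numeric length-2 (tx, ty).
#' @return an object of class \code{"similarity"}.
#' @export
similarity_transform <- function(scale = 1, angle = 0, translation = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0,
            is.numeric(angle), length(angle) == 1L, is.finite(angle),
            is.numeric(translation), length(translation) == 2L,
            all(is.finite(translation)))
  structure(list(scale = scale, angle = angle,
                 translation = as.numeric(translation)),
            class = "similarity")
}

#' @export
print.similarity <- function(x, ...) {
  cat(sprintf("Similarity transform: s = %.6g, theta = %.6g rad, t = (%.6g, %.6g)\n",
              x$scale, x$angle, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply or invert a similarity transform on a shape vector
#'
#' @param transform a \code{similarity} object.
#' @param v shape vector (x1..xn, y1..yn).
#' @return transformed shape vector of the same length.
#' @export
apply_similarity <- function(transform, v) {
  n <- length(v) / 2L
  z <- complex(real = v[seq_len(n)], imaginary = v[n + seq_len(n)])
  a <- complex(modulus = transform$scale, argument = transform$angle)
  w <- a * z + complex(real = transform$translation[1],
                       imaginary = transform$translation[2])
  c(Re(w), Im(w))
}

#' @rdname apply_similarity
#' @export
invert_similarity <- function(transform) {
  a <- complex(modulus = transform$scale, argument = transform$angle)
  t0 <- complex(real = transform$translation[1],
                imaginary = transform$translation[2])
  ainv <- 1 / a
  tinv <- -ainv * t0
  similarity_transform(Mod(ainv), Arg(ainv), c(Re(tinv), Im(tinv)))
}

#' Least-squares similarity alignment of one shape onto another
#'
#' Finds the similarity transform T (scale, rotation, translation; no
#' reflection) minimizing \code{sum_i w_i || T(src_i) - dst_i ||^2}. The
#' closed form treats points as complex numbers: the optimal rotation-scale is
#' the weighted complex regression coefficient of the centered destination on
#' the centered source.
#'
#' @param src,dst shape vectors of equal length (x..., y...).
#' @param weights optional nonnegative per-point weights, not all zero.
#' @return a \code{similarity} object.
#' @export
fit_similarity <- function(src, dst, weights = NULL) {
  stopifnot(length(src) == length(dst), length(src) %% 2L == 0L)
  n <- length(src) / 2L
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  wsum <- sum(weights)
  if (wsum <= 0) stop("weights must not be all zero", call. = FALSE)
  w <- weights / wsum
  z <- complex(real = src[seq_len(n)], imaginary = src[n + seq_len(n)])
  u <- complex(real = dst[seq_len(n)], imaginary = dst[n + seq_len(n)])
  zc <- z - sum(w * z)
  uc <- u - sum(w * u)
  denom <- sum(w * Mod(zc)^2)
  if (denom < .Machine$double.eps * max(1, sum(Mod(z)^2)))
    stop("degenerate configuration: source points are coincident", call. = FALSE)
  a <- sum(w * uc * Conj(zc)) / denom
  if (Mod(a) == 0)
    stop("degenerate configuration: zero optimal scale", call. = FALSE)
  t0 <- sum(w * u) - a * sum(w * z)
  similarity_transform(Mod(a), Arg(a), c(Re(t0), Im(t0)))
}

#' Generalized Procrustes analysis
#'
#' Iteratively aligns a set of shapes to their evolving mean by least-squares
#' similarity transforms. The mean is centered at the origin and scaled to
#' unit Euclidean norm at every pass (the standard normalization for point
#' distribution models), so the aligned shapes live on (near) the unit shape
#' sphere.
#'
#' @param shapes list of shape vectors of equal length.
#' @param tol convergence tolerance on the change of the mean vector.
#' @param max_iter maximum number of alignment passes.
#' @return list with \code{aligned} (list of aligned shape vectors),
#'   \code{mean} (centered, unit-norm), \code{iterations}, and
#'   \code{converged} (FALSE flags non-convergence; not an error).
#' @export
generalized_procrustes <- function(shapes, tol = 1e-10, max_iter = 100L) {
  stopifnot(is.list(shapes), length(shapes) >= 2L)
  len <- unique(vapply(shapes, length, 1L))
  if (length(len) != 1L) stop("shapes must all have the same length", call. = FALSE)
  normalize <- function(v) {
    v <- sv_center(v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate shape: all points coincident", call. = FALSE)
    v / nv
  }
  mean_shape <- normalize(shapes[[1L]])
  aligned <- shapes
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(shapes, function(s)
      apply_similarity(fit_similarity(s, mean_shape), s))
    new_mean <- normalize(Reduce(`+`, aligned) / length(aligned))
    # fix the rotational gauge freedom: align the new mean onto the old one
    new_mean <- apply_similarity(fit_similarity(new_mean, mean_shape), new_mean)
    new_mean <- normalize(new_mean)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  aligned <- lapply(shapes, function(s)
    apply_similarity(fit_similarity(s, mean_shape), s))
  if (!converged)
    warning("generalized Procrustes analysis did not converge in ",
            max_iter, " iterations", call. = FALSE)
  list(aligned = aligned, mean = mean_shape, iterations = it,
       converged = converged)
}
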