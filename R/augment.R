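#' Parameters of the artificial spondylolisthesis augmentation
#'
#' A slip is emulated as a rigid translation of a consecutive block of
#' vertebral elements. \code{v_start} and \code{v_end} select the block
#' (1..5 = L1..L5, 6 = the S1 endplate pair), \code{alpha} the slip sense
#' (forward/backward), and \code{beta} the slip magnitude as a fraction of
#' the upper endplate width of the first moved element.
#'
#' @param v_start,v_end integers in 1..6 with \code{v_start <= v_end}.
#' @param alpha -1 or +1.
#' @param beta slip fraction in \code{[0, beta_max]}.
#' @param beta_max maximum slip fraction; default 0.3.
#' @return an object of class \code{"augmentation_params"}.
#' @export
augmentation_params <- function(v_start, v_end, alpha, beta, beta_max = 0.3) {
  stopifnot(length(v_start) == 1L, v_start %in% 1:6,
            length(v_end) == 1L, v_end %in% 1:6,
            length(alpha) == 1L, alpha %in% c(-1, 1),
            length(beta) == 1L, is.finite(beta),
            length(beta_max) == 1L, beta_max >= 0)
  if (v_start > v_end)
    stop("v_start must be <= v_end", call. = FALSE)
  if (beta < 0 || beta > beta_max)
    stop("beta must lie in [0, beta_max]", call. = FALSE)
  structure(list(v_start = as.integer(v_start), v_end = as.integer(v_end),
                 alpha = as.integer(alpha), beta = beta, beta_max = beta_max),
            class = "augmentation_params")
}

#' Generate an artificial spondylolisthesis configuration
#'
#' Rigidly translates every landmark of vertebral elements
#' \code{v_start..v_end} by \code{d = alpha * beta * (UR* - UL*)}, where
#' (UL*, UR*) are the top two points of the first moved element (its upper
#' endplate corners; for element 6 the two S1 endpoints). In a lateral view
#' the upper-endplate direction approximates the anterior-posterior slip
#' axis. All other landmarks are untouched.
#'
#' @param lm a \code{landmarks} object.
#' @param params an \code{augmentation_params} object.
#' @param direction \code{"endplate"} (default) translates along the upper
#'   endplate of the first moved element; \code{"image_x"} along the global
#'   image x-axis with the same magnitude.
#' @return the slipped \code{landmarks}, labeled \code{"spondylolisthesis"}.
#' @export
augment_spondylolisthesis <- function(lm, params,
                                      direction = c("endplate", "image_x")) {
  stopifnot(is_landmarks(lm), inherits(params, "augmentation_params"))
  direction <- match.arg(direction)
  pts <- unclass(lm)
  top <- vertebra_indices(params$v_start)[1:2]  # UL*, UR* (or S1 left/right)
  edge <- pts[top[2L], ] - pts[top[1L], ]
  d <- if (direction == "endplate") {
    params$alpha * params$beta * edge
  } else {
    params$alpha * params$beta * c(sqrt(sum(edge^2)), 0)
  }
  moved <- unlist(lapply(params$v_start:params$v_end, vertebra_indices))
  pts[moved, 1L] <- pts[moved, 1L] + d[1L]
  pts[moved, 2L] <- pts[moved, 2L] + d[2L]
  landmarks(pts, pixel_spacing_mm = attr(lm, "pixel_spacing_mm"),
            label = "spondylolisthesis")
}

#' Sample random augmentation parameters
#'
#' \code{v_start} is uniform over 1..6, \code{v_end} uniform over
#' \code{v_start..6} (or fixed at 6, the sacrum, if \code{fix_v_end}),
#' \code{alpha} uniform over \{-1, +1\}, and \code{beta} uniform over
#' \code{[0, beta_max]}. Uses the current R random number stream.
#'
#' @param beta_max maximum slip fraction (default 0.3).
#' @param fix_v_end if TRUE the slipped block always extends to the sacrum.
#' @return an \code{augmentation_params} object.
#' @export
sample_augmentation_params <- function(beta_max = 0.3, fix_v_end = FALSE) {
  v_start <- sample.int(6L, 1L)
  v_end <- if (fix_v_end) 6L else v_start + sample.int(7L - v_start, 1L) - 1L
  alpha <- sample(c(-1L, 1L), 1L)
  beta <- stats::runif(1L, 0, beta_max)
  augmentation_params(v_start, v_end, alpha, beta, beta_max = beta_max)
}

#' Rebalance a training set by appending artificial spondylolisthesis cases
#'
#' Appends slipped copies of randomly chosen normal configurations until the
#' spondylolisthesis fraction reaches at least \code{target_fraction}. The
#' original configurations are returned untouched, in their input order,
#' followed by the appended cases.
#'
#' @param shapes list of \code{landmarks}.
#' @param labels character vector ("normal"/"spondylolisthesis") aligned with
#'   \code{shapes}; defaults to the label attributes (missing labels are
#'   treated as normal).
#' @param target_fraction desired minimum spondylolisthesis fraction,
#'   in (0, 1).
#' @param beta_max,fix_v_end passed to [sample_augmentation_params()].
#' @param seed optional integer seed for reproducibility.
#' @return list with \code{shapes} (input plus appended, each labeled),
#'   \code{labels}, \code{n_added}, and \code{params} (the sampled
#'   augmentation parameters for each appended case).
#' @export
balance_training_set <- function(shapes, labels = NULL, target_fraction = 0.15,
                                 beta_max = 0.3, fix_v_end = FALSE,
                                 seed = NULL) {
  stopifnot(is.list(shapes), length(shapes) >= 1L,
            target_fraction > 0, target_fraction < 1)
  if (is.null(labels)) {
    labels <- vapply(shapes, function(s) {
      lab <- attr(s, "label")
      if (is.null(lab)) "normal" else lab
    }, "")
  }
  stopifnot(length(labels) == length(shapes))
  if (!is.null(seed)) set.seed(seed)
  n <- length(shapes)
  s <- sum(labels == "spondylolisthesis")
  normals <- which(labels != "spondylolisthesis")
  m <- max(0L, as.integer(ceiling((target_fraction * n - s) /
                                  (1 - target_fraction) - 1e-12)))
  if (m > 0L && length(normals) == 0L)
    stop("no normal shapes available to augment", call. = FALSE)
  params <- vector("list", m)
  added <- vector("list", m)
  for (i in seq_len(m)) {
    src <- shapes[[sample(normals, 1L)]]
    params[[i]] <- sample_augmentation_params(beta_max = beta_max,
                                              fix_v_end = fix_v_end)
    added[[i]] <- augment_spondylolisthesis(src, params[[i]])
  }
  list(shapes = c(shapes, added),
       labels = c(labels, rep("spondylolisthesis", m)),
       n_added = m,
       params = params)
}
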