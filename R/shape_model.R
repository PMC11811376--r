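#' Fit a point-distribution shape model
#'
#' Builds the statistical shape prior used by the correction loop: the input
#' landmark configurations are brought into a common frame by generalized
#' Procrustes analysis (similarity transforms only), projected into the
#' tangent plane of the unit shape sphere at the mean (which linearizes the
#' shape statistics), and principal component analysis of the projected
#' 44-element shape vectors about the mean yields the modes of variation. Any shape consistent with the prior can then be
#' written \code{x = xbar + P b} for a small coefficient vector \code{b}.
#'
#' All modes with positive eigenvalue are retained in the fitted object (at
#' most 43); the number of modes actually used, \code{n_modes}, is chosen at
#' projection time.
#'
#' @param shapes a list of \code{landmarks} objects or 44-element shape
#'   vectors, or an n x 44 numeric matrix (one shape per row). At least 3.
#' @param gpa_tol,gpa_max_iter convergence control for the Procrustes step.
#' @param augmentation optional list recording how the training set was
#'   augmented (kept as metadata only).
#' @return an object of class \code{"shape_model"} with components
#'   \code{mean} (44-vector, centroid at origin, unit norm),
#'   \code{eigenvectors} (44 x K, orthonormal columns),
#'   \code{eigenvalues} (length K, non-increasing), \code{n_train},
#'   \code{gpa}, \code{augmentation}.
#' @examples
#' set.seed(1)
#' spines <- generate_dataset(spine_template_params(n_images = 30))
#' model <- shape_model(spines)
#' model
#' @export
shape_model <- function(shapes, gpa_tol = 1e-10, gpa_max_iter = 100L,
                        augmentation = NULL) {
  if (is.matrix(shapes))
    shapes <- lapply(seq_len(nrow(shapes)), function(i) shapes[i, ])
  stopifnot(is.list(shapes), length(shapes) >= 3L)
  vecs <- lapply(shapes, function(s)
    if (is_landmarks(s)) as_shape_vector(s) else as.numeric(s))
  if (!all(vapply(vecs, length, 1L) == 2L * N_LANDMARKS))
    stop("all training shapes must have 22 landmarks", call. = FALSE)
  gpa <- generalized_procrustes(vecs, tol = gpa_tol, max_iter = gpa_max_iter)
  A <- do.call(rbind, gpa$aligned)
  n <- nrow(A)
  xbar <- gpa$mean
  # project each aligned shape into the tangent plane of the unit shape
  # sphere at the mean (a -> a / (a . xbar)); the mode deviations are then
  # orthogonal to the mean, which makes the constraint iteration's fixed
  # point exact for model-generated shapes
  A <- A / as.numeric(A %*% xbar)
  D <- sweep(A, 2L, xbar)
  C <- crossprod(D) / (n - 1L)
  eig <- eigen(C, symmetric = TRUE)
  keep <- which(eig$values > max(eig$values) * 1e-12 & eig$values > 0)
  keep <- keep[seq_len(min(length(keep), 2L * N_LANDMARKS - 1L))]
  P <- eig$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude component of each mode is positive
  for (k in seq_len(ncol(P))) {
    j <- which.max(abs(P[, k]))
    if (P[j, k] < 0) P[, k] <- -P[, k]
  }
  structure(list(mean = xbar,
                 eigenvectors = P,
                 eigenvalues = eig$values[keep],
                 n_train = n,
                 gpa = list(iterations = gpa$iterations,
                            converged = gpa$converged),
                 augmentation = augmentation,
                 call = match.call()),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("Point-distribution shape model (22 lumbar landmarks)\n")
  cat(sprintf("  training shapes: %d, retained modes: %d\n",
              x$n_train, length(x$eigenvalues)))
  ve <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  k5 <- min(5L, length(ve))
  cat(sprintf("  variance explained by top %d modes: %.1f%%\n",
              k5, 100 * ve[k5]))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  lam <- object$eigenvalues
  tab <- data.frame(mode = seq_along(lam),
                    eigenvalue = lam,
                    prop_var = lam / sum(lam),
                    cum_var = cumsum(lam) / sum(lam))
  structure(list(modes = tab, n_train = object$n_train,
                 gpa = object$gpa, augmentation = object$augmentation),
            class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat("Shape model summary:", x$n_train, "training shapes,",
      nrow(x$modes), "modes\n")
  print(utils::head(x$modes, 10), row.names = FALSE, digits = 4)
  if (nrow(x$modes) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
coef.shape_model <- function(object, ...) {
  stats::setNames(object$eigenvalues,
                  paste0("lambda", seq_along(object$eigenvalues)))
}

#' @export
plot.shape_model <- function(x, mode = 1L, sd_range = 3, ...) {
  xb <- sv_xy(x$mean)
  dev <- sv_xy(x$eigenvectors[, mode] * sd_range * sqrt(x$eigenvalues[mode]))
  graphics::plot(xb[, 1], xb[, 2], asp = 1, ylim = rev(range(xb[, 2])),
       xlab = "x (aligned frame)", ylab = "y (aligned frame)",
       main = sprintf("Mean shape and mode %d (+/- %g sd)", mode, sd_range),
       pch = 19, ...)
  for (v in 1:5) {
    idx <- vertebra_indices(v)[c(1, 2, 4, 3, 1)]
    graphics::lines(xb[idx, 1], xb[idx, 2])
  }
  graphics::lines(xb[21:22, 1], xb[21:22, 2])
  graphics::arrows(xb[, 1] - dev[, 1], xb[, 2] - dev[, 2],
                   xb[, 1] + dev[, 1], xb[, 2] + dev[, 2],
                   length = 0.04, col = "grey40")
  invisible(x)
}

#' Draw random shapes from a fitted shape model
#'
#' Samples mode coefficients independently as \code{b_k ~ N(0, lambda_k)} and
#' returns the shapes \code{xbar + P b} in the aligned (model) frame.
#'
#' @param object a \code{shape_model}.
#' @param nsim number of shapes.
#' @param seed optional integer seed.
#' @param n_modes number of leading modes to sample (default: all).
#' @param ... unused.
#' @return list of \code{landmarks} in the aligned frame.
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL,
                                 n_modes = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(object$eigenvalues)
  if (is.null(n_modes)) n_modes <- K
  stopifnot(n_modes >= 1L, n_modes <= K)
  P <- object$eigenvectors[, seq_len(n_modes), drop = FALSE]
  sdv <- sqrt(object$eigenvalues[seq_len(n_modes)])
  lapply(seq_len(nsim), function(i) {
    b <- stats::rnorm(n_modes, sd = sdv)
    as_landmarks(object$mean + as.numeric(P %*% b))
  })
}

#' Project a landmark configuration onto the shape model
#'
#' The workhorse of the shape step: given an arbitrary configuration Y in the
#' image frame, finds the model-consistent configuration X nearest to Y in
#' the least-squares sense. Iterates pose fitting (similarity transform of
#' the current model shape onto Y), mapping Y into the model frame,
#' projection onto the tangent plane of the unit shape sphere at the mean
#' (\code{y' = y / (y . xbar)}), and re-estimation of the mode coefficients
#' \code{b = P'(y' - xbar)}, optionally clamped to \code{+/- clamp_k *
#' sqrt(lambda_k)}, until \code{b} stabilizes.
#'
#' @param Y shape vector (length 44) or \code{landmarks} in the image frame.
#' @param model a \code{shape_model}.
#' @param n_modes number of leading modes used (default: all retained).
#' @param clamp_k clamp half-width in units of per-mode standard deviation;
#'   \code{NULL} disables clamping. Default 3.
#' @param tol convergence tolerance on \code{||delta b||}.
#' @param max_iter inner iteration budget.
#' @return list with \code{X} (constrained shape vector, image frame),
#'   \code{b} (mode coefficients), \code{transform} (the final pose, a
#'   \code{similarity}), \code{iterations}, \code{converged}.
#' @export
constrain_shape <- function(Y, model, n_modes = NULL, clamp_k = 3,
                            tol = 1e-6, max_iter = 50L) {
  if (is_landmarks(Y)) Y <- as_shape_vector(Y)
  stopifnot(inherits(model, "shape_model"),
            length(Y) == length(model$mean))
  K <- length(model$eigenvalues)
  if (is.null(n_modes)) n_modes <- K
  if (n_modes < 1L || n_modes > K)
    stop("n_modes must be between 1 and ", K, " (available modes)", call. = FALSE)
  P <- model$eigenvectors[, seq_len(n_modes), drop = FALSE]
  lam <- model$eigenvalues[seq_len(n_modes)]
  xbar <- model$mean
  lim <- if (!is.null(clamp_k)) clamp_k * sqrt(lam)
  b <- numeric(n_modes)
  converged <- FALSE
  it <- 0L
  trans <- NULL
  while (it < max_iter) {
    it <- it + 1L
    x <- xbar + as.numeric(P %*% b)
    trans <- fit_similarity(x, Y)
    y <- apply_similarity(invert_similarity(trans), Y)
    denom <- sum(y * xbar)
    if (abs(denom) < 1e-8)
      stop("tangent projection degenerate: aligned shape orthogonal to the mean",
           call. = FALSE)
    yp <- y / denom
    b_new <- as.numeric(crossprod(P, yp - xbar))
    if (!is.null(lim)) b_new <- pmin(pmax(b_new, -lim), lim)
    delta <- sqrt(sum((b_new - b)^2))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  x <- xbar + as.numeric(P %*% b)
  trans <- fit_similarity(x, Y)
  list(X = apply_similarity(trans, x), b = b, transform = trans,
       iterations = it, converged = converged)
}

#' Predict method: constrain new configurations with a shape model
#'
#' Applies [constrain_shape()] to each new landmark configuration and returns
#' the model-consistent configurations in the image frame.
#'
#' @param object a \code{shape_model}.
#' @param newdata a \code{landmarks} object, a 44-vector, or a list of either.
#' @param n_modes,clamp_k,tol,max_iter passed to [constrain_shape()].
#' @param ... unused.
#' @return a \code{landmarks} object, or a list of them if \code{newdata} was
#'   a list.
#' @export
predict.shape_model <- function(object, newdata, n_modes = NULL, clamp_k = 3,
                                tol = 1e-6, max_iter = 50L, ...) {
  one <- function(y) {
    res <- constrain_shape(y, object, n_modes = n_modes, clamp_k = clamp_k,
                           tol = tol, max_iter = max_iter)
    as_landmarks(res$X,
                 pixel_spacing_mm = if (is_landmarks(y)) attr(y, "pixel_spacing_mm"),
                 label = if (is_landmarks(y)) attr(y, "label"))
  }
  if (is.list(newdata) && !is_landmarks(newdata)) lapply(newdata, one)
  else one(newdata)
}
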