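#' Per-landmark Euclidean point errors
#'
#' @param detected,truth lists of \code{landmarks} of equal length with
#'   matched ordering (or single \code{landmarks} objects).
#' @param units \code{"px"} (default) or \code{"mm"}; mm requires a
#'   \code{pixel_spacing_mm} attribute on every truth set.
#' @return N x 22 matrix of errors.
#' @export
point_errors <- function(detected, truth, units = c("px", "mm")) {
  units <- match.arg(units)
  if (is_landmarks(detected)) detected <- list(detected)
  if (is_landmarks(truth)) truth <- list(truth)
  if (length(detected) != length(truth))
    stop("detected and truth must have the same number of images", call. = FALSE)
  E <- t(vapply(seq_along(truth), function(i) {
    d <- sqrt(rowSums((unclass(detected[[i]]) - unclass(truth[[i]]))^2))
    if (units == "mm") {
      sp <- attr(truth[[i]], "pixel_spacing_mm")
      if (is.null(sp))
        stop("mm output requested but image ", i,
             " has no pixel_spacing_mm", call. = FALSE)
      d <- d * sp
    }
    d
  }, numeric(N_LANDMARKS)))
  attr(E, "units") <- units
  E
}

#' Per-image and averaged error summaries
#'
#' Per image: the maximum and mean over the 22 landmark errors. Averaged over
#' images: AE_max and AE_mean.
#'
#' @param E an N x 22 error matrix from [point_errors()].
#' @return list with \code{E_max_i}, \code{E_mean_i} (length N),
#'   \code{AE_max}, \code{AE_mean}.
#' @export
summarize_errors <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) == 0L) stop("empty error matrix", call. = FALSE)
  e_max <- apply(E, 1L, max)
  e_mean <- rowMeans(E)
  list(E_max_i = e_max, E_mean_i = e_mean,
       AE_max = mean(e_max), AE_mean = mean(e_mean))
}

#' Allowable error of a landmark configuration
#'
#' 20 percent of the mean length of the 21 vertebral edges: the four edges
#' (upper, left, right, lower) of each of L1..L5 plus the S1 upper endplate
#' edge. Applied to ground-truth points it normalizes evaluation errors
#' across image scales; applied to detected points it provides the snap-back
#' criterion of the post-processing step.
#'
#' @param lm a \code{landmarks} object.
#' @return nonnegative scalar, in the units of the coordinates.
#' @export
allowable_error <- function(lm) {
  stopifnot(is_landmarks(lm))
  pts <- unclass(lm)
  edge <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  total <- 0
  for (v in 1:5) {
    i <- vertebra_indices(v)  # UL, UR, LL, LR
    total <- total + edge(i[1], i[2]) + edge(i[1], i[3]) +
      edge(i[2], i[4]) + edge(i[3], i[4])
  }
  total <- total + edge(21L, 22L)
  (total / 21) / 5
}

#' Normalized error indices
#'
#' Means over images of the per-image maximum (and mean) error divided by
#' that image's allowable error; dimensionless.
#'
#' @param E_max_i,E_mean_i,E_a_i equal-length numeric vectors.
#' @return list with \code{NE_max} and \code{NE_mean}.
#' @export
normalized_errors <- function(E_max_i, E_mean_i, E_a_i) {
  stopifnot(length(E_max_i) == length(E_a_i),
            length(E_mean_i) == length(E_a_i))
  if (any(E_a_i <= 0))
    stop("allowable errors must be positive", call. = FALSE)
  list(NE_max = mean(E_max_i / E_a_i), NE_mean = mean(E_mean_i / E_a_i))
}

#' Interval histogram of per-image maximum errors
#'
#' Assigns each image to one of six bins by the ratio of its maximum error to
#' its own allowable error: \code{[0, Ea], (Ea, 2Ea], ..., (4Ea, 5Ea],
#' (5Ea, Inf)}. Upper bin edges are inclusive.
#'
#' @param E_max_i,E_a_i equal-length numeric vectors, \code{E_a_i > 0}.
#' @return named integer vector of six counts summing to the number of
#'   images.
#' @export
interval_histogram <- function(E_max_i, E_a_i) {
  stopifnot(length(E_max_i) == length(E_a_i), all(E_a_i > 0))
  ratio <- E_max_i / E_a_i
  bin <- pmin(ceiling(pmax(ratio, .Machine$double.xmin)), 6)
  counts <- tabulate(bin, nbins = 6L)
  names(counts) <- c("<=1Ea", "<=2Ea", "<=3Ea", "<=4Ea", "<=5Ea", ">5Ea")
  counts
}

#' Paired-samples t-test on per-image indices
#'
#' Two-sided paired t-test on the differences \code{a - b}. Degenerate cases
#' are flagged explicitly rather than failing: identical vectors give
#' \code{p = 1}, and a constant nonzero difference gives an infinite
#' statistic with \code{p = 0}.
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_diff},
#'   \code{degenerate} (\code{"none"}, \code{"zero_diff"}, or
#'   \code{"zero_variance"}).
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                degenerate = "zero_diff"))
  if (stats::sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d), degenerate = "zero_variance"))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = "none")
}

#' Percent change between two index values
#'
#' \code{100 * (a - b) / a}: the reduction from a baseline value \code{a} to
#' a new value \code{b}, as a percentage of the baseline.
#'
#' @param a baseline value (nonzero).
#' @param b comparison value.
#' @return percentage.
#' @export
percent_change <- function(a, b) 100 * (a - b) / a

#' Full evaluation report for a set of detections
#'
#' Combines all evaluation indices: the point-error matrix, per-image
#' maximum/mean errors, their averages, per-image allowable errors, the
#' normalized indices, and the interval histogram. Errors are reported in mm
#' when every truth configuration carries a pixel spacing, else in px.
#'
#' @param detected,truth lists of \code{landmarks} (or single objects).
#' @param baseline optional list of baseline detections; when given, paired
#'   t-tests comparing baseline and detected per-image indices are included.
#' @return an object of class \code{"error_report"}.
#' @export
error_report <- function(detected, truth, baseline = NULL) {
  if (is_landmarks(detected)) detected <- list(detected)
  if (is_landmarks(truth)) truth <- list(truth)
  have_mm <- all(vapply(truth, function(t)
    !is.null(attr(t, "pixel_spacing_mm")), TRUE))
  units <- if (have_mm) "mm" else "px"
  E <- point_errors(detected, truth, units = units)
  s <- summarize_errors(E)
  ea <- vapply(truth, allowable_error, 1)
  if (have_mm)
    ea <- ea * vapply(truth, function(t) attr(t, "pixel_spacing_mm"), 1)
  ne <- normalized_errors(s$E_max_i, s$E_mean_i, ea)
  hist <- interval_histogram(s$E_max_i, ea)
  rep <- list(E = E, E_max_i = s$E_max_i, E_mean_i = s$E_mean_i,
              AE_max = s$AE_max, AE_mean = s$AE_mean, E_a_i = ea,
              NE_max = ne$NE_max, NE_mean = ne$NE_mean,
              histogram = hist, units = units, n_images = nrow(E))
  if (!is.null(baseline)) {
    if (is_landmarks(baseline)) baseline <- list(baseline)
    Eb <- point_errors(baseline, truth, units = units)
    sb <- summarize_errors(Eb)
    # paired tests need at least two images
    tt_max <- if (nrow(E) >= 2L) paired_t_test(sb$E_max_i, s$E_max_i)
    tt_mean <- if (nrow(E) >= 2L) paired_t_test(sb$E_mean_i, s$E_mean_i)
    rep$baseline <- list(AE_max = sb$AE_max, AE_mean = sb$AE_mean,
                         t_test_max = tt_max,
                         t_test_mean = tt_mean,
                         AE_max_change_pct = percent_change(sb$AE_max, s$AE_max),
                         AE_mean_change_pct = percent_change(sb$AE_mean, s$AE_mean))
  }
  structure(rep, class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Landmark error report (%d images, %s)\n", x$n_images, x$units))
  cat(sprintf("  AE_max  = %.4f %s   AE_mean = %.4f %s\n",
              x$AE_max, x$units, x$AE_mean, x$units))
  cat(sprintf("  NE_max  = %.4f      NE_mean = %.4f\n", x$NE_max, x$NE_mean))
  cat("  interval histogram (by E_max,i / E_a,i):\n  ")
  print(x$histogram)
  if (!is.null(x$baseline)) {
    pmax_txt <- if (!is.null(x$baseline$t_test_max))
      sprintf(", p = %.3g", x$baseline$t_test_max$p) else ""
    pmean_txt <- if (!is.null(x$baseline$t_test_mean))
      sprintf(", p = %.3g", x$baseline$t_test_mean$p) else ""
    cat(sprintf("  vs baseline: AE_max %.4f -> %.4f (%+.2f%%)%s\n",
                x$baseline$AE_max, x$AE_max,
                -x$baseline$AE_max_change_pct, pmax_txt))
    cat(sprintf("               AE_mean %.4f -> %.4f (%+.2f%%)%s\n",
                x$baseline$AE_mean, x$AE_mean,
                -x$baseline$AE_mean_change_pct, pmean_txt))
  }
  invisible(x)
}
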