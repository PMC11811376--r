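# fixtures and independent oracles shared across the suite

# a spine whose 21 vertebral edges all have length 1 (five unit squares
# stacked with gaps, plus a unit S1 edge): allowable error is 0.2 exactly
unit_spine <- function(spacing = NULL) {
  pts <- matrix(NA_real_, 22, 2)
  for (j in 1:5) {
    y <- 3 * (j - 1)
    pts[4 * (j - 1) + 1, ] <- c(0, y)      # UL
    pts[4 * (j - 1) + 2, ] <- c(1, y)      # UR
    pts[4 * (j - 1) + 3, ] <- c(0, y + 1)  # LL
    pts[4 * (j - 1) + 4, ] <- c(1, y + 1)  # LR
  }
  pts[21, ] <- c(0, 15)
  pts[22, ] <- c(1, 15)
  landmarks(pts, pixel_spacing_mm = spacing)
}

# the layout-definition fixture: point k at (k, 100 + k)
index_spine <- function() landmarks(cbind(1:22, 101:122))

# direct numerical least squares for the similarity fit (independent of the
# closed form): quasi-Newton over (log s, theta, tx, ty)
numeric_similarity_ls <- function(src, dst, weights = NULL) {
  n <- length(src) / 2
  if (is.null(weights)) weights <- rep(1, n)
  obj <- function(p) {
    s <- exp(p[1]); th <- p[2]
    x <- src[1:n]; y <- src[n + 1:n]
    tx <- s * (cos(th) * x - sin(th) * y) + p[3]
    ty <- s * (sin(th) * x + cos(th) * y) + p[4]
    sum(weights * ((tx - dst[1:n])^2 + (ty - dst[n + 1:n])^2))
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  list(par = c(scale = exp(fit$par[1]), angle = fit$par[2],
               tx = fit$par[3], ty = fit$par[4]),
       value = fit$value, objective = obj)
}

# interior central differences on the same grid (exact on affine surfaces)
central_diff <- function(r) {
  H <- nrow(r); W <- ncol(r)
  list(gx = (r[2:(H - 1), 3:W] - r[2:(H - 1), 1:(W - 2)]) / 2,
       gy = (r[3:H, 2:(W - 1)] - r[1:(H - 2), 2:(W - 1)]) / 2)
}

# independent bilinear interpolation of a matrix at 0-based (x, y)
bilinear_oracle <- function(m, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  (1 - fx) * (1 - fy) * m[i, j] + fx * (1 - fy) * m[i, j + 1] +
    (1 - fx) * fy * m[i + 1, j] + fx * fy * m[i + 1, j + 1]
}

# convexity of a quadrilateral given in UL, UR, LL, LR order: walk the
# perimeter UL -> UR -> LR -> LL and require consistent turn signs
quad_convex <- function(p) {
  q <- p[c(1, 2, 4, 3), ]
  cr <- numeric(4)
  for (i in 1:4) {
    a <- q[i %% 4 + 1, ] - q[i, ]
    b <- q[(i + 1) %% 4 + 1, ] - q[i %% 4 + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  all(cr > 0) || all(cr < 0)
}

# a stack of clean Gaussian channels for a configuration with integer
# coordinates (argmax then recovers the truth exactly)
integer_truth_stack <- function(seed = 1) {
  set.seed(seed)
  spine <- generate_spine(spine_template_params(spondylolisthesis_fraction = 0))
  truth <- landmarks(round(unclass(spine)),
                     pixel_spacing_mm = attr(spine, "pixel_spacing_mm"))
  list(truth = truth,
       stack = simulate_heatmaps(truth, heatmap_noise_params()))
}

# small training set + model used by several correction tests
small_model <- function(seed = 5, n = 80) {
  set.seed(seed)
  shape_model(generate_dataset(spine_template_params(), n = n))
}

# centroid of a shape vector (test-side copy, independent of the package)
sv_centroid_test <- function(v) {
  n <- length(v) / 2
  c(mean(v[1:n]), mean(v[n + 1:n]))
}
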