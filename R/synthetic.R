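#' Parameters of the synthetic spine generator
#'
#' The generator is parametric-geometric: it emulates the label geometry of
#' lateral lumbar radiographs (five vertebral bodies stacked along a lordotic
#' curve plus the sacral upper endplate) without synthesizing images, since
#' the correction method consumes only coordinates and heatmaps. See
#' \code{vignette("hasm-methods")} for what the generator does and does not
#' emulate.
#'
#' @param n_images default dataset size for [generate_dataset()].
#' @param width_mean,width_cv vertebral body width (anteroposterior endplate
#'   length), px, and its coefficient of variation.
#' @param height_mean,height_cv vertebral body height, px, and CV.
#' @param gap_mean,gap_cv inter-vertebral (disc) gap, px, and CV.
#' @param size_correlation within-subject correlation of vertebral
#'   dimensions (a subject's vertebrae are similarly sized; one shared
#'   factor per dimension group plus independent residuals).
#' @param curvature_amplitude mean bow of the lordotic curve, px; each spine
#'   draws its own amplitude around this value.
#' @param tilt_sd per-vertebra tilt spread around the curve tangent, radians.
#' @param corner_jitter_sd isotropic per-corner jitter emulating endplate
#'   irregularity, px.
#' @param s1_extra_tilt additional inclination of the sacral endplate,
#'   radians.
#' @param spondylolisthesis_fraction fraction of generated spines carrying an
#'   artificial slip.
#' @param slip_beta_range slip magnitude range (fraction of endplate width)
#'   for generated spondylolisthesis cases.
#' @param extent image extent c(H, W), px.
#' @param pixel_spacing_mm mm per pixel recorded on generated landmark sets.
#' @param seed optional integer seed consumed by the generating functions.
#' @return an object of class \code{"spine_template_params"}.
#' @export
spine_template_params <- function(n_images = 100L,
                                  width_mean = 60, width_cv = 0.08,
                                  height_mean = 42, height_cv = 0.08,
                                  gap_mean = 12, gap_cv = 0.2,
                                  size_correlation = 0.85,
                                  curvature_amplitude = 15,
                                  tilt_sd = 0.04,
                                  corner_jitter_sd = 1,
                                  s1_extra_tilt = 0.3,
                                  spondylolisthesis_fraction = 0.15,
                                  slip_beta_range = c(0.1, 0.3),
                                  extent = c(400, 300),
                                  pixel_spacing_mm = 0.17,
                                  seed = NULL) {
  stopifnot(n_images >= 1L, width_mean > 0, width_cv >= 0,
            height_mean > 0, height_cv >= 0, gap_mean > 0, gap_cv >= 0,
            size_correlation >= 0, size_correlation <= 1,
            curvature_amplitude >= 0, tilt_sd >= 0, corner_jitter_sd >= 0,
            spondylolisthesis_fraction >= 0, spondylolisthesis_fraction <= 1,
            length(slip_beta_range) == 2L, slip_beta_range[1] >= 0,
            slip_beta_range[2] <= 0.3 + 1e-12,
            slip_beta_range[1] <= slip_beta_range[2],
            length(extent) == 2L, all(extent > 0))
  structure(as.list(environment()), class = "spine_template_params")
}

# truncated-normal draw for strictly positive sizes; rho is the
# within-subject correlation (one shared factor plus independent residuals)
rsize <- function(n, mean, cv, rho = 0) {
  shared <- stats::rnorm(1L)
  z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
  v <- mean * (1 + cv * z)
  pmin(pmax(v, 0.5 * mean), 1.5 * mean)
}

#' Generate one synthetic 22-landmark lumbar configuration
#'
#' Stacks L1..L5 quadrilaterals and the S1 upper endplate top-to-bottom along
#' a bowed curve with sampled sizes, gaps and tilts; vertebral centers have
#' strictly increasing y and all quadrilaterals are convex. With probability
#' \code{spondylolisthesis_fraction} an artificial slip
#' ([augment_spondylolisthesis()]) is applied and the result labeled
#' accordingly. Uses the current R random number stream (set
#' \code{params$seed} or call \code{set.seed} for reproducibility).
#'
#' @param params a \code{spine_template_params}.
#' @return a \code{landmarks} object, labeled normal or spondylolisthesis.
#' @export
generate_spine <- function(params) {
  stopifnot(inherits(params, "spine_template_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  H <- params$extent[1L]; W <- params$extent[2L]
  rho <- params$size_correlation
  w <- rsize(6L, params$width_mean, params$width_cv, rho)
  h <- rsize(5L, params$height_mean, params$height_cv, rho)
  gap <- pmax(rsize(5L, params$gap_mean, params$gap_cv, rho),
              0.2 * params$gap_mean)
  total <- sum(h) + sum(gap)
  y_top <- (H - total) / 2
  # vertebral center depths: L1..L5 body centers, then the S1 endplate line
  yc <- numeric(6L)
  y <- y_top
  for (j in 1:5) {
    yc[j] <- y + h[j] / 2
    y <- y + h[j] + gap[j]
  }
  yc[6L] <- y
  # lordotic bow: per-spine amplitude, quadratic offset peaking mid-column
  amp <- max(0, stats::rnorm(1L, params$curvature_amplitude,
                             0.4 * params$curvature_amplitude))
  u <- (seq_len(6L) - 3.5) / 2.5
  xc <- W / 2 + amp * (1 - u^2)
  xc <- xc - mean(xc) + W / 2
  # tilts follow the curve tangent plus independent spread
  dxdj <- amp * (-2) * u / 2.5
  dydj <- c(diff(yc), yc[6L] - yc[5L])
  tilt <- atan2(dxdj, dydj) + stats::rnorm(6L, 0, params$tilt_sd)
  tilt[6L] <- tilt[6L] + params$s1_extra_tilt
  pts <- matrix(NA_real_, N_LANDMARKS, 2L)
  corner <- function(j, u_loc, v_loc) {
    ct <- cos(tilt[j]); st <- sin(tilt[j])
    c(xc[j] + ct * u_loc - st * v_loc, yc[j] + st * u_loc + ct * v_loc)
  }
  for (j in 1:5) {
    i <- vertebra_indices(j)
    pts[i[1L], ] <- corner(j, -w[j] / 2, -h[j] / 2)  # UL
    pts[i[2L], ] <- corner(j,  w[j] / 2, -h[j] / 2)  # UR
    pts[i[3L], ] <- corner(j, -w[j] / 2,  h[j] / 2)  # LL
    pts[i[4L], ] <- corner(j,  w[j] / 2,  h[j] / 2)  # LR
  }
  pts[21L, ] <- corner(6L, -w[6L] / 2, 0)
  pts[22L, ] <- corner(6L,  w[6L] / 2, 0)
  if (params$corner_jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(2L * N_LANDMARKS,
                                     0, params$corner_jitter_sd),
                        N_LANDMARKS, 2L)
  lm <- landmarks(pts, pixel_spacing_mm = params$pixel_spacing_mm,
                  label = "normal")
  if (stats::runif(1L) < params$spondylolisthesis_fraction) {
    slip <- augmentation_params(
      v_start = sample(4:5, 1L), v_end = 6L,
      alpha = sample(c(-1L, 1L), 1L),
      beta = stats::runif(1L, params$slip_beta_range[1L],
                          params$slip_beta_range[2L]))
    lm <- augment_spondylolisthesis(lm, slip)
  }
  p <- unclass(lm)
  if (any(p[, 1L] < 0 | p[, 1L] > W - 1 | p[, 2L] < 0 | p[, 2L] > H - 1))
    stop("template parameters place landmarks outside the image extent",
         call. = FALSE)
  lm
}

#' Generate a dataset of synthetic spines
#'
#' @param params a \code{spine_template_params}.
#' @param n number of spines (default \code{params$n_images}).
#' @param seed optional integer seed.
#' @return list of labeled \code{landmarks}.
#' @export
generate_dataset <- function(params, n = params$n_images, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$seed <- NULL  # one stream for the whole dataset
  lapply(seq_len(n), function(i) generate_spine(params))
}

#' Parameters of the heatmap corruption model
#'
#' Abstract heatmap-level corruptions emulating the typical failure modes of
#' keypoint networks on radiographs (occluding structures, film artifacts,
#' ambiguous anatomy): a displaced primary peak, a spurious secondary peak,
#' attenuation of the primary peak, and additive pixel noise.
#'
#' @param sigma Gaussian peak width, channel px (default 5).
#' @param shift_prob,shift_range probability of displacing the primary peak,
#'   and the displacement magnitude range in image px.
#' @param spurious_prob,spurious_amp_range probability of adding a secondary
#'   peak elsewhere in the channel, and its amplitude range (the primary has
#'   amplitude 1 before attenuation).
#' @param atten_prob,atten_floor probability of attenuating the primary peak,
#'   and the lowest attenuation factor.
#' @param noise_sd additive Gaussian pixel noise, clipped at zero.
#' @param channel_size channel grid side length (square), px.
#' @param channel_scale channel px per image px.
#' @param seed optional integer seed consumed by [simulate_heatmaps()].
#' @return an object of class \code{"heatmap_noise_params"}.
#' @export
heatmap_noise_params <- function(sigma = 5,
                                 shift_prob = 0, shift_range = c(10, 30),
                                 spurious_prob = 0,
                                 spurious_amp_range = c(0.3, 0.9),
                                 atten_prob = 0, atten_floor = 0.3,
                                 noise_sd = 0,
                                 channel_size = 128L, channel_scale = 1,
                                 seed = NULL) {
  stopifnot(sigma > 0,
            shift_prob >= 0, shift_prob <= 1,
            length(shift_range) == 2L, shift_range[1] <= shift_range[2],
            spurious_prob >= 0, spurious_prob <= 1,
            length(spurious_amp_range) == 2L,
            all(spurious_amp_range >= 0), all(spurious_amp_range <= 1),
            atten_prob >= 0, atten_prob <= 1,
            atten_floor > 0, atten_floor <= 1,
            noise_sd >= 0, channel_size >= 3L, channel_scale > 0)
  structure(as.list(environment()), class = "heatmap_noise_params")
}

#' Simulate a heatmap stack for a known configuration
#'
#' Renders, per landmark, a Gaussian response on a channel window centered
#' near the true point (the window position is recorded in the channel's
#' \code{origin_offset}), then applies the corruptions of
#' \code{noise} independently with their stated probabilities. Uses the
#' current R random number stream.
#'
#' @param truth a \code{landmarks} object.
#' @param noise a \code{heatmap_noise_params}.
#' @param landmarks_affected integer indices of channels eligible for
#'   corruption (default: all 22).
#' @param image_id identifier recorded on the stack.
#' @return a \code{heatmap_stack}.
#' @export
simulate_heatmaps <- function(truth, noise,
                              landmarks_affected = seq_len(N_LANDMARKS),
                              image_id = "synthetic") {
  stopifnot(is_landmarks(truth), inherits(noise, "heatmap_noise_params"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  size <- as.integer(noise$channel_size)
  sc <- noise$channel_scale
  pts <- unclass(truth)
  channels <- vector("list", N_LANDMARKS)
  for (k in seq_len(N_LANDMARKS)) {
    # integer window origin so grid nodes line up with integer image pixels
    offset <- round(pts[k, ]) - floor((size - 1L) / (2 * sc))
    center <- (pts[k, ] - offset) * sc
    eligible <- k %in% landmarks_affected
    if (eligible && stats::runif(1L) < noise$shift_prob) {
      ang <- stats::runif(1L, 0, 2 * pi)
      mag <- stats::runif(1L, noise$shift_range[1L], noise$shift_range[2L])
      center <- center + sc * mag * c(cos(ang), sin(ang))
    }
    amp <- 1
    if (eligible && stats::runif(1L) < noise$atten_prob)
      amp <- stats::runif(1L, noise$atten_floor, 1)
    ch <- render_gaussian(center, noise$sigma * sc, size, size,
                          origin_offset = offset, scale = sc,
                          landmark_index = k)
    r <- amp * ch$response
    if (eligible && stats::runif(1L) < noise$spurious_prob) {
      amp2 <- stats::runif(1L, noise$spurious_amp_range[1L],
                           noise$spurious_amp_range[2L])
      pos2 <- stats::runif(2L, 0.1 * size, 0.9 * size)
      ch2 <- render_gaussian(pos2, noise$sigma * sc, size, size)
      r <- r + amp2 * ch2$response
    }
    if (noise$noise_sd > 0)
      r <- pmax(r + stats::rnorm(length(r), 0, noise$noise_sd), 0)
    channels[[k]] <- heatmap_channel(r, origin_offset = offset, scale = sc,
                                     landmark_index = k,
                                     sigma_hint = noise$sigma * sc)
  }
  heatmap_stack(channels, image_id = image_id,
                pixel_spacing_mm = attr(truth, "pixel_spacing_mm"))
}

#' Write a complete reproducible mini-experiment to disk
#'
#' Generates a training landmark CSV, a fitted shape model JSON, and a set of
#' validation heatmap stacks (TIFF + JSON sidecar) with their ground-truth
#' CSV, plus a manifest of the seeds, parameters and MD5 hashes. Re-running
#' with the same seed reproduces every file byte-identically.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param n_train,n_validation set sizes.
#' @param template a \code{spine_template_params}.
#' @param noise a \code{heatmap_noise_params}.
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
make_fixture <- function(seed, out_dir, n_train = 40L, n_validation = 3L,
                         template = spine_template_params(),
                         noise = heatmap_noise_params()) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  set.seed(seed)
  template$seed <- NULL
  noise$seed <- NULL
  train <- generate_dataset(template, n = n_train)
  train_csv <- file.path(out_dir, "train_landmarks.csv")
  write_landmarks_csv(train, train_csv)
  model <- shape_model(train)
  model_json <- file.path(out_dir, "model.json")
  write_shape_model(model, model_json)
  truth <- vector("list", n_validation)
  stack_files <- character(0)
  for (i in seq_len(n_validation)) {
    truth[[i]] <- generate_spine(template)
    stack <- simulate_heatmaps(truth[[i]], noise,
                               image_id = sprintf("val_%03d", i))
    tp <- file.path(out_dir, sprintf("val_%03d.tiff", i))
    sp <- file.path(out_dir, sprintf("val_%03d.json", i))
    write_heatmap_stack(stack, tp, sp)
    stack_files <- c(stack_files, tp, sp)
  }
  truth_csv <- file.path(out_dir, "truth_landmarks.csv")
  names(truth) <- sprintf("val_%03d", seq_len(n_validation))
  write_landmarks_csv(truth, truth_csv)
  files <- c(train_csv, model_json, stack_files, truth_csv)
  manifest <- list(seed = seed,
                   n_train = n_train, n_validation = n_validation,
                   template = template[setdiff(names(template), "seed")],
                   noise = noise[setdiff(names(noise), "seed")],
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(manifest)
}
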