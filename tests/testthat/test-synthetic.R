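test_that("spine generation is deterministic per seed and degenerates to congruent rectangles", {
  p <- spine_template_params(seed = 99L)
  a <- generate_spine(p)
  b <- generate_spine(p)
  expect_identical(unclass(a), unclass(b))

  p0 <- spine_template_params(width_cv = 0, height_cv = 0, gap_cv = 0,
                              curvature_amplitude = 0, tilt_sd = 0,
                              corner_jitter_sd = 0,
                              spondylolisthesis_fraction = 0, seed = 1L)
  rigid <- unclass(generate_spine(p0))
  for (j in 1:5) {
    i <- vertebra_indices(j)
    expect_equal(rigid[i[1], 2], rigid[i[2], 2], tolerance = 1e-12)  # UL/UR level
    expect_equal(unname(rigid[i[2], 1] - rigid[i[1], 1]), 60, tolerance = 1e-12)
    expect_equal(unname(rigid[i[3], 2] - rigid[i[1], 2]), 42, tolerance = 1e-12)
  }
  # congruence: identical corner offsets about each vertebra center
  ref <- sweep(rigid[1:4, ], 2, colMeans(rigid[1:4, ]))
  for (j in 2:5) {
    i <- vertebra_indices(j)
    expect_equal(sweep(rigid[i, ], 2, colMeans(rigid[i, ])), ref,
                 tolerance = 1e-10)
  }
})

test_that("generated spines are geometrically valid (ordering and convexity)", {
  set.seed(202)
  params <- spine_template_params()
  bad <- 0
  for (i in 1:1000) {
    p <- unclass(generate_spine(params))
    centers_y <- c(vapply(1:5, function(j)
      mean(p[vertebra_indices(j), 2]), 1), mean(p[21:22, 2]))
    ok <- all(diff(centers_y) > 0) &&
      all(vapply(1:5, function(j) quad_convex(p[vertebra_indices(j), ]), TRUE))
    if (!ok) bad <- bad + 1
  }
  expect_equal(bad, 0)
})

test_that("dataset labels hit the requested spondylolisthesis fraction", {
  p <- spine_template_params(spondylolisthesis_fraction = 0)
  d0 <- generate_dataset(p, n = 50, seed = 7)
  expect_true(all(vapply(d0, function(s) attr(s, "label"), "") == "normal"))

  p15 <- spine_template_params(spondylolisthesis_fraction = 0.15)
  d <- generate_dataset(p15, n = 2000, seed = 8)
  frac <- mean(vapply(d, function(s) attr(s, "label"), "") == "spondylolisthesis")
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / 2000))

  d2 <- generate_dataset(p15, n = 20, seed = 8)
  d3 <- generate_dataset(p15, n = 20, seed = 9)
  expect_false(identical(unclass(d2[[1]]), unclass(d3[[1]])))
})

test_that("clean simulated heatmaps reproduce the truth at argmax precision", {
  set.seed(13)
  spine <- generate_spine(spine_template_params(spondylolisthesis_fraction = 0))
  stack <- simulate_heatmaps(spine, heatmap_noise_params())
  det <- detect_initial(stack)
  err <- abs(unclass(det) - unclass(spine))
  expect_true(all(err <= 0.5 + 1e-12))  # per-axis grid quantization

  # integer-coordinate truth is recovered exactly
  fx <- integer_truth_stack(seed = 14)
  det2 <- detect_initial(fx$stack)
  expect_equal(unclass(det2)[1:22, ], unclass(fx$truth)[1:22, ], tolerance = 1e-12)
})

test_that("a designated peak shift lands the argmax at the requested distance", {
  set.seed(15)
  spine <- generate_spine(spine_template_params(spondylolisthesis_fraction = 0))
  stack <- simulate_heatmaps(spine,
                             heatmap_noise_params(shift_prob = 1,
                                                  shift_range = c(20, 20)),
                             landmarks_affected = 11)
  det <- detect_initial(stack)
  d <- sqrt(rowSums((unclass(det) - unclass(spine))^2))
  expect_gt(d[11], 20 - 1)
  expect_lt(d[11], 20 + 1)
  expect_true(all(d[-11] <= sqrt(2) / 2 + 1e-12))
})

test_that("a weaker spurious peak does not displace the argmax", {
  prim <- render_gaussian(c(30, 40), sigma = 5, height = 101, width = 101)
  spur <- render_gaussian(c(75, 20), sigma = 5, height = 101, width = 101)
  for (amp in c(0.3, 0.6, 0.95)) {
    combo <- heatmap_channel(prim$response + amp * spur$response,
                             landmark_index = 1)
    am <- channel_to_image(hasm:::channel_argmax(combo), combo)
    expect_equal(am, c(30, 40), tolerance = 1e-12)
  }
  # amplitude ordering on the rendered grid
  r <- prim$response + 0.6 * spur$response
  expect_gt(r[41, 31], r[21, 76])
})

test_that("additive noise and attenuation keep channels valid and near-recoverable", {
  set.seed(16)
  spine <- generate_spine(spine_template_params(spondylolisthesis_fraction = 0))
  stack <- simulate_heatmaps(spine,
                             heatmap_noise_params(atten_prob = 1,
                                                  atten_floor = 0.4,
                                                  noise_sd = 0.02))
  for (ch in stack$channels) {
    expect_true(all(ch$response >= 0))
    expect_true(all(is.finite(ch$response)))
  }
  det <- detect_initial(stack)
  d <- sqrt(rowSums((unclass(det) - unclass(spine))^2))
  expect_lt(max(d), 3)  # mild noise moves the argmax by at most a pixel or two
})

test_that("the shape model of a large draw concentrates variance in few modes", {
  set.seed(11)
  shapes <- generate_dataset(spine_template_params(), n = 500)
  model <- shape_model(shapes)
  cumvar <- cumsum(model$eigenvalues) / sum(model$eigenvalues)
  expect_gte(cumvar[5], 0.80)
})

test_that("fixtures are byte-reproducible and round-trip through every reader", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_fixture(1234, d1, n_train = 12, n_validation = 2)
  m2 <- make_fixture(1234, d2, n_train = 12, n_validation = 2)
  h1 <- vapply(m1$files, `[[`, "", "md5")
  h2 <- vapply(m2$files, `[[`, "", "md5")
  expect_identical(h1, h2)

  train <- read_landmarks_csv(file.path(d1, "train_landmarks.csv"))
  expect_length(train, 12)
  model <- read_shape_model(file.path(d1, "model.json"))
  expect_s3_class(model, "shape_model")
  truth <- read_landmarks_csv(file.path(d1, "truth_landmarks.csv"))
  stack <- read_heatmap_stack(file.path(d1, "val_001.tiff"),
                              file.path(d1, "val_001.json"))
  det <- detect_initial(stack)
  err <- abs(unclass(det) - unclass(truth[["val_001"]]))
  expect_true(all(err <= 0.5 + 1e-9))
  unlink(c(d1, d2), recursive = TRUE)
})
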