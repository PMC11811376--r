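test_that("gradient updates: zero sensitivity, vanishing gradient at the peak, and the ramp formula", {
  fx <- integer_truth_stack(seed = 31)
  det <- detect_initial(fx$stack)

  # mu = 0: bit-exact no-op
  ul0 <- update_landmarks(det, fx$stack, mu = 0)
  expect_identical(unclass(ul0), unclass(det))

  # at the exact Gaussian peak the sampled magnitude vanishes
  ch <- render_gaussian(c(10, 10), sigma = 4, height = 21, width = 21)
  gf <- compute_gradient_field(ch)
  g <- sample_gradient(gf, c(10, 10))
  expect_lt(unname(g["m_h"]), 1e-10)

  # linear ramp with gradient (2, 0): displacement mu * m_h = 0.04 in x
  ramp <- outer(0:40, 0:40, function(y, x) 2 * x)
  chans <- lapply(1:22, function(k)
    heatmap_channel(ramp, origin_offset = c(0, 0), scale = 1,
                    landmark_index = k))
  stack <- heatmap_stack(chans)
  cl <- landmarks(matrix(20, 22, 2))
  fields <- lapply(stack$channels, compute_gradient_field, normalize = FALSE)
  ul <- update_landmarks(cl, stack, mu = 0.02, fields = fields)
  # oracle: finite differences of the ramp give m_h = 2, o_h = 0
  cd <- central_diff(ramp)
  expect_equal(cd$gx[19, 19], 2, tolerance = 1e-12)
  expect_equal(unname(unclass(ul) - unclass(cl)),
               matrix(rep(c(0.04, 0), each = 22), 22, 2), tolerance = 1e-10)

  # out-of-channel landmarks are left untouched
  far <- landmarks(matrix(c(rep(20, 21), 500, rep(20, 22)), 22, 2))
  ul_far <- update_landmarks(far, stack, mu = 0.02, fields = fields)
  expect_identical(unclass(ul_far)[22, ], unclass(far)[22, ])
  expect_false(all(unclass(ul_far)[1, ] == unclass(far)[1, ]))
})

test_that("a zero iteration budget returns the initial detection with an empty trace", {
  fx <- integer_truth_stack(seed = 32)
  model <- small_model()
  res <- hasm_correct(fx$stack, model, hasm_config(max_iterations = 0))
  expect_identical(unclass(res$landmarks), unclass(res$initial))
  expect_length(res$trace, 0)
  expect_identical(res$iterations_run, 0L)
})

test_that("the loop is inert with mu = 0, all modes, and no clamping", {
  model <- small_model(seed = 41, n = 80)
  set.seed(42)
  spine <- generate_spine(spine_template_params())
  stack <- simulate_heatmaps(spine, heatmap_noise_params())
  det <- detect_initial(stack)
  cfg <- hasm_config(n_P = length(model$eigenvalues), mu = 0, clamp_k = NULL)
  res <- hasm_correct(stack, model, cfg)
  expect_lte(res$iterations_run, 2L)
  expect_lt(max(sqrt(rowSums((unclass(res$landmarks) - unclass(det))^2))),
            0.5)
  expect_true(all(is.finite(unclass(res$landmarks))))
})

test_that("corrected landmarks are equivariant to translating the channel windows", {
  model <- small_model(seed = 43, n = 80)
  set.seed(44)
  spine <- generate_spine(spine_template_params())
  stack <- simulate_heatmaps(spine, heatmap_noise_params(shift_prob = 1,
                                                         shift_range = c(15, 15)),
                             landmarks_affected = 9)
  delta <- c(17, -23)
  shifted <- stack
  shifted$channels <- lapply(stack$channels, function(ch) {
    ch$origin_offset <- ch$origin_offset + delta
    ch
  })
  r1 <- hasm_correct(stack, model, hasm_config())
  r2 <- hasm_correct(shifted, model, hasm_config())
  expect_equal(unclass(r2$landmarks),
               unclass(r1$landmarks) + rep(delta, each = 22),
               tolerance = 1e-9)
})

test_that("correction reduces the error of a single corrupted channel", {
  model <- small_model(seed = 45, n = 120)
  set.seed(46)
  wins <- 0
  for (i in 1:10) {
    spine <- generate_spine(spine_template_params())
    k <- sample.int(22, 1)
    stack <- simulate_heatmaps(spine,
                               heatmap_noise_params(shift_prob = 1,
                                                    shift_range = c(20, 20)),
                               landmarks_affected = k)
    res <- hasm_correct(stack, model, hasm_config())
    e0 <- max(sqrt(rowSums((unclass(res$initial) - unclass(spine))^2)))
    e1 <- max(sqrt(rowSums((unclass(res$landmarks) - unclass(spine))^2)))
    if (e1 < e0) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("snap-back post-processing follows the strict distance criterion", {
  fx <- integer_truth_stack(seed = 47)
  det <- detect_initial(fx$stack)  # argmaxes equal the integer truth here

  # gamma = 0: strict inequality means nothing ever snaps
  s0 <- snap_postprocess(det, fx$stack, gamma = 0)
  expect_identical(unclass(s0$landmarks), unclass(det))
  expect_false(any(s0$snapped))

  # a landmark at half the allowable error from its argmax snaps at gamma = 1
  ea <- allowable_error(det)
  off <- unclass(det)
  off[5, ] <- off[5, ] + c(0.5 * ea, 0)
  s1 <- snap_postprocess(landmarks(off), fx$stack, gamma = 1)
  expect_true(s1$snapped[5])
  expect_identical(unclass(s1$landmarks)[5, ], unclass(det)[5, ])
})

test_that("snapped sets are nested and mean error non-increasing over the gamma grid", {
  model <- small_model(seed = 48, n = 80)
  fx <- integer_truth_stack(seed = 49)
  res <- hasm_correct(fx$stack, model, hasm_config())
  gammas <- c(0.01, 0.03, 0.05, 0.07, 0.1)
  prev <- integer(0)
  prev_mean <- Inf
  for (g in gammas) {
    sp <- snap_postprocess(res$landmarks, fx$stack, gamma = g)
    cur <- which(sp$snapped)
    expect_true(all(prev %in% cur))
    prev <- cur
    e <- mean(sqrt(rowSums((unclass(sp$landmarks) - unclass(fx$truth))^2)))
    expect_lte(e, prev_mean + 1e-12)
    prev_mean <- e
  }
})

test_that("grid search picks the corrective candidate and carries the reference pair", {
  expect_true(any(default_candidates()$n_P == 20 &
                  default_candidates()$mu == 0.02))

  model <- small_model(seed = 50, n = 80)
  set.seed(51)
  spine <- generate_spine(spine_template_params())
  stack <- simulate_heatmaps(spine,
                             heatmap_noise_params(shift_prob = 1,
                                                  shift_range = c(20, 20)),
                             landmarks_affected = 3)
  validation <- list(list(stack = stack, truth = spine))

  single <- grid_search(data.frame(n_P = 7L, mu = 0.5), validation, model)
  expect_identical(single$n_P, 7L)
  expect_identical(single$mu, 0.5)

  cands <- data.frame(n_P = c(length(model$eigenvalues), 20L),
                      mu = c(0, 0.02))
  cfg <- hasm_config(clamp_k = NULL)
  best <- grid_search(cands, validation, model, cfg)
  expect_identical(best$n_P, 20L)
  expect_identical(best$mu, 0.02)
  expect_lt(best$results$AE_max[2], best$results$AE_max[1])
})
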