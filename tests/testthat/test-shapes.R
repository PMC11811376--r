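test_that("shape vector layout is (x1..x22, y1..y22) and roundtrips losslessly", {
  z <- landmarks(matrix(0, 22, 2))
  expect_identical(as_shape_vector(z), rep(0, 44))

  v <- as_shape_vector(index_spine())
  expect_equal(v, c(1:22, 101:122) * 1.0)

  back <- as_landmarks(v)
  expect_identical(unclass(back), unclass(index_spine()))
  expect_identical(as_shape_vector(as_landmarks(v)), v)

  expect_error(landmarks(matrix(0, 21, 2)), "22")
  expect_error(as_landmarks(rep(0, 43)), "44")
  expect_error(landmarks(matrix(c(NA, rep(0, 43)), 22, 2)), "finite")
})

test_that("fit_similarity recovers identity, pure translation, and constructed transforms", {
  src <- as_shape_vector(index_spine())

  id <- fit_similarity(src, src)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$angle, 0, tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0), tolerance = 1e-12)

  tr <- fit_similarity(src, apply_similarity(similarity_transform(1, 0, c(5, -2)), src))
  expect_equal(tr$scale, 1, tolerance = 1e-12)
  expect_equal(tr$angle, 0, tolerance = 1e-12)
  expect_equal(tr$translation, c(5, -2), tolerance = 1e-10)

  truth <- similarity_transform(2, 30 * pi / 180, c(3, 7))
  dst <- apply_similarity(truth, src)
  fit <- fit_similarity(src, dst)
  expect_equal(fit$scale, 2, tolerance = 1e-8)
  expect_equal(fit$angle, 30 * pi / 180, tolerance = 1e-8)
  expect_equal(fit$translation, c(3, 7), tolerance = 1e-8)

  # cross-check the closed form against direct numerical least squares:
  # the closed-form objective must not exceed the numerical optimum
  set.seed(21)
  noisy <- dst + rnorm(44, 0, 0.5)
  num <- numeric_similarity_ls(src, noisy)
  cf <- fit_similarity(src, noisy)
  cf_obj <- num$objective(c(log(cf$scale), cf$angle, cf$translation))
  expect_lte(cf_obj, num$value + 1e-8 * (1 + num$value))

  expect_error(fit_similarity(rep(c(1, 2), each = 22), src), "degenerate")
})

test_that("weighted similarity fits honor the weights", {
  src <- as_shape_vector(index_spine())
  dst <- apply_similarity(similarity_transform(1.5, 0.3, c(-4, 9)), src)
  dst[1] <- dst[1] + 50  # corrupt point 1
  w <- c(0, rep(1, 21))  # ignore it
  fit <- fit_similarity(src, dst, weights = w)
  expect_equal(fit$scale, 1.5, tolerance = 1e-8)
  expect_equal(fit$angle, 0.3, tolerance = 1e-8)
  expect_error(fit_similarity(src, dst, weights = rep(0, 22)), "weights")
})

test_that("generalized Procrustes aligns similarity-equivalent shapes exactly", {
  base <- as_shape_vector(index_spine())
  copies <- lapply(1:5, function(i)
    apply_similarity(similarity_transform(0.5 + i, i / 3, c(10 * i, -5 * i)), base))
  gpa <- generalized_procrustes(copies)
  expect_true(gpa$converged)
  expect_equal(sum(sv_centroid_test(gpa$mean)^2), 0, tolerance = 1e-18)
  expect_equal(sum(gpa$mean^2), 1, tolerance = 1e-10)
  for (a in gpa$aligned)
    expect_lt(sqrt(sum((a - gpa$aligned[[1]])^2)), 1e-8)
})

test_that("the GPA mean is invariant to input order and to pre-transforming inputs", {
  set.seed(9)
  shapes <- lapply(generate_dataset(spine_template_params(), n = 60),
                   as_shape_vector)
  gpa <- generalized_procrustes(shapes)
  perm <- sample(length(shapes))
  gpa_p <- generalized_procrustes(shapes[perm])
  # remove the rotational gauge before comparing means
  m2 <- apply_similarity(fit_similarity(gpa_p$mean, gpa$mean), gpa_p$mean)
  expect_lt(sqrt(sum((m2 - gpa$mean)^2)), 1e-6)

  shapes2 <- shapes
  shapes2[[4]] <- apply_similarity(similarity_transform(3, 1, c(100, 50)),
                                   shapes2[[4]])
  gpa_t <- generalized_procrustes(shapes2)
  m3 <- apply_similarity(fit_similarity(gpa_t$mean, gpa$mean), gpa_t$mean)
  expect_lt(sqrt(sum((m3 - gpa$mean)^2)), 1e-6)
})

test_that("PCA shape model: orthonormal modes, complete basis, variance accounting", {
  set.seed(2)
  shapes <- generate_dataset(spine_template_params(), n = 50)
  model <- shape_model(shapes)
  P <- model$eigenvectors
  expect_lt(max(abs(crossprod(P) - diag(ncol(P)))), 1e-10)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_true(all(model$eigenvalues >= 0))
  expect_equal(sum(sv_centroid_test(model$mean)^2), 0, tolerance = 1e-18)
  expect_equal(sum(model$mean^2), 1, tolerance = 1e-10)

  # eigenvalues sum to the total aligned (tangent-projected) variance
  gpa <- generalized_procrustes(lapply(shapes, as_shape_vector))
  proj <- lapply(gpa$aligned, function(a) a / sum(a * model$mean))
  A <- do.call(rbind, proj)
  total <- sum(sweep(A, 2, model$mean)^2) / (nrow(A) - 1)
  expect_equal(sum(model$eigenvalues), total, tolerance = 1e-8)

  # complete basis reproduces every training shape in model space
  for (i in c(1, 25, 50)) {
    a <- proj[[i]]
    rec <- model$mean + as.numeric(P %*% crossprod(P, a - model$mean))
    expect_lt(sqrt(sum((rec - a)^2)), 1e-8)
  }
})

test_that("a single direction of variation is captured by one dominant mode", {
  base <- as_shape_vector(unit_spine())
  set.seed(4)
  u <- rnorm(44); u <- u / sqrt(sum(u^2))
  shapes <- lapply(seq(-1, 1, length.out = 21), function(c)
    base + 0.1 * c * u)
  model <- shape_model(shapes)
  expect_gte(model$eigenvalues[1] / sum(model$eigenvalues), 0.999)
})

test_that("constrain_shape: mean shape under any similarity transform is a fixed point", {
  model <- small_model()
  Y <- apply_similarity(similarity_transform(120, 0.4, c(150, 220)), model$mean)
  res <- constrain_shape(Y, model, n_modes = 10)
  expect_lt(max(abs(res$b)), 1e-8)
  expect_lt(max(abs(res$X - Y)), 1e-8)
})

test_that("constrain_shape recovers constructed coefficients inside the clamp box", {
  model <- small_model()
  set.seed(8)
  n_modes <- 12
  b0 <- 0.8 * sqrt(model$eigenvalues[1:n_modes]) * rnorm(n_modes)
  Y <- apply_similarity(
    similarity_transform(90, -0.2, c(140, 200)),
    model$mean + as.numeric(model$eigenvectors[, 1:n_modes] %*% b0))
  res <- constrain_shape(Y, model, n_modes = n_modes, tol = 1e-9)
  expect_lt(max(abs(res$b - b0)), 1e-6)
  expect_lt(max(abs(res$X - Y)), 1e-6)
})

test_that("constrain_shape pulls an off-model outlier toward the clean shape", {
  model <- small_model()
  set.seed(10)
  for (trial in 1:5) {
    clean <- generate_spine(spine_template_params())
    Y <- unclass(clean)
    Y[7, ] <- Y[7, ] + c(15, -12)
    corrupted <- as_shape_vector(landmarks(Y))
    res <- constrain_shape(corrupted, model, n_modes = 20)
    clean_v <- as_shape_vector(clean)
    expect_lt(sqrt(sum((res$X - clean_v)^2)),
              sqrt(sum((corrupted - clean_v)^2)))
  }
})

test_that("constrain_shape is idempotent and equivariant to similarity transforms", {
  model <- small_model()
  set.seed(12)
  spine <- generate_spine(spine_template_params())
  Y <- as_shape_vector(spine)
  Y[5] <- Y[5] + 10
  r1 <- constrain_shape(Y, model, n_modes = 15)
  r2 <- constrain_shape(r1$X, model, n_modes = 15)
  expect_lt(max(abs(r2$X - r1$X)), 10 * 1e-6)

  tf <- similarity_transform(1.7, 0.25, c(-30, 60))
  rt <- constrain_shape(apply_similarity(tf, Y), model, n_modes = 15)
  expect_lt(max(abs(rt$X - apply_similarity(tf, r1$X))), 1e-4)
})

test_that("predict and simulate methods are consistent with the model", {
  model <- small_model()
  sims <- simulate(model, nsim = 3, seed = 99, n_modes = 10)
  expect_length(sims, 3)
  for (s in sims) {
    # simulated shapes are model-consistent: constraining changes them little
    p <- predict(model, s, n_modes = length(model$eigenvalues), clamp_k = NULL)
    expect_lt(max(abs(unclass(p) - unclass(s))), 1e-6)
  }
  expect_named(coef(model)[1], "lambda1")
})
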