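test_that("centroid size matches its definition and scales homogeneously", {
  sq <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5), 0)
  expect_equal(centroid_size(sq), sqrt(2))
  cfg <- rand_config(p = 289, seed = 42)
  # independent coordinate-wise recomputation of the definition
  direct <- sqrt(sum(apply(cfg, 2, function(v) sum((v - mean(v))^2))))
  expect_equal(centroid_size(cfg), direct, tolerance = 1e-14)
  expect_equal(centroid_size(cfg * 2), 2 * centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 5, 3)), "degenerate")
})

test_that("opa recovers similarity transforms and the 2D closed form", {
  ref <- rand_config(p = 8, seed = 1)
  moved <- similarity_transform(ref, seed = 2)
  expect_lt(opa(moved, ref)$distance, 1e-10)

  # planar pair: optimal angle equals the closed-form arctangent of the
  # cross/dot coordinate sums
  set.seed(3)
  a <- cbind(rnorm(5), rnorm(5), 0)
  theta0 <- 0.7
  Rz <- rbind(
    c(cos(theta0), sin(theta0), 0),
    c(-sin(theta0), cos(theta0), 0),
    c(0, 0, 1)
  )
  b <- sweep(1.7 * a %*% Rz, 2, c(1, -2, 0), `+`)
  A <- center_scale_ref(a)
  B <- center_scale_ref(b)
  theta <- atan2(
    sum(A[, 1] * B[, 2] - A[, 2] * B[, 1]),
    sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
  )
  expect_equal(theta, theta0, tolerance = 1e-12)
  fit2 <- opa(a, b)
  expect_lt(fit2$distance, 1e-12)
  expect_equal(atan2(fit2$rotation[1, 2], fit2$rotation[1, 1]), theta,
    tolerance = 1e-10
  )

  # chirality: a mirror image cannot be reached by a proper rotation
  mir <- ref
  mir[, 1] <- -mir[, 1]
  expect_gt(opa(mir, ref, allow_reflection = FALSE)$distance, 0.1)
  expect_lt(opa(mir, ref, allow_reflection = TRUE)$distance, 1e-10)

  expect_error(opa(ref[1:5, ], ref), "differ in size")
})

test_that("opa residual distance is symmetric in its arguments", {
  a <- rand_config(p = 7, seed = 4)
  b <- rand_config(p = 7, seed = 5)
  expect_equal(opa(a, b)$distance, opa(b, a)$distance, tolerance = 1e-12)
})

test_that("opa agrees with vegan's Procrustes rotation", {
  skip_if_not_installed("vegan")
  a <- rand_config(p = 9, seed = 6)
  b <- rand_config(p = 9, seed = 7)
  # vegan does not constrain the rotation to be proper, so compare the
  # reflection-permitting fit
  ours <- opa(a, b, allow_reflection = TRUE)
  ref <- vegan::procrustes(
    center_scale_ref(b), center_scale_ref(a),
    scale = FALSE, symmetric = FALSE
  )
  expect_equal(sum((ref$Yrot - center_scale_ref(b))^2), ours$distance^2,
    tolerance = 1e-8
  )
})

test_that("gpa collapses identical-up-to-similarity samples and is rotation invariant", {
  base <- rand_config(p = 10, seed = 8)
  coords <- array(NA_real_, c(10, 3, 4))
  for (i in 1:4) coords[, , i] <- similarity_transform(base, seed = 10 + i)
  fit <- gpa(landmark_dataset(coords))
  expect_lt(total_procrustes_variance(fit), 1e-12)

  ds <- small_dataset(n = 6, p = 8, seed = 9)
  f1 <- gpa(ds)
  set.seed(99)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  coords2 <- ds$coords
  for (i in 1:6) coords2[, , i] <- ds$coords[, , i] %*% rot
  f2 <- gpa(landmark_dataset(coords2, ds$points, ds$specimens))
  expect_equal(f1$tangent, f2$tangent, tolerance = 1e-8)
})

test_that("gpa matches a brute-force alternating minimization from random starts", {
  set.seed(20)
  coords <- array(NA_real_, c(6, 3, 3))
  for (i in 1:3) coords[, , i] <- rand_config(p = 6)
  fit <- gpa(landmark_dataset(coords), tol = 1e-12)
  ours <- sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
  for (s in 1:5) {
    oracle <- oracle_gpa(coords, tol = 1e-12, start_seed = s)
    expect_equal(oracle$objective, ours, tolerance = 1e-8)
    # consensuses agree up to a rotation
    expect_lt(opa(oracle$consensus, fit$consensus)$distance, 1e-6)
  }
})

test_that("gpa invariants hold: unit sizes, centered means, monotone objective", {
  sim <- simulate_landmarks(tiny_params(seed = 5))
  fit <- gpa(sim$dataset)
  for (i in seq_len(dim(fit$aligned)[3])) {
    expect_lt(abs(sum(fit$aligned[, , i]^2) - 1), 1e-12)
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-12)
  }
  expect_true(all(diff(fit$objective) <= 1e-12))
  expect_true(fit$converged)
})

test_that("tangent projection is the rank-one-deflated orthogonal projector", {
  ds <- small_dataset(n = 4, p = 6, seed = 11)
  fit <- gpa(ds)
  cvec <- as.vector(fit$consensus)
  # explicit projector oracle: identity minus outer product of unit consensus
  P <- diag(length(cvec)) - outer(cvec, cvec)
  for (i in 1:4) {
    dev <- as.vector(fit$aligned[, , i]) - cvec
    expect_equal(unname(fit$tangent[i, ]), as.vector(P %*% dev), tolerance = 1e-12)
    expect_lte(sqrt(sum(fit$tangent[i, ]^2)), sqrt(sum(dev^2)) + 1e-15)
  }
  # the consensus itself projects to the zero vector
  cons_fit <- fit
  cons_fit$aligned <- array(fit$consensus, c(dim(fit$consensus), 1))
  expect_lt(max(abs(tangent_project(cons_fit))), 1e-14)
})
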