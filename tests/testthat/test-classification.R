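test_that("shape PCA matches the closed-form 2x2 eigendecomposition", {
  y <- rbind(c(0, 0), c(2, 1), c(1, 3))
  pc <- shape_pca(y)
  S <- stats::cov(y)
  # characteristic-polynomial roots of the 2x2 covariance
  tr <- sum(diag(S))
  dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam <- sort(c((tr + sqrt(tr^2 - 4 * dt)) / 2, (tr - sqrt(tr^2 - 4 * dt)) / 2),
    decreasing = TRUE
  )
  expect_equal(pc$sdev^2, lam, tolerance = 1e-12)
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-9)
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
    ignore_attr = TRUE, tolerance = 1e-12
  )
})

test_that("PCA scores are invariant to a common pre-GPA rotation of the inputs", {
  ds <- small_dataset(n = 6, p = 8, seed = 40)
  set.seed(41)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  coords2 <- ds$coords
  for (i in 1:6) coords2[, , i] <- ds$coords[, , i] %*% rot
  p1 <- shape_pca(gpa(ds))
  p2 <- shape_pca(gpa(landmark_dataset(coords2, ds$points, ds$specimens)))
  pcs <- grep("^PC", names(p1$scores), value = TRUE)
  for (j in pcs) {
    expect_equal(abs(p1$scores[[j]]), abs(p2$scores[[j]]), tolerance = 1e-8)
  }
})

test_that("between-group PCA spans the group means with the expected geometry", {
  set.seed(42)
  # g = 2: exactly one axis
  y <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 3), 10, 2))
  b2 <- bgpca(y, rep(c("a", "b"), each = 10))
  expect_equal(ncol(b2$loadings), 1)

  # means differing only in coordinate 1: axis collinear with coordinate 1
  y2 <- matrix(rnorm(40, sd = 0.1), 20, 2)
  y2[11:20, 1] <- y2[11:20, 1] + 5
  y2[11:20, 2] <- y2[11:20, 2] - mean(y2[11:20, 2]) + mean(y2[1:10, 2])
  b1 <- bgpca(y2, rep(c("a", "b"), each = 10))
  expect_gt(abs(b1$loadings[1, 1]), 1 - 1e-9)

  # 3-group toy: axes match an independent eigendecomposition of the
  # group-mean matrix
  y3 <- matrix(rnorm(60), 30, 2)
  g3 <- rep(c("a", "b", "c"), each = 10)
  b3 <- bgpca(y3, g3)
  means <- t(sapply(c("a", "b", "c"), function(g) colMeans(y3[g3 == g, ])))
  M <- sweep(means, 2, colMeans(means))
  eig <- eigen(crossprod(M))
  for (j in 1:2) {
    expect_equal(abs(sum(b3$loadings[, j] * eig$vectors[, j])), 1, tolerance = 1e-9)
  }

  # isometry on the span: projected group means keep pairwise distances
  d_orig <- dist(M)
  d_proj <- dist(b3$group_scores)
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-9)

  expect_error(bgpca(y3, rep("a", 30)), ">= 2 groups")
})

test_that("LOOCV is perfect on separable groups and honest about leakage", {
  set.seed(43)
  n <- 20
  y <- rbind(
    matrix(rnorm(n / 2 * 4, sd = 1), n / 2, 4),
    matrix(rnorm(n / 2 * 4, mean = 10, sd = 1), n / 2, 4)
  )
  g <- rep(c("a", "b"), each = n / 2)
  rep1 <- loocv_classify(y, g)
  expect_equal(rep1$accuracy_pct, 100)
  expect_equal(rep1$kappa, 1)

  # no leakage: the fold-i model is fit entirely without specimen i — an
  # independent refit on y[-i, ] must reproduce loocv's prediction for i
  i <- 7
  b <- bgpca(y[-i, ], g[-i])
  sc <- as.vector((y[i, ] - b$center) %*% b$loadings)
  d <- sqrt(colSums((t(b$group_scores) - sc)^2))
  expect_identical(
    attr(rep1, "predictions")$predicted[i],
    rownames(b$group_scores)[which.min(d)]
  )
  # and changing specimen i's coordinates cannot change its own fold's model:
  # the assignment rule for i is a pure function of y[-i, ]
  y2 <- y
  y2[i, ] <- y[i, ] + 0.01
  rep2 <- loocv_classify(y2, g)
  expect_identical(
    attr(rep2, "predictions")$predicted[i],
    attr(rep1, "predictions")$predicted[i]
  )

  expect_error(loocv_classify(y[c(1, 11, 12), ], g[c(1, 11, 12)]), ">= 2 members")
})

test_that("LOOCV accuracy sits at chance for exchangeable groups", {
  set.seed(44)
  accs <- replicate(200, {
    y <- matrix(rnorm(20 * 3), 20, 3)
    loocv_classify(y, rep(c("a", "b"), each = 10))$accuracy_pct / 100
  })
  # chance rate for balanced LOOCV nearest-mean is just below 1/2; allow
  # 3 standard errors around 0.5
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("classification_report reproduces the published confusion summary", {
  cm <- matrix(c(5, 2, 2, 2), 2, byrow = TRUE, dimnames = list(c("f", "m"), c("f", "m")))
  rep <- classification_report(cm)
  expect_equal(round(rep$accuracy_pct, 1), 63.6)
  expect_equal(round(rep$per_class_pct["f", "f"], 1), 71.4)
  expect_equal(round(rep$per_class_pct["f", "m"], 1), 28.6)
  expect_equal(round(rep$per_class_pct["m", "m"], 1), 50.0)
  expect_equal(round(rep$kappa, 3), 0.214)
})

test_that("kappa anchors and permutation equivariance hold", {
  perfect <- diag(c(4, 6))
  rp <- classification_report(perfect)
  expect_equal(rp$accuracy_pct, 100)
  expect_equal(rp$kappa, 1)

  # marginal-product (independent) matrix: kappa = 0
  ind <- outer(c(6, 4), c(5, 5)) / 10
  expect_equal(classification_report(ind)$kappa, 0, tolerance = 1e-12)

  cm <- matrix(c(5, 2, 1, 4), 2, byrow = TRUE, dimnames = list(c("f", "m"), c("f", "m")))
  r1 <- classification_report(cm)
  r2 <- classification_report(cm[c(2, 1), c(2, 1)])
  expect_equal(r2$accuracy_pct, r1$accuracy_pct)
  expect_equal(r2$kappa, r1$kappa)
  expect_equal(r2$confusion["m", "f"], r1$confusion["m", "f"])

  expect_error(classification_report(matrix(0, 2, 2)), "all-zero")
})

test_that("replicate averaging collapses triads and keeps factors", {
  sim <- simulate_landmarks(tiny_params(seed = 45, n_sexed = 4, n_female = 2))
  fit <- gpa(sim$dataset)
  avg <- average_replicates(fit)
  expect_equal(nrow(avg$y), 6 * 2)
  expect_true(all(c("individual", "device", "sex") %in% names(avg$data)))
  key <- sim$dataset$specimens$individual == "ind01" &
    sim$dataset$specimens$device == "scan3d"
  expect_equal(
    avg$y[avg$data$individual == "ind01" & avg$data$device == "scan3d", ],
    colMeans(fit$tangent[key, , drop = FALSE]),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})
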