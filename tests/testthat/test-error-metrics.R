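test_that("the mean-squares repeatability formula is exact arithmetic", {
  # published worked example: among 1.96E-3, within 1.96E-4, r = 3 -> 0.750
  r <- repeatability_from_ms(1.96e-3, 1.96e-4, 3)
  expect_equal(round(r$r_value, 3), 0.750)

  # symbolic check on rational inputs: ms_among = 7/4, ms_within = 1/4, r = 2
  # s2 = (7/4 - 1/4)/2 = 3/4; R = (3/4)/(3/4 + 1/4) = 3/4 exactly
  r2 <- repeatability_from_ms(7 / 4, 1 / 4, 2)
  expect_identical(r2$r_value, 3 / 4)
  expect_identical(r2$s2_among, 3 / 4)

  expect_warning(r0 <- repeatability_from_ms(1, 1, 3), "not positive")
  expect_equal(r0$r_value, 0)
  expect_equal(repeatability_from_ms(2, 0, 3)$r_value, 1)
  # negative values are reported, not clamped
  expect_warning(rn <- repeatability_from_ms(0.5, 1, 2), "not positive")
  expect_lt(rn$r_value, 0)
  expect_error(repeatability_from_ms(1, 0.1, 1), "r >= 2")
})

test_that("repeatability pipeline recovers perfect and degraded designs", {
  # zero digitization noise: essentially perfect repeatability
  sim <- simulate_landmarks(tiny_params(
    seed = 21, devices = "d1", sigma_digitization = c(d1 = 0),
    da_magnitude = 0, sigma_fa = 0, device_offset_scale = 0,
    sigma_individual = 0.05
  ))
  expect_gt(repeatability(sim$dataset)$r_value, 0.999)

  # unbalanced replicates are rejected
  sim2 <- simulate_landmarks(tiny_params(seed = 22))
  ds2 <- subset_landmarks(sim2$dataset, specimens = -1)
  expect_error(repeatability(ds2, device = "scan3d"), "unbalanced")
})

test_that("fixed-only repeatability is lowest when fixed landmarks carry the noise", {
  # tangential-mode noise lives only at sliding points; after sliding it is
  # removed there, so the all-landmarks analysis must beat fixed-only when
  # extra isotropic noise is put on everything
  sim <- simulate_landmarks(tiny_params(
    seed = 23, devices = "d1", sigma_individual = 0.06,
    sigma_digitization = c(d1 = 0.025), da_magnitude = 0, sigma_fa = 0,
    device_offset_scale = 0
  ))
  r_all <- repeatability(sim$dataset,
    sliders = sim$template$sliders, landmark_subset = "all"
  )
  r_fix <- repeatability(sim$dataset, landmark_subset = "fixed_only")
  expect_lte(r_fix$r_value, r_all$r_value)
})

test_that("cell Procrustes variance follows its definition", {
  # identical replicates: zero variance
  y <- matrix(rnorm(4), 2, 2)[c(1, 1, 2, 2), ]
  dat <- tibble::tibble(
    individual = c("i1", "i1", "i2", "i2"), device = "d1"
  )
  pv <- procrustes_variance_by_group(y, dat)
  expect_equal(pv$variance, c(0, 0))

  # two replicates at distance d: variance d^2/4 (denominator n)
  d <- 1.8
  y2 <- rbind(c(0, 0), c(d, 0))
  dat2 <- tibble::tibble(individual = "i1", device = "d1")[c(1, 1), ]
  pv2 <- procrustes_variance_by_group(y2, dat2)
  expect_equal(pv2$variance, d^2 / 4)
  # unbiased option uses n - 1
  expect_equal(
    procrustes_variance_by_group(y2, dat2, unbiased = TRUE)$variance, d^2 / 2
  )

  # invariance under reordering of rows
  set.seed(30)
  y3 <- matrix(rnorm(36), 12, 3)
  dat3 <- tibble::tibble(
    individual = rep(c("a", "b"), each = 6),
    device = rep(rep(c("d1", "d2"), each = 3), 2)
  )
  pv3 <- procrustes_variance_by_group(y3, dat3)
  perm <- sample(12)
  pv3p <- procrustes_variance_by_group(y3[perm, ], dat3[perm, ])
  m <- merge(as.data.frame(pv3), as.data.frame(pv3p),
    by = c("individual", "device")
  )
  expect_equal(m$variance.x, m$variance.y, tolerance = 1e-12)

  # singleton cells are named
  dat4 <- dat3
  dat4$individual[1] <- "lonely"
  expect_error(procrustes_variance_by_group(y3, dat4), "lonely")
})

test_that("device variance comparison permutes within individuals reproducibly", {
  sim <- simulate_landmarks(tiny_params(
    seed = 31, n_individuals = 10,
    sigma_digitization = c(scan3d = 0.06, uct = 0.02),
    da_magnitude = 0, sigma_fa = 0, device_offset_scale = 0
  ))
  disp <- procrustes_variance_by_group(gpa(sim$dataset))
  p1 <- compare_group_variance(disp, n_perm = 199, seed = 5)
  p2 <- compare_group_variance(disp, n_perm = 199, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_lt(p1$p, 0.05)
  expect_warning(compare_group_variance(disp, n_perm = 50, seed = 1), "coarse")
})

test_that("a 2:1 digitization sd ratio yields a ~4x device variance ratio", {
  ratios <- vapply(1:6, function(s) {
    sim <- simulate_landmarks(tiny_params(
      seed = 100 + s, sigma_digitization = c(scan3d = 0.06, uct = 0.03),
      da_magnitude = 0, sigma_fa = 0, device_offset_scale = 0
    ))
    m <- attr(procrustes_variance_by_group(gpa(sim$dataset)), "device_means")
    m[["scan3d"]] / m[["uct"]]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.8)
})
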