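test_that("write/read round-trips are lossless for all dialects", {
  ds <- small_dataset(n = 5, p = 10)
  for (dialect in c("csv_long", "csv_wide", "tps")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(ds, f, dialect = dialect)
    back <- read_landmarks(f, dialect = dialect)
    expect_equal(unname(back$coords), unname(ds$coords),
      tolerance = 0, info = dialect
    )
    expect_equal(back$specimens$specimen, ds$specimens$specimen, info = dialect)
  }
  # csv_long also carries point names and roles
  f <- withr::local_tempfile(fileext = ".csv")
  ds$points$role[3:5] <- "patch"
  ds <- landmark_dataset(ds$coords, ds$points, ds$specimens)
  write_landmarks(ds, f, "csv_long")
  back <- read_landmarks(f, "csv_long")
  expect_identical(back$points$role, ds$points$role)
  expect_identical(back$points$name, ds$points$name)
})

test_that("a crafted csv_long file parses field by field", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen,name,x,y,z",
    "A,p1,0.5,1.25,-3",
    "A,p2,1,0,0",
    "A,p3,2,2,2",
    "B,p1,0.5,1.25,-3.5",
    "B,p2,1,0,0.25",
    "B,p3,2,1,2"
  ), f)
  ds <- read_landmarks(f, "csv_long")
  expect_equal(n_points(ds), 3)
  expect_equal(n_specimens(ds), 2)
  expect_identical(ds$points$name, c("p1", "p2", "p3"))
  expect_equal(ds$coords[, , 1], cbind(c(0.5, 1, 2), c(1.25, 0, 2), c(-3, 0, 2)),
    ignore_attr = TRUE
  )
  expect_equal(ds$coords[1, , 2], c(0.5, 1.25, -3.5), ignore_attr = TRUE)
})

test_that("structural errors name the offending specimen or row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen,name,x,y,z",
    "A,p1,0,0,0", "A,p2,1,1,1",
    "B,p1,0,0,0"
  ), f)
  expect_error(read_landmarks(f, "csv_long"), "B")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen,name,x,y,z",
    "A,p1,0,0,oops", "A,p2,1,1,1"
  ), f2)
  expect_error(read_landmarks(f2, "csv_long"), "non-numeric.*row 1")
})

test_that("read_landmarks preserves within-specimen row order", {
  ds <- small_dataset(n = 2, p = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  long <- as_tibble(ds)
  perm <- c(3, 1, 6, 2, 5, 4)
  long <- long[c(perm, perm + 6), ]
  readr::write_csv(long[, c("specimen", "name", "role", "x", "y", "z")], f)
  back <- read_landmarks(f, "csv_long")
  expect_equal(unname(back$coords[, , 1]), unname(ds$coords[perm, , 1]))
  expect_identical(back$points$name, ds$points$name[perm])
})

test_that("slider tables read in file order with valid-range checking", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("before,slide,after", "12,13,14", "13,14,15", "1,5,9"), f)
  sl <- read_sliders(f, n_points = 20)
  expect_equal(nrow(sl$curves), 3)
  expect_equal(sl$curves$slider, c(13, 14, 5))
  expect_equal(sl$curves$before[1], 12)
  expect_equal(sl$curves$after[1], 14)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("before,slide,after", "12,999,14"), f2)
  expect_error(read_sliders(f2, n_points = 289), "outside 1\\.\\.289")

  # degenerate rows rejected at construction
  expect_error(sliding_definition(data.frame(before = 3, slider = 3, after = 4)), "row 1")
})

test_that("bilateral tables round-trip and derive the midline as complement", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("right,left", "2,3", "5,6"), f)
  bl <- read_bilateral(f, n_points = 7)
  expect_equal(bl$pairs$right, c(2, 5))
  expect_equal(bl$midline, c(1, 4, 7))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_bilateral(bl, f2)
  expect_equal(read_bilateral(f2, n_points = 7)$pairs, bl$pairs)
})

test_that("validate_landmarks reports each violation and nothing else", {
  sim <- simulate_landmarks(tiny_params(seed = 2))
  ds <- sim$dataset
  tpl <- sim$template
  expect_equal(nrow(validate_landmarks(ds, tpl$sliders, tpl$bilateral)), 0)

  # bilateral map missing one point
  bad_bl <- bilateral_map(tpl$bilateral$pairs, midline = tpl$bilateral$midline[-1])
  rep1 <- validate_landmarks(ds, bilateral = bad_bl)
  expect_equal(nrow(rep1), 1)
  expect_match(rep1$message, paste0("\\b", tpl$bilateral$midline[1], "\\b"))

  # duplicated (individual, device, replicate) triple
  spec <- ds$specimens
  spec$replicate[2] <- spec$replicate[1]
  spec$individual[2] <- spec$individual[1]
  spec$device[2] <- spec$device[1]
  ds2 <- ds
  ds2$specimens <- spec
  rep2 <- validate_landmarks(ds2)
  expect_equal(nrow(rep2), 1)
  expect_match(rep2$message, "duplicated")
})

test_that("subsetting remaps slider and bilateral indices consistently", {
  sim <- simulate_landmarks(tiny_params(seed = 3))
  ds <- sim$dataset
  keep <- which(ds$points$role != "patch")
  sub <- subset_landmarks(ds, points = keep)
  sl2 <- remap_sliders(sim$template$sliders, keep)
  bl2 <- remap_bilateral(sim$template$bilateral, keep)
  expect_equal(nrow(validate_landmarks(sub, sl2, bl2)), 0)
  expect_equal(nrow(sl2$patches), 0)
  # remapped slider rows still reference the same physical points
  old <- sim$template$sliders$curves
  expect_equal(
    sub$coords[sl2$curves$slider[1], , 1],
    ds$coords[old$slider[1], , 1],
    ignore_attr = TRUE
  )
})
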