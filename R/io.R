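#' Read landmark configurations from a file
#'
#' Three dialects are supported, covering the usual export styles of
#' digitizing software and R morphometrics packages:
#' \describe{
#'   \item{`csv_long`}{columns `specimen, name, x, y, z` and optionally
#'     `role`; one row per point, point order = row order within specimen.}
#'   \item{`csv_wide`}{one row per specimen: column `specimen` then
#'     `x1,y1,z1,x2,y2,z2,...`.}
#'   \item{`tps`}{`LM3=p` blocks of `x y z` lines with `ID=` keys.}
#' }
#' Point indices in companion tables are 1-based positions in file order.
#'
#' @param path File path.
#' @param dialect One of `"csv_long"`, `"csv_wide"`, `"tps"`.
#' @param factors Optional data frame (or CSV path) of specimen factors keyed
#'   by `specimen`, merged into the dataset's factor table.
#' @param point_roles Optional character vector of per-point roles for
#'   dialects that cannot carry them (`csv_wide`, `tps`).
#' @return A [landmark_dataset()].
#' @export
read_landmarks <- function(path, dialect = c("csv_long", "csv_wide", "tps"),
                           factors = NULL, point_roles = NULL) {
  dialect <- match.arg(dialect)
  ds <- switch(dialect,
    csv_long = read_landmarks_long(path),
    csv_wide = read_landmarks_wide(path, point_roles),
    tps = read_landmarks_tps(path, point_roles)
  )
  if (!is.null(factors)) {
    if (is.character(factors)) {
      factors <- readr::read_csv(factors, show_col_types = FALSE)
    }
    factors <- tibble::as_tibble(factors)
    stopifnot("specimen" %in% names(factors))
    spec <- dplyr::left_join(
      ds$specimens[, "specimen"], factors,
      by = "specimen"
    )
    ds <- landmark_dataset(ds$coords, ds$points, spec)
  }
  ds
}

read_landmarks_long <- function(path) {
  # base read.csv: correctly rounded doubles, so write/read is bit-lossless
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("specimen", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("csv_long file must have columns specimen, x, y, z (got: ",
      paste(names(df), collapse = ", "), ")")
  }
  for (col in c("x", "y", "z")) {
    bad <- which(!is.na(df$specimen) & is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("non-numeric coordinate in column '", col, "' at data row ", bad[1])
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  as_landmark_dataset(df)
}

read_landmarks_wide <- function(path, point_roles) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot("specimen" %in% names(df))
  mat <- as.matrix(df[setdiff(names(df), "specimen")])
  if (!is.numeric(mat)) stop("non-numeric coordinate values in csv_wide file")
  if (ncol(mat) %% 3 != 0) stop("csv_wide coordinate columns not a multiple of 3")
  p <- ncol(mat) / 3
  coords <- array(NA_real_, c(p, 3, nrow(mat)))
  for (i in seq_len(nrow(mat))) {
    coords[, , i] <- matrix(mat[i, ], ncol = 3, byrow = TRUE)
  }
  points <- tibble::tibble(
    point = seq_len(p), name = sprintf("pt%03d", seq_len(p)),
    role = point_roles %||% "fixed"
  )
  landmark_dataset(coords, points, tibble::tibble(
    specimen = as.character(df$specimen),
    individual = as.character(df$specimen), device = "device1", replicate = 1L
  ))
}

read_landmarks_tps <- function(path, point_roles) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM3= blocks found in TPS file")
  blocks <- list()
  ids <- character()
  for (b in seq_along(starts)) {
    s <- starts[b]
    p <- as.integer(sub("^LM3\\s*=\\s*", "", lines[s], ignore.case = TRUE))
    rows <- lines[(s + 1):(s + p)]
    mat <- t(vapply(
      strsplit(rows, "\\s+"),
      function(v) {
        num <- suppressWarnings(as.numeric(v))
        if (length(num) != 3 || anyNA(num)) {
          stop("non-numeric or malformed coordinate line in TPS block ", b)
        }
        num
      },
      numeric(3)
    ))
    end <- if (b < length(starts)) starts[b + 1] - 1 else length(lines)
    idline <- grep("^ID\\s*=", lines[(s + p + 1):end], ignore.case = TRUE, value = TRUE)
    ids[b] <- if (length(idline)) sub("^ID\\s*=\\s*", "", idline[1], ignore.case = TRUE) else paste0("spec", b)
    blocks[[b]] <- mat
  }
  ps <- vapply(blocks, nrow, integer(1))
  if (length(unique(ps)) != 1) {
    stop(
      "inconsistent point counts across specimens: ",
      ids[which(ps != stats::median(ps))[1]]
    )
  }
  coords <- array(unlist(blocks), c(ps[1], 3, length(blocks)))
  points <- tibble::tibble(
    point = seq_len(ps[1]), name = sprintf("pt%03d", seq_len(ps[1])),
    role = point_roles %||% "fixed"
  )
  landmark_dataset(coords, points, tibble::tibble(
    specimen = ids, individual = ids, device = "device1", replicate = 1L
  ))
}

#' Write landmark configurations to a file
#'
#' Inverse of [read_landmarks()]; round-trips are lossless at full double
#' precision for all dialects.
#'
#' @param dataset A `landmark_dataset`.
#' @param path Output file path.
#' @param dialect One of `"csv_long"`, `"csv_wide"`, `"tps"`.
#' @export
write_landmarks <- function(dataset, path, dialect = c("csv_long", "csv_wide", "tps")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) sprintf("%.17g", v) # full double precision round-trip
  if (dialect == "csv_long") {
    long <- as_tibble(dataset)[, c("specimen", "name", "role", "x", "y", "z")]
    long <- dplyr::mutate(long, dplyr::across(c("x", "y", "z"), fmt))
    readr::write_csv(long, path)
  } else if (dialect == "csv_wide") {
    p <- n_points(dataset)
    mat <- t(apply(dataset$coords, 3, function(m) as.vector(t(m))))
    colnames(mat) <- paste0(rep(c("x", "y", "z"), p), rep(seq_len(p), each = 3))
    df <- dplyr::bind_cols(
      tibble::tibble(specimen = dataset$specimens$specimen),
      tibble::as_tibble(mat)
    )
    df <- dplyr::mutate(df, dplyr::across(-"specimen", fmt))
    readr::write_csv(df, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n_specimens(dataset))) {
      writeLines(sprintf("LM3=%d", n_points(dataset)), con)
      m <- dataset$coords[, , i]
      writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
      writeLines(sprintf("ID=%s", dataset$specimens$specimen[i]), con)
    }
  }
  invisible(path)
}

#' Read a slider-definition table (plus optional patch neighbors)
#'
#' The curve table is a headered CSV with columns `before, slide, after`
#' (or `before, slider, after`): 1-based point indices, the middle point
#' sliding along the chord through the two neighbors. The optional patch
#' table is a long CSV `point, neighbor` giving each patch point's tangent-
#' plane neighbor set (>= 3 rows per point).
#'
#' @param path Curve slider CSV path.
#' @param patches_path Optional patch-neighbor CSV path.
#' @param n_points Optional total point count, used to range-check indices.
#' @return A [sliding_definition()].
#' @export
read_sliders <- function(path, patches_path = NULL, n_points = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  if ("slide" %in% names(df)) names(df)[names(df) == "slide"] <- "slider"
  stopifnot(all(c("before", "slider", "after") %in% names(df)))
  patches <- NULL
  if (!is.null(patches_path)) {
    patches <- readr::read_csv(patches_path, show_col_types = FALSE)
    names(patches) <- tolower(names(patches))
  }
  sl <- sliding_definition(df, patches)
  if (!is.null(n_points)) {
    idx <- c(
      sl$curves$before, sl$curves$slider, sl$curves$after,
      sl$patches$point, sl$patches$neighbor
    )
    rowref <- which(
      sl$curves$before > n_points | sl$curves$slider > n_points |
        sl$curves$after > n_points
    )
    if (any(idx > n_points | idx < 1)) {
      stop(
        "slider table references point outside 1..", n_points,
        if (length(rowref)) paste0(" (curve row ", rowref[1], ")") else ""
      )
    }
  }
  sl
}

#' Read a bilateral-pair table
#'
#' Headered CSV with columns `right, left` (1-based point indices). Midline
#' points are all points not listed in either column.
#'
#' @param path CSV path.
#' @param n_points Total number of points in the dataset.
#' @return A [bilateral_map()].
#' @export
read_bilateral <- function(path, n_points) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("right", "left") %in% names(df)))
  if (any(c(df$right, df$left) > n_points | c(df$right, df$left) < 1)) {
    stop("bilateral table references point outside 1..", n_points)
  }
  bilateral_map(df, n_points = n_points)
}

#' Write slider / bilateral tables
#' @param sliders A `sliding_definition`.
#' @param path Curve table path.
#' @param patches_path Optional patch table path.
#' @export
write_sliders <- function(sliders, path, patches_path = NULL) {
  readr::write_csv(
    dplyr::rename(sliders$curves, slide = "slider"), path
  )
  if (!is.null(patches_path)) readr::write_csv(sliders$patches, patches_path)
  invisible(path)
}

#' @rdname write_sliders
#' @param bilateral A `bilateral_map`.
#' @export
write_bilateral <- function(bilateral, path) {
  readr::write_csv(bilateral$pairs, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
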