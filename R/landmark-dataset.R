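#' Stacked landmark configurations with point roles and a specimen factor table
#'
#' A `landmark_dataset` bundles the three pieces every stage of the pipeline
#' consumes: a `p x 3 x n` coordinate array (one `p x 3` configuration per
#' specimen), a point table describing each of the `p` points (name and role:
#' `"fixed"`, `"semilandmark"` or `"patch"`), and a specimen table with the
#' study factors (`individual`, `device`, `replicate`, optionally `sex`).
#'
#' All indices are 1-based, both in files and in memory. Every specimen must
#' share the same point count and point order, coordinates must be finite, and
#' `(individual, device, replicate)` triples must be unique.
#'
#' @param coords Numeric `p x 3 x n` array, or a list of `p x 3` matrices.
#' @param points Data frame with columns `name` and `role`, one row per point,
#'   or `NULL` to autogenerate names with role `"fixed"`.
#' @param specimens Data frame with one row per specimen: columns `specimen`
#'   (unique label), `individual`, `device`, `replicate` and optionally `sex`.
#'   If `NULL`, minimal labels are generated.
#' @return An object of class `landmark_dataset`.
#' @examples
#' cfg <- matrix(rnorm(30), 10, 3)
#' d <- landmark_dataset(array(c(cfg, cfg), c(10, 3, 2)))
#' d
#' @export
landmark_dataset <- function(coords, points = NULL, specimens = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    p <- nrow(coords[[1]])
    coords <- array(unlist(coords), dim = c(p, 3, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  p <- dim(coords)[1]
  n <- dim(coords)[3]
  if (!all(is.finite(coords))) {
    bad <- which(apply(coords, 3, function(m) !all(is.finite(m))))
    stop("non-finite coordinates in specimen(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(points)) {
    points <- tibble::tibble(
      point = seq_len(p),
      name = sprintf("pt%03d", seq_len(p)),
      role = "fixed"
    )
  } else {
    points <- tibble::as_tibble(points)
    if (!"point" %in% names(points)) points$point <- seq_len(p)
    stopifnot(nrow(points) == p, all(c("name", "role") %in% names(points)))
    if (!all(points$role %in% c("fixed", "semilandmark", "patch"))) {
      stop("point roles must be 'fixed', 'semilandmark' or 'patch'")
    }
  }
  if (is.null(specimens)) {
    specimens <- tibble::tibble(
      specimen = sprintf("spec%03d", seq_len(n)),
      individual = sprintf("ind%03d", seq_len(n)),
      device = "device1",
      replicate = 1L
    )
  } else {
    specimens <- tibble::as_tibble(specimens)
    stopifnot(nrow(specimens) == n, "specimen" %in% names(specimens))
    for (col in c("individual", "device", "replicate")) {
      if (!col %in% names(specimens)) {
        specimens[[col]] <- if (col == "replicate") 1L else specimens$specimen
      }
    }
    if (anyDuplicated(specimens$specimen)) stop("specimen labels must be unique")
    triple <- paste(specimens$individual, specimens$device, specimens$replicate)
    if (anyDuplicated(triple)) {
      stop(
        "duplicated (individual, device, replicate) triple: ",
        triple[duplicated(triple)][1]
      )
    }
  }
  dimnames(coords) <- list(points$name, c("x", "y", "z"), specimens$specimen)
  structure(
    list(coords = coords, points = points, specimens = specimens),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(
    "<landmark_dataset> ", n_specimens(x), " specimens x ", n_points(x),
    " points\n", sep = ""
  )
  cat("  roles: ", paste(
    sprintf("%s=%d", names(table(x$points$role)), table(x$points$role)),
    collapse = ", "
  ), "\n", sep = "")
  fac <- x$specimens
  cat(
    "  individuals: ", length(unique(fac$individual)),
    "; devices: ", paste(unique(fac$device), collapse = "/"),
    "; replicates: ", length(unique(fac$replicate)), "\n", sep = ""
  )
  invisible(x)
}

#' @export
n_points <- function(x) UseMethod("n_points")
#' @export
n_points.landmark_dataset <- function(x) dim(x$coords)[1]
#' @export
n_specimens <- function(x) UseMethod("n_specimens")
#' @export
n_specimens.landmark_dataset <- function(x) dim(x$coords)[3]

#' Convert a landmark dataset to/from a long tibble
#'
#' The long form has one row per (specimen, point) with columns
#' `specimen, point, name, role, x, y, z`, joined to the specimen factors.
#'
#' @param x A `landmark_dataset`.
#' @param ... Unused.
#' @return A tibble in long form.
#' @export
as_tibble.landmark_dataset <- function(x, ...) {
  p <- n_points(x)
  n <- n_specimens(x)
  xyz <- apply(x$coords, 2, identity) # (p*n) x 3
  out <- tibble::tibble(
    specimen = rep(x$specimens$specimen, each = p),
    point = rep(x$points$point, n),
    name = rep(x$points$name, n),
    role = rep(x$points$role, n),
    x = xyz[, 1],
    y = xyz[, 2],
    z = xyz[, 3]
  )
  dplyr::left_join(out, x$specimens, by = "specimen")
}

#' Build a landmark dataset from a long tibble
#'
#' @param df Data frame with columns `specimen, x, y, z` plus optional
#'   `name`, `role`, and factor columns (`individual`, `device`, `replicate`,
#'   `sex`). Point order within each specimen is row order.
#' @return A `landmark_dataset`.
#' @export
as_landmark_dataset <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("specimen", "x", "y", "z") %in% names(df)))
  specs <- unique(df$specimen)
  counts <- table(factor(df$specimen, levels = specs))
  if (length(unique(counts)) != 1L) {
    off <- names(counts)[counts != stats::median(counts)]
    stop("inconsistent point counts across specimens: ", paste(off, collapse = ", "))
  }
  p <- unname(counts[1])
  first <- df[df$specimen == specs[1], ]
  points <- tibble::tibble(
    point = seq_len(p),
    name = if ("name" %in% names(df)) as.character(first$name) else sprintf("pt%03d", seq_len(p)),
    role = if ("role" %in% names(df)) as.character(first$role) else "fixed"
  )
  coords <- array(NA_real_, c(p, 3, length(specs)))
  for (i in seq_along(specs)) {
    block <- df[df$specimen == specs[i], c("x", "y", "z")]
    coords[, , i] <- as.matrix(block)
  }
  faccols <- intersect(c("individual", "device", "replicate", "sex"), names(df))
  specimens <- dplyr::distinct(df[, c("specimen", faccols), drop = FALSE])
  landmark_dataset(coords, points, specimens)
}

#' Subset a landmark dataset by specimens and/or points
#'
#' Slider and bilateral tables refer to point indices, so after point
#' subsetting use [remap_sliders()] / [remap_bilateral()] to translate them.
#'
#' @param x A `landmark_dataset`.
#' @param specimens Logical or integer index, or character specimen labels.
#' @param points Logical or integer index into the point table.
#' @return A `landmark_dataset`.
#' @export
subset_landmarks <- function(x, specimens = NULL, points = NULL) {
  si <- seq_len(n_specimens(x))
  pi <- seq_len(n_points(x))
  if (!is.null(specimens)) {
    si <- if (is.character(specimens)) match(specimens, x$specimens$specimen) else si[specimens]
  }
  if (!is.null(points)) pi <- pi[points]
  pts <- x$points[pi, ]
  pts$point <- seq_along(pi)
  landmark_dataset(x$coords[pi, , si, drop = FALSE], pts, x$specimens[si, ])
}
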