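#' Sliding definition: which points slide, and along which neighbors
#'
#' Curve semilandmarks slide along the chord through their two neighbors
#' (one degree of freedom); patch points slide within a tangent plane
#' estimated from a neighbor set (two degrees of freedom). All indices are
#' 1-based positions in the dataset's point table.
#'
#' @param curves Data frame with integer columns `before`, `slider`, `after`.
#' @param patches Data frame with integer columns `point`, `neighbor`
#'   (long form: one row per neighbor; each patch point needs >= 3 neighbors),
#'   or `NULL` for none.
#' @return An object of class `sliding_definition`.
#' @export
sliding_definition <- function(curves = NULL, patches = NULL) {
  if (is.null(curves)) {
    curves <- tibble::tibble(before = integer(), slider = integer(), after = integer())
  }
  curves <- tibble::as_tibble(curves)
  stopifnot(all(c("before", "slider", "after") %in% names(curves)))
  curves <- dplyr::mutate(curves, dplyr::across(
    c("before", "slider", "after"), as.integer
  ))
  bad <- curves$before == curves$slider | curves$slider == curves$after
  if (any(bad)) {
    stop("slider row ", which(bad)[1], ": before/slider/after must be distinct")
  }
  if (anyDuplicated(curves$slider)) stop("duplicated curve slider index")
  if (!is.null(patches)) {
    patches <- tibble::as_tibble(patches)
    stopifnot(all(c("point", "neighbor") %in% names(patches)))
    patches <- dplyr::mutate(patches, dplyr::across(c("point", "neighbor"), as.integer))
    nn <- table(patches$point)
    if (any(nn < 3)) {
      stop(
        "patch point(s) with fewer than 3 neighbors: ",
        paste(names(nn)[nn < 3], collapse = ", ")
      )
    }
    if (any(patches$point %in% curves$slider)) {
      stop("a point cannot be both a curve slider and a patch point")
    }
  } else {
    patches <- tibble::tibble(point = integer(), neighbor = integer())
  }
  structure(list(curves = curves, patches = patches), class = "sliding_definition")
}

#' @export
print.sliding_definition <- function(x, ...) {
  cat(
    "<sliding_definition> ", nrow(x$curves), " curve sliders, ",
    length(unique(x$patches$point)), " patch points\n", sep = ""
  )
  invisible(x)
}

#' All sliding point indices (curve sliders then patch points)
#' @param sliders A `sliding_definition`.
#' @export
sliding_points <- function(sliders) {
  c(sliders$curves$slider, unique(sliders$patches$point))
}

#' Bilateral map: paired right/left points and unpaired midline points
#'
#' @param pairs Data frame with integer columns `right`, `left` (1-based point
#'   indices).
#' @param midline Integer vector of midline point indices, or `NULL` to derive
#'   it as the complement of the pairs when `n_points` is given.
#' @param n_points Total number of points (required when `midline` is NULL).
#' @return An object of class `bilateral_map`.
#' @export
bilateral_map <- function(pairs, midline = NULL, n_points = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("right", "left") %in% names(pairs)))
  pairs <- dplyr::mutate(pairs, dplyr::across(c("right", "left"), as.integer))
  used <- c(pairs$right, pairs$left)
  if (anyDuplicated(used)) {
    stop("point index appears twice in bilateral pairs: ", used[duplicated(used)][1])
  }
  if (is.null(midline)) {
    stopifnot(!is.null(n_points))
    midline <- setdiff(seq_len(n_points), used)
  }
  midline <- as.integer(midline)
  if (any(midline %in% used)) stop("midline point also appears in a pair")
  structure(list(pairs = pairs, midline = midline), class = "bilateral_map")
}

#' @export
print.bilateral_map <- function(x, ...) {
  cat(
    "<bilateral_map> ", nrow(x$pairs), " pairs, ",
    length(x$midline), " midline points\n", sep = ""
  )
  invisible(x)
}

#' Remap a sliding definition after point subsetting
#'
#' Sliders whose slider point or any referenced neighbor falls outside the
#' kept set are dropped.
#'
#' @param sliders A `sliding_definition`.
#' @param keep Integer vector of original point indices kept, in new order.
#' @export
remap_sliders <- function(sliders, keep) {
  map <- match(seq_len(max(keep, 0L, na.rm = TRUE)), keep)
  remap1 <- function(i) if (length(i)) map[i] else integer()
  cur <- sliders$curves
  cur <- dplyr::mutate(cur,
    before = remap1(.data$before), slider = remap1(.data$slider),
    after = remap1(.data$after)
  )
  cur <- cur[stats::complete.cases(cur), ]
  pat <- sliders$patches
  pat <- dplyr::mutate(pat, point = remap1(.data$point), neighbor = remap1(.data$neighbor))
  pat <- pat[stats::complete.cases(pat), ]
  if (nrow(pat)) {
    nn <- table(pat$point)
    pat <- pat[pat$point %in% as.integer(names(nn)[nn >= 3]), ]
  }
  sliding_definition(cur, if (nrow(pat)) pat else NULL)
}

#' Remap a bilateral map after point subsetting
#'
#' Pairs with either member dropped are removed entirely (a half pair cannot
#' be mirrored); midline points are kept where present.
#'
#' @param bilateral A `bilateral_map`.
#' @param keep Integer vector of original point indices kept, in new order.
#' @export
remap_bilateral <- function(bilateral, keep) {
  map <- match(seq_len(max(keep, 0L)), keep)
  pr <- bilateral$pairs
  pr <- dplyr::mutate(pr, right = map[.data$right], left = map[.data$left])
  pr <- pr[stats::complete.cases(pr), ]
  mid <- map[bilateral$midline]
  bilateral_map(pr, midline = mid[!is.na(mid)])
}

#' Structural validation of a dataset and its side-tables
#'
#' Checks every invariant the pipeline relies on and reports all violations
#' (an empty report means the inputs are consistent). This never throws.
#'
#' @param dataset A `landmark_dataset`.
#' @param sliders Optional `sliding_definition`.
#' @param bilateral Optional `bilateral_map`.
#' @return A tibble with columns `component`, `message`; zero rows if valid.
#' @export
validate_landmarks <- function(dataset, sliders = NULL, bilateral = NULL) {
  out <- list()
  add <- function(component, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(component = component, message = message)
  }
  p <- n_points(dataset)
  if (!all(is.finite(dataset$coords))) add("coords", "non-finite coordinates present")
  triple <- with(dataset$specimens, paste(individual, device, replicate))
  if (anyDuplicated(triple)) {
    add("factors", paste0(
      "duplicated (individual, device, replicate) triple: ",
      triple[duplicated(triple)][1]
    ))
  }
  if (!is.null(sliders)) {
    idx <- c(
      sliders$curves$before, sliders$curves$slider, sliders$curves$after,
      sliders$patches$point, sliders$patches$neighbor
    )
    bad <- idx[idx < 1 | idx > p]
    if (length(bad)) {
      add("sliders", paste0("point index out of range: ", paste(unique(bad), collapse = ", ")))
    }
    fixed <- which(dataset$points$role == "fixed")
    sl <- intersect(sliding_points(sliders), fixed)
    if (length(sl)) {
      add("sliders", paste0(
        "fixed landmark(s) declared as sliding: ", paste(sl, collapse = ", ")
      ))
    }
  }
  if (!is.null(bilateral)) {
    idx <- c(bilateral$pairs$right, bilateral$pairs$left, bilateral$midline)
    bad <- idx[idx < 1 | idx > p]
    if (length(bad)) {
      add("bilateral", paste0("point index out of range: ", paste(unique(bad), collapse = ", ")))
    }
    missing <- setdiff(seq_len(p), idx)
    if (length(missing)) {
      add("bilateral", paste0(
        "point(s) in neither pairs nor midline: ", paste(missing, collapse = ", ")
      ))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else tibble::tibble(component = character(), message = character())
}
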