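#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared deviations of the points from their
#' centroid; the size measure removed by Procrustes scaling.
#'
#' @param config Numeric `p x 3` (or `p x k`) matrix of coordinates.
#' @return Positive scalar.
#' @examples
#' sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5), 0)
#' centroid_size(sq) # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(nrow(config) >= 3, all(is.finite(config)))
  cen <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(cen^2))
  if (cs == 0) stop("degenerate configuration: all points coincident (zero centroid size)")
  cs
}

# Center at origin and scale to unit centroid size.
center_scale <- function(config) {
  cen <- sweep(as.matrix(config), 2, colMeans(config))
  cen / sqrt(sum(cen^2))
}

# Rotation taking a configuration to its principal axes (columns ordered by
# decreasing variance), with signs fixed by coordinate skewness and a proper
# determinant.
canonical_orientation <- function(config) {
  V <- svd(config, nu = 0)$v
  C2 <- config %*% V
  for (j in 1:2) {
    if (sum(C2[, j]^3) < 0) {
      V[, j] <- -V[, j]
      C2[, j] <- -C2[, j]
    }
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# Optimal rotation of (already centered) A onto B by SVD of crossprod.
# det +1 enforced unless allow_reflection.
optimal_rotation <- function(A, B, allow_reflection = FALSE) {
  sv <- svd(crossprod(A, B))
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  R
}

#' Ordinary Procrustes superimposition of one configuration on another
#'
#' Centers both configurations, scales both to unit centroid size, and
#' rotates `moving` to minimize the summed squared distance to `reference`.
#' The rotation is proper (determinant +1) unless `allow_reflection = TRUE`.
#'
#' @param moving,reference Numeric `p x 3` matrices with equal `p`.
#' @param allow_reflection Permit improper rotations (used when aligning
#'   mirrored copies).
#' @return List with `aligned` (transformed moving configuration, unit
#'   centroid size), `rotation`, and `distance` (root summed squared
#'   difference to the unit-scaled reference).
#' @export
opa <- function(moving, reference, allow_reflection = FALSE) {
  moving <- as.matrix(moving)
  reference <- as.matrix(reference)
  if (!identical(dim(moving), dim(reference))) {
    stop("configurations differ in size: ", nrow(moving), " vs ", nrow(reference), " points")
  }
  A <- center_scale(moving)
  B <- center_scale(reference)
  R <- optimal_rotation(A, B, allow_reflection)
  aligned <- A %*% R
  list(aligned = aligned, rotation = R, distance = sqrt(sum((aligned - B)^2)))
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes all configurations on their consensus: each
#' configuration is centered, scaled to unit centroid size and rotated to the
#' current consensus; the consensus is the coordinate-wise mean, renormalized
#' to unit centroid size. Iteration stops when the consensus moves by less
#' than `tol` (root-sum-square) or after `max_iter` iterations. The aligned
#' configurations are then projected to the tangent space at the consensus,
#' giving the shape variables used by all downstream statistics.
#'
#' @param dataset A [landmark_dataset()] (or `p x 3 x n` array).
#' @param tol Convergence tolerance on consensus change. Default `1e-10`.
#' @param max_iter Maximum iterations. Default 100.
#' @return An object of class `gpa_fit`: list with `aligned` (`p x 3 x n`),
#'   `consensus` (`p x 3`, unit centroid size), `centroid_sizes` (original
#'   sizes), `tangent` (`n x 3p` matrix of tangent-space deviations from the
#'   consensus), `iterations`, `converged`, `objective` (per-iteration summed
#'   squared distance of the aligned sample to its consensus, non-increasing),
#'   plus the dataset's `points` and `specimens` tables.
#' @seealso [slide_gpa()] for GPA interleaved with semilandmark sliding.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100) {
  if (inherits(dataset, "landmark_dataset")) {
    coords <- dataset$coords
    points <- dataset$points
    specimens <- dataset$specimens
  } else {
    coords <- dataset
    points <- NULL
    specimens <- NULL
  }
  n <- dim(coords)[3]
  stopifnot(n >= 2)
  sizes <- apply(coords, 3, centroid_size)
  aligned <- coords
  for (i in seq_len(n)) aligned[, , i] <- center_scale(coords[, , i])
  consensus <- center_scale(aligned[, , 1])
  converged <- FALSE
  iterations <- 0L
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)) {
      R <- optimal_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% R
    }
    new_consensus <- center_scale(apply(aligned, c(1, 2), mean))
    objective[it] <- sum(sweep(aligned, c(1, 2), new_consensus)^2)
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("GPA did not converge in ", max_iter, " iterations")
  # canonical orientation: principal axes of the consensus with a skewness
  # sign convention, so results do not depend on the inputs' common rotation
  rot <- canonical_orientation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot
  fit <- structure(
    list(
      aligned = aligned, consensus = consensus, centroid_sizes = sizes,
      tangent = NULL, iterations = iterations, converged = converged,
      objective = objective, points = points, specimens = specimens
    ),
    class = "gpa_fit"
  )
  fit$tangent <- tangent_project(fit)
  fit
}

#' Orthogonal tangent-space projection
#'
#' Projects each aligned configuration's deviation from the consensus onto
#' the hyperplane orthogonal to the (unit) consensus vector: with `c` the
#' flattened consensus, the deviation `x - c` is mapped to
#' `(I - c c')(x - c)`. The consensus itself projects to zero.
#'
#' @param fit A `gpa_fit`.
#' @return `n x 3p` matrix of tangent coordinates (deviations from consensus).
#' @export
tangent_project <- function(fit) {
  cvec <- as.vector(fit$consensus)
  n <- dim(fit$aligned)[3]
  X <- t(apply(fit$aligned, 3, as.vector))
  dev <- sweep(X, 2, cvec)
  tang <- dev - outer(as.vector(dev %*% cvec), cvec)
  rownames(tang) <- dimnames(fit$aligned)[[3]]
  tang
}

#' Total Procrustes variance of an aligned sample
#'
#' Mean squared deviation of the tangent coordinates from their mean
#' (denominator `n`), i.e. the trace of the sample covariance matrix with
#' divisor `n`.
#'
#' @param x A `gpa_fit` or an `n x q` matrix of shape variables.
#' @export
total_procrustes_variance <- function(x) {
  X <- if (inherits(x, "gpa_fit")) x$tangent else as.matrix(x)
  dev <- sweep(X, 2, colMeans(X))
  sum(dev^2) / nrow(X)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(
    "<gpa_fit> ", dim(x$aligned)[3], " specimens x ", dim(x$aligned)[1],
    " points; ", x$iterations, " iterations (",
    if (x$converged) "converged" else "NOT converged", ")\n", sep = ""
  )
  cat(sprintf("  total Procrustes variance: %.4g\n", total_procrustes_variance(x)))
  invisible(x)
}

#' Tidy an aligned Procrustes fit into a long tibble
#'
#' One row per (specimen, point) with aligned coordinates, joined to the
#' specimen factors when available.
#'
#' @param x A `gpa_fit`.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  p <- dim(x$aligned)[1]
  n <- dim(x$aligned)[3]
  spec <- if (!is.null(x$specimens)) x$specimens$specimen else sprintf("spec%03d", seq_len(n))
  out <- tibble::tibble(
    specimen = rep(spec, each = p),
    point = rep(seq_len(p), n),
    x = as.vector(x$aligned[, 1, ]),
    y = as.vector(x$aligned[, 2, ]),
    z = as.vector(x$aligned[, 3, ]),
    centroid_size = rep(x$centroid_sizes, each = p)
  )
  if (!is.null(x$points)) {
    out$name <- rep(x$points$name, n)
    out$role <- rep(x$points$role, n)
  }
  if (!is.null(x$specimens)) out <- dplyr::left_join(out, x$specimens, by = "specimen")
  out
}

#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(
    n_specimens = dim(x$aligned)[3],
    n_points = dim(x$aligned)[1],
    iterations = x$iterations,
    converged = x$converged,
    total_variance = total_procrustes_variance(x)
  )
}
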