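#' Repeatability from Procrustes ANOVA mean squares
#'
#' The intraclass-correlation analogue for a balanced one-factor repeated
#' measures design: with `r` replicates per group, the among-group variance
#' component is `s2 = (ms_among - ms_within) / r` and repeatability is
#' `R = s2 / (s2 + ms_within)`. Values near 1 indicate that among-individual
#' variation dwarfs digitization variation. A negative value (possible when
#' `ms_among <= ms_within`) is reported as-is with a warning, not clamped.
#'
#' @param ms_among Among-group (individual) mean square.
#' @param ms_within Within-group (residual) mean square.
#' @param r Replicates per group (>= 2).
#' @return A one-row tibble of class `repeatability`: columns `r_value`,
#'   `s2_among`, `ms_among`, `ms_within`, `replicates`.
#' @examples
#' repeatability_from_ms(1.96e-3, 1.96e-4, 3) # R = 0.750
#' @export
repeatability_from_ms <- function(ms_among, ms_within, r) {
  if (r < 2) stop("repeatability requires r >= 2 replicates per group")
  stopifnot(ms_among >= 0, ms_within >= 0)
  s2 <- (ms_among - ms_within) / r
  r_value <- s2 / (s2 + ms_within)
  if (ms_among <= ms_within && ms_within > 0) {
    warning("ms_among <= ms_within: repeatability is not positive (degenerate design?)")
  }
  out <- tibble::tibble(
    r_value = r_value, s2_among = s2,
    ms_among = ms_among, ms_within = ms_within, replicates = as.integer(r)
  )
  class(out) <- c("repeatability", class(out))
  out
}

# tangent coordinates of arbitrary configurations at a given consensus
tangent_coords_at <- function(configs, consensus) {
  cvec <- as.vector(consensus)
  X <- t(apply(configs, 3, as.vector))
  dev <- sweep(X, 2, cvec)
  dev - outer(as.vector(dev %*% cvec), cvec)
}

#' Repeatability of digitization for one device
#'
#' Re-runs the full alignment on the requested subset — specimens of one
#' device, optionally restricted to landmark types — and computes the
#' intraclass-correlation repeatability from a one-factor (individual)
#' Procrustes ANOVA of the resulting shape variables. When a bilateral map
#' is supplied the ANOVA is run on the symmetric shape component (the usual
#' choice for repeatability studies); sliders, when supplied, are re-slid on
#' the subset. Landmark subsets re-run the superimposition from scratch, so
#' results are not nested versions of the full analysis.
#'
#' @param dataset A [landmark_dataset()] with replicate digitizations.
#' @param device Device label to subset to, or `NULL` to use all specimens.
#' @param landmark_subset `"all"`, `"fixed_curves"` (drops patch points) or
#'   `"fixed_only"`.
#' @param bilateral Optional [bilateral_map()]; triggers symmetric-component
#'   analysis.
#' @param sliders Optional [sliding_definition()] for semilandmark sliding.
#' @param n_cycles Sliding cycles when `sliders` is given.
#' @return A `repeatability` tibble (see [repeatability_from_ms()]) with the
#'   ANOVA table attached as attribute `"anova"`.
#' @export
repeatability <- function(dataset, device = NULL,
                          landmark_subset = c("all", "fixed_curves", "fixed_only"),
                          bilateral = NULL, sliders = NULL, n_cycles = 3) {
  landmark_subset <- match.arg(landmark_subset)
  if (!is.null(device)) {
    dataset <- subset_landmarks(dataset, specimens = dataset$specimens$device == device)
  }
  keep_roles <- switch(landmark_subset,
    all = c("fixed", "semilandmark", "patch"),
    fixed_curves = c("fixed", "semilandmark"),
    fixed_only = "fixed"
  )
  keep <- which(dataset$points$role %in% keep_roles)
  if (length(keep) < n_points(dataset)) {
    if (!is.null(bilateral)) bilateral <- remap_bilateral(bilateral, keep)
    if (!is.null(sliders)) sliders <- remap_sliders(sliders, keep)
    dataset <- subset_landmarks(dataset, points = keep)
  }
  reps <- table(dataset$specimens$individual)
  if (length(unique(reps)) != 1L) {
    stop("unbalanced replicate counts across individuals; the ICC formula assumes balance")
  }
  r <- unname(reps[1])
  fit <- if (!is.null(sliders)) {
    slide_gpa(dataset, sliders, n_cycles = n_cycles)
  } else {
    gpa(dataset)
  }
  if (!is.null(bilateral)) {
    dec <- decompose_symmetry(
      landmark_dataset(fit$aligned, dataset$points, dataset$specimens), bilateral
    )
    y <- tangent_coords_at(dec$symmetric, dec$consensus)
  } else {
    y <- fit$tangent
  }
  tab <- procrustes_anova(y, ~individual, data = dataset$specimens, n_perm = 0)
  out <- repeatability_from_ms(
    tab$MS[tab$term == "individual"], tab$MS[tab$term == "Residuals"], r
  )
  out$device <- device %||% "all"
  out$landmark_subset <- landmark_subset
  out$symmetric <- !is.null(bilateral)
  attr(out, "anova") <- tab
  out
}

#' Procrustes variance per individual/device cell
#'
#' For each cell (set of replicate digitizations of one individual on one
#' device) the Procrustes variance is the mean squared deviation of the
#' replicates' shape variables from the cell mean — the trace of the cell's
#' covariance matrix with divisor `n` (the number of observations; set
#' `unbiased = TRUE` for divisor `n - 1`). Because individual and device are
#' constant within a cell, this isolates digitization variation. The
#' device-level value is the unweighted mean over that device's cells.
#'
#' @param fit A `gpa_fit` (its tangent coordinates and specimen factors are
#'   used), or an `n x q` matrix with `data` supplied.
#' @param data Factor table with `individual` and `device` columns.
#' @param unbiased Use divisor `n - 1` instead of `n`. Default `FALSE`.
#' @return A tibble of class `gm_disparity`: one row per cell with columns
#'   `individual, device, n, variance`; device means and their observed
#'   absolute difference are attached as attributes `"device_means"` and
#'   `"observed_diff"`.
#' @export
procrustes_variance_by_group <- function(fit, data = NULL, unbiased = FALSE) {
  if (inherits(fit, "gpa_fit")) {
    if (is.null(data)) data <- fit$specimens
    y <- fit$tangent
  } else {
    y <- as.matrix(fit)
  }
  stopifnot(!is.null(data), nrow(data) == nrow(y))
  cells <- dplyr::distinct(tibble::as_tibble(data)[, c("individual", "device")])
  res <- purrr::pmap_dfr(cells, function(individual, device) {
    rows <- data$individual == individual & data$device == device
    m <- sum(rows)
    if (m < 2) {
      stop("singleton cell: individual ", individual, ", device ", device)
    }
    block <- y[rows, , drop = FALSE]
    dev <- sweep(block, 2, colMeans(block))
    tibble::tibble(
      individual = individual, device = device, n = m,
      variance = sum(dev^2) / (m - as.integer(unbiased))
    )
  })
  means <- tapply(res$variance, res$device, mean)
  class(res) <- c("gm_disparity", class(res))
  attr(res, "device_means") <- means
  attr(res, "observed_diff") <- if (length(means) == 2) abs(diff(means)) else NA_real_
  res
}

#' Permutation comparison of per-device Procrustes variance
#'
#' Tests whether digitization variance differs between exactly two devices
#' by permuting device labels within each individual (the paired structure
#' of the design), recomputing the absolute difference of device mean
#' variances, and reporting `p = (b + 1) / (n_perm + 1)`.
#'
#' @param disparity A `gm_disparity` from [procrustes_variance_by_group()].
#' @param n_perm Number of permutations (warning below 99).
#' @param seed Integer seed.
#' @return A one-row tibble: device means, observed absolute difference, `p`.
#' @export
compare_group_variance <- function(disparity, n_perm = 999, seed = NULL) {
  devices <- sort(unique(disparity$device))
  if (length(devices) != 2) stop("exactly 2 device groups required")
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value")
  if (is.null(seed)) stop("seed is required")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(disparity)[, c("individual", "device", "variance")],
    names_from = "device", values_from = "variance"
  )
  a <- wide[[devices[1]]]
  b <- wide[[devices[2]]]
  if (anyNA(a) || anyNA(b)) stop("every individual needs a cell on both devices")
  obs <- abs(mean(a) - mean(b))
  set.seed(as.integer(seed))
  k <- length(a)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    flip <- stats::runif(k) < 0.5
    aa <- ifelse(flip, b, a)
    bb <- ifelse(flip, a, b)
    if (abs(mean(aa) - mean(bb)) >= obs - 1e-15) cnt <- cnt + 1L
  }
  tibble::tibble(
    device_a = devices[1], device_b = devices[2],
    mean_a = mean(a), mean_b = mean(b),
    observed_diff = obs,
    n_perm = as.integer(n_perm),
    p = (cnt + 1) / (n_perm + 1)
  )
}
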