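#' Principal component analysis of shape variables
#'
#' Eigendecomposition of the specimen covariance matrix of the shape
#' variables (tangent coordinates), components ordered by decreasing
#' variance.
#'
#' @param y A `gpa_fit` or an `n x q` matrix of shape variables.
#' @param data Optional factor table bound to the scores.
#' @return An object of class `shape_pca`: list with `scores` tibble
#'   (specimen factors + `PC1..PCk`), `variance_explained` (percent per
#'   component), `sdev`, and `loadings` (orthonormal columns).
#' @export
shape_pca <- function(y, data = NULL) {
  if (inherits(y, "gpa_fit")) {
    if (is.null(data)) data <- y$specimens
    y <- y$tangent
  }
  Y <- as.matrix(y)
  stopifnot(nrow(Y) >= 2)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  ve <- 100 * pc$sdev[keep]^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, keep, drop = FALSE])
  if (!is.null(data)) scores <- dplyr::bind_cols(tibble::as_tibble(data), scores)
  structure(
    list(
      scores = scores, variance_explained = ve,
      sdev = pc$sdev[keep], loadings = pc$rotation[, keep, drop = FALSE],
      center = pc$center
    ),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(3, length(x$variance_explained))
  cat("<shape_pca> ", nrow(x$scores), " specimens, ",
    length(x$variance_explained), " components\n", sep = "")
  cat("  ", paste(
    sprintf("PC%d = %.1f%%", seq_len(k), x$variance_explained[seq_len(k)]),
    collapse = ", "
  ), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_explained)),
    sdev = x$sdev,
    variance_explained = x$variance_explained,
    cumulative = cumsum(x$variance_explained)
  )
}

#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$variance_explained),
    pc1_pct = x$variance_explained[1],
    pc3_cumulative = sum(x$variance_explained[seq_len(min(3, length(x$variance_explained)))])
  )
}

#' Between-group principal component analysis
#'
#' Principal components of the `g` group mean vectors (groups weighted
#' equally regardless of size), giving at most `g - 1` axes; all specimens
#' are projected onto those axes after centering on the grand mean of the
#' group means.
#'
#' @param y An `n x q` matrix of shape variables (or `gpa_fit`).
#' @param groups Factor/character vector of group labels, length `n`.
#' @return An object of class `bgpca`: `scores` tibble (`group`,
#'   `bgPC1..`), `group_means` (rows = groups, original variable space),
#'   `group_scores` (means projected on the axes), `loadings`
#'   (orthonormal `q x (g-1)`), `variance_explained` (percent of group-mean
#'   variance per axis), `center`.
#' @export
bgpca <- function(y, groups) {
  if (inherits(y, "gpa_fit")) y <- y$tangent
  Y <- as.matrix(y)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(Y))
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need >= 2 groups")
  sizes <- table(factor(groups, levels = glev))
  if (any(sizes == 0)) stop("empty group: ", names(sizes)[sizes == 0][1])
  means <- t(vapply(glev, function(g) colMeans(Y[groups == g, , drop = FALSE]),
    numeric(ncol(Y))))
  center <- colMeans(means)
  M <- sweep(means, 2, center)
  sv <- svd(M, nu = 0)
  k <- min(length(glev) - 1L, sum(sv$d > max(sv$d) * 1e-10))
  V <- sv$v[, seq_len(k), drop = FALSE]
  ev <- sv$d[seq_len(k)]^2
  scores <- sweep(Y, 2, center) %*% V
  colnames(scores) <- paste0("bgPC", seq_len(k))
  gm_scores <- M %*% V
  rownames(gm_scores) <- glev
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(group = groups), tibble::as_tibble(scores)
      ),
      group_means = means, group_scores = gm_scores,
      loadings = V,
      variance_explained = 100 * ev / sum(sv$d^2),
      center = center
    ),
    class = "bgpca"
  )
}

#' @export
print.bgpca <- function(x, ...) {
  cat("<bgpca> ", nrow(x$scores), " specimens, ",
    nrow(x$group_means), " groups, ", ncol(x$loadings), " axes\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated classification by between-group PCA
#'
#' For each specimen in turn: drop it, recompute the group means (and, by
#' default, the between-group PCA axes), project the held-out specimen, and
#' assign it to the group whose projected mean is nearest (Euclidean
#' distance in the bgPC score space). Ties go deterministically to the
#' first group in sorted label order, with a warning.
#'
#' @param y An `n x q` matrix of shape variables (or `gpa_fit`).
#' @param groups Group labels, length `n`; every group needs >= 2 members.
#' @param refit_axes Recompute the bgPCA axes without the held-out specimen
#'   (default); `FALSE` refits only the group means and reuses the full-
#'   sample axes.
#' @return A `classification_report` (see [classification_report()]) with
#'   the per-specimen predictions attached as attribute `"predictions"`.
#' @export
loocv_classify <- function(y, groups, refit_axes = TRUE) {
  if (inherits(y, "gpa_fit")) y <- y$tangent
  Y <- as.matrix(y)
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  sizes <- table(factor(groups, levels = glev))
  if (any(sizes < 2)) {
    stop("every group needs >= 2 members for leave-one-out (",
      names(sizes)[sizes < 2][1], " has ", min(sizes), ")")
  }
  full <- if (!refit_axes) bgpca(Y, groups) else NULL
  pred <- character(nrow(Y))
  tie_seen <- FALSE
  for (i in seq_len(nrow(Y))) {
    yt <- Y[-i, , drop = FALSE]
    gt <- groups[-i]
    if (refit_axes) {
      b <- bgpca(yt, gt)
      V <- b$loadings
      center <- b$center
      gm <- b$group_scores
    } else {
      V <- full$loadings
      means <- t(vapply(glev, function(g) colMeans(yt[gt == g, , drop = FALSE]),
        numeric(ncol(Y))))
      center <- colMeans(means)
      gm <- sweep(means, 2, center) %*% V
      rownames(gm) <- glev
    }
    sc <- as.vector((Y[i, ] - center) %*% V)
    d <- sqrt(colSums((t(gm) - sc)^2))
    best <- which(d <= min(d) + 1e-12)
    if (length(best) > 1) tie_seen <- TRUE
    pred[i] <- rownames(gm)[best[1]]
  }
  if (tie_seen) warning("distance tie(s) broken toward the first group in label order")
  confusion <- table(
    true = factor(groups, levels = glev),
    predicted = factor(pred, levels = glev)
  )
  rep <- classification_report(unclass(confusion))
  attr(rep, "predictions") <- tibble::tibble(true = groups, predicted = pred)
  rep
}

#' Confusion-matrix summary: accuracy, per-class rates, Cohen's kappa
#'
#' @param confusion Square matrix of non-negative integer counts, rows = true
#'   class, columns = predicted class.
#' @return An object of class `classification_report`: list with `confusion`,
#'   `per_class_pct` (row-normalized percentages), `accuracy_pct`
#'   (`100 * trace / total`), and `kappa`
#'   (`(p_o - p_e) / (1 - p_e)`, expected agreement from the row/column
#'   marginal products).
#' @examples
#' classification_report(matrix(c(5, 2, 2, 2), 2, byrow = TRUE,
#'   dimnames = list(c("f", "m"), c("f", "m"))))
#' @export
classification_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("all-zero confusion matrix")
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  per_class <- 100 * sweep(confusion, 1, pmax(rowSums(confusion), 1), "/")
  structure(
    list(
      confusion = confusion, per_class_pct = per_class,
      accuracy_pct = 100 * p_o, kappa = kappa
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  print(x$confusion)
  cat(sprintf("  accuracy: %.1f%%   kappa: %.3f\n", x$accuracy_pct, x$kappa))
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) {
  cf <- as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)
  names(cf) <- c("true", "predicted", "n")
  pc <- as.data.frame(as.table(x$per_class_pct), stringsAsFactors = FALSE)
  cf$pct <- pc$Freq
  tibble::as_tibble(cf)
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    accuracy_pct = x$accuracy_pct,
    kappa = x$kappa,
    n = sum(x$confusion),
    n_classes = nrow(x$confusion)
  )
}

#' Average replicate shapes within individual/device
#'
#' Averages the shape variables of each individual's replicate set
#' separately per device (the usual preparation before between-group PCA on
#' a replicate design, keeping devices distinct).
#'
#' @param y An `n x q` matrix of shape variables (or `gpa_fit`).
#' @param data Factor table with `individual`, `device` and any columns to
#'   carry through (e.g. `sex`).
#' @return List with `y` (averaged matrix, one row per individual x device)
#'   and `data` (collapsed factor table).
#' @export
average_replicates <- function(y, data = NULL) {
  if (inherits(y, "gpa_fit")) {
    if (is.null(data)) data <- y$specimens
    y <- y$tangent
  }
  Y <- as.matrix(y)
  data <- tibble::as_tibble(data)
  key <- paste(data$individual, data$device, sep = "\r")
  ukey <- unique(key)
  out <- t(vapply(ukey, function(k) colMeans(Y[key == k, , drop = FALSE]),
    numeric(ncol(Y))))
  carry <- dplyr::distinct(
    data[, setdiff(names(data), c("specimen", "replicate")), drop = FALSE]
  )
  meta <- carry[match(ukey, paste(carry$individual, carry$device, sep = "\r")), ]
  list(y = out, data = meta)
}
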