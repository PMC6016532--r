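#' Estimate tangent directions for sliding points
#'
#' Curve semilandmarks get one allowed direction: the unit chord from their
#' before-neighbor to their after-neighbor. Patch points get two: the top
#' two principal directions of their neighbor set centered on the point
#' (an orthonormal basis of the local least-squares tangent plane).
#' Tangents are normally estimated on the consensus configuration so the
#' frames are stable across specimens.
#'
#' @param config Numeric `p x 3` matrix (typically the GPA consensus).
#' @param sliders A [sliding_definition()].
#' @return A list of class `tangent_frame`: per sliding point index, a
#'   `3 x k` orthonormal basis matrix (`k` = 1 for curves, 2 for patches).
#' @export
estimate_tangents <- function(config, sliders) {
  config <- as.matrix(config)
  frames <- list()
  cur <- sliders$curves
  for (i in seq_len(nrow(cur))) {
    chord <- config[cur$after[i], ] - config[cur$before[i], ]
    len <- sqrt(sum(chord^2))
    if (len < 1e-12) {
      stop("coincident neighbors for curve slider at point ", cur$slider[i])
    }
    frames[[as.character(cur$slider[i])]] <- matrix(chord / len, ncol = 1)
  }
  pat <- sliders$patches
  for (pt in unique(pat$point)) {
    nb <- pat$neighbor[pat$point == pt]
    M <- sweep(config[nb, , drop = FALSE], 2, config[pt, ])
    sv <- svd(M, nu = 0, nv = 2)
    if (sv$d[2] < 1e-12) {
      stop("degenerate (collinear) neighbor set for patch point ", pt)
    }
    frames[[as.character(pt)]] <- sv$v
  }
  structure(frames, class = "tangent_frame")
}

#' One sliding pass toward the consensus
#'
#' Moves every sliding point by the orthogonal projection of its deviation
#' from the consensus (`consensus point - current point`) onto its tangent
#' basis. Fixed landmarks are untouched (bitwise). In exact arithmetic this
#' never increases the Procrustes distance to the consensus.
#'
#' @param aligned `p x 3 x n` array of superimposed configurations.
#' @param consensus `p x 3` consensus configuration.
#' @param frames A `tangent_frame` from [estimate_tangents()].
#' @return Updated `p x 3 x n` array.
#' @export
slide_once <- function(aligned, consensus, frames) {
  out <- aligned
  idx <- as.integer(names(frames))
  for (j in seq_along(frames)) {
    pt <- idx[j]
    Tb <- frames[[j]]
    P <- Tb %*% t(Tb)
    for (i in seq_len(dim(aligned)[3])) {
      dev <- consensus[pt, ] - out[pt, , i]
      out[pt, , i] <- out[pt, , i] + as.vector(P %*% dev)
    }
  }
  out
}

#' GPA with sliding semilandmarks
#'
#' Alternates generalized Procrustes superimposition with sliding: after each
#' GPA, tangent frames are estimated on the consensus, sliding points are
#' moved within their frames toward the consensus, and the slid dataset is
#' re-superimposed. Runs for `n_cycles` cycles or until the consensus changes
#' by less than `tol` between cycles. With an empty sliding definition this
#' reduces exactly to [gpa()].
#'
#' @param dataset A [landmark_dataset()].
#' @param sliders A [sliding_definition()] (may be empty).
#' @param n_cycles Sliding cycles. Default 3; convergence is rapid.
#' @param tol Consensus-change tolerance between cycles.
#' @param per_specimen_tangents Estimate tangent frames on each specimen
#'   instead of on the consensus (off by default; consensus frames are more
#'   stable).
#' @return A `gpa_fit` (see [gpa()]) of the slid dataset; `$cycle_objective`
#'   holds the summed squared distance to the consensus after the initial
#'   GPA and after each sliding cycle (non-increasing).
#' @export
slide_gpa <- function(dataset, sliders, n_cycles = 3, tol = 1e-10,
                      per_specimen_tangents = FALSE) {
  fit <- gpa(dataset, tol = tol)
  if (nrow(sliders$curves) == 0 && nrow(sliders$patches) == 0) return(fit)
  prev_consensus <- fit$consensus
  cycle_objective <- sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
  for (cycle in seq_len(n_cycles)) {
    if (per_specimen_tangents) {
      slid <- fit$aligned
      for (i in seq_len(dim(slid)[3])) {
        fr <- estimate_tangents(fit$aligned[, , i], sliders)
        one <- slide_once(fit$aligned[, , i, drop = FALSE], fit$consensus, fr)
        slid[, , i] <- one[, , 1]
      }
    } else {
      frames <- estimate_tangents(fit$consensus, sliders)
      slid <- slide_once(fit$aligned, fit$consensus, frames)
    }
    slid_ds <- landmark_dataset(
      slid,
      fit$points, fit$specimens
    )
    fit <- gpa(slid_ds, tol = tol)
    cycle_objective <- c(
      cycle_objective, sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
    )
    delta <- sqrt(sum((fit$consensus - prev_consensus)^2))
    prev_consensus <- fit$consensus
    if (delta < tol) break
  }
  fit$cycle_objective <- cycle_objective
  fit
}
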