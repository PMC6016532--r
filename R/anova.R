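#' Procrustes ANOVA: sequential variance partitioning of shape
#'
#' Decomposes the total summed squared variation of the shape variables
#' (tangent coordinates, summed over all `3p` coordinates) over an ordered
#' sequence of design factors using sequential (Type I) sums of squares:
#' each term's SS is the reduction in residual SS when that term is added to
#' the model containing all earlier terms. `F = MS_term / MS_residual`.
#' Significance comes from residual randomization under the reduced model
#' (RRPP): for each term, residuals of the model without it are permuted
#' across specimens, the statistic is recomputed, and
#' `p = (b + 1) / (n_perm + 1)` with `b` the number of permuted statistics at
#' or above the observed one. The effect size `Z` is the standardized
#' position of `log F` in the permutation distribution (observed included).
#'
#' Degrees of freedom follow the standard linear model on specimen counts.
#'
#' @param y Shape variables: a `gpa_fit`, a `symmetry_decomposition` (its
#'   joint doubled sample is used), or an `n x q` numeric matrix.
#' @param formula One-sided model formula over factor-table columns, e.g.
#'   `~ individual + individual:device`. Terms are fitted in the order given.
#' @param data Factor table (one row per row of `y`); taken from the fit when
#'   `y` carries one.
#' @param n_perm Number of random permutations (0 skips the permutation
#'   test; then `p` and `Z` are `NA`).
#' @param seed Integer seed for the permutations (required when
#'   `n_perm > 0` unless `exact`).
#' @param exact Enumerate all `n!` row permutations instead of sampling
#'   (only for `n <= 8`); `p` is then the exact permutation p-value.
#' @return A tibble of class `procrustes_anova` with columns
#'   `term, df, SS, MS, Rsq, F, Z, p`, including `Residuals` and `Total`
#'   rows, and the permutation settings as attributes.
#' @examples
#' y <- matrix(rnorm(40), 20, 2)
#' grp <- tibble::tibble(g = rep(c("a", "b"), each = 10))
#' procrustes_anova(y, ~g, data = grp, n_perm = 99, seed = 1)
#' @export
procrustes_anova <- function(y, formula, data = NULL, n_perm = 999,
                             seed = NULL, exact = FALSE) {
  if (inherits(y, "symmetry_decomposition")) y <- y$joint
  if (inherits(y, "gpa_fit")) {
    if (is.null(data)) data <- y$specimens
    y <- y$tangent
  }
  Y <- as.matrix(y)
  n <- nrow(Y)
  stopifnot(!is.null(data), nrow(data) == n)
  data <- as.data.frame(data)
  terms_list <- attr(stats::terms(formula), "term.labels")
  if (!length(terms_list)) stop("formula must contain at least one term")

  # orthonormal bases of the cumulative design spans (intercept first)
  qlist <- vector("list", length(terms_list) + 1L)
  X0 <- matrix(1, n, 1)
  qlist[[1]] <- qr.Q(qr(X0))
  dfs <- integer(length(terms_list))
  for (k in seq_along(terms_list)) {
    Xk <- stats::model.matrix(
      stats::reformulate(terms_list[seq_len(k)]), data = data
    )
    qrk <- qr(Xk)
    rank_k <- qrk$rank
    prev_rank <- ncol(qlist[[k]])
    dfs[k] <- rank_k - prev_rank
    if (dfs[k] == 0L) {
      stop(
        "term '", terms_list[k], "' is confounded with earlier terms (",
        paste(terms_list[seq_len(k - 1)], collapse = ", "), ")"
      )
    }
    qlist[[k + 1]] <- qr.Q(qrk)[, seq_len(rank_k), drop = FALSE]
  }
  df_res <- n - ncol(qlist[[length(qlist)]])
  if (df_res <= 0L) {
    stop("zero residual degrees of freedom: model saturates the ", n, " specimens")
  }

  # fitted sums of squares beyond the grand mean, per cumulative model
  ssq <- function(Q, M) sum(crossprod(Q, M)^2)
  tot_ss <- sum(Y^2) - ssq(qlist[[1]], Y)
  fit_ss <- vapply(qlist, ssq, numeric(1), M = Y) - ssq(qlist[[1]], Y)
  ss <- diff(fit_ss)
  ss_res <- tot_ss - sum(ss)
  ms <- ss / dfs
  ms_res <- ss_res / df_res
  fstat <- ms / ms_res

  pvals <- rep(NA_real_, length(ss))
  zvals <- rep(NA_real_, length(ss))
  do_perm <- exact || n_perm > 0
  if (do_perm) {
    if (exact) {
      if (n > 8) stop("exact enumeration limited to n <= 8")
      perms <- all_permutations(n)
    } else {
      if (is.null(seed)) stop("seed is required for random permutations")
      set.seed(as.integer(seed))
      perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    }
    base_q <- ssq(qlist[[1]], Y)
    for (k in seq_along(ss)) {
      Qred <- qlist[[k]]
      Qfull_k <- qlist[[k + 1]]
      Qfull <- qlist[[length(qlist)]]
      fitted_red <- Qred %*% crossprod(Qred, Y)
      resid_red <- Y - fitted_red
      fperm <- vapply(perms, function(pm) {
        Ys <- fitted_red + resid_red[pm, , drop = FALSE]
        ss_k <- ssq(Qfull_k, Ys) - ssq(Qred, Ys)
        rss <- sum(Ys^2) - ssq(Qfull, Ys)
        (ss_k / dfs[k]) / (rss / df_res)
      }, numeric(1))
      if (exact) {
        pvals[k] <- mean(fperm >= fstat[k] - 1e-12)
      } else {
        b <- sum(fperm >= fstat[k] - 1e-12)
        pvals[k] <- (b + 1) / (n_perm + 1)
      }
      lf <- log(pmax(c(fstat[k], fperm), .Machine$double.xmin))
      zvals[k] <- (lf[1] - mean(lf)) / stats::sd(lf)
    }
  }

  out <- tibble::tibble(
    term = c(terms_list, "Residuals", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss, ss_res, tot_ss),
    MS = c(ms, ms_res, NA_real_),
    Rsq = c(ss / tot_ss, ss_res / tot_ss, NA_real_),
    F = c(fstat, NA_real_, NA_real_),
    Z = c(zvals, NA_real_, NA_real_),
    p = c(pvals, NA_real_, NA_real_)
  )
  class(out) <- c("procrustes_anova", class(out))
  attr(out, "n_perm") <- if (exact) NA_integer_ else n_perm
  attr(out, "exact") <- exact
  attr(out, "seed") <- seed
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (s in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(s, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Procrustes ANOVA on sources of shape variation including asymmetry
#'
#' Runs the object-symmetry variance partition on the doubled (original +
#' mirrored) aligned sample of a [decompose_symmetry()] result, with the
#' classical factor sequence: `Individual` (symmetric individual variation),
#' `Side` (directional asymmetry: the mean original-vs-mirrored contrast),
#' `Ind:Side` (fluctuating asymmetry), `Device` (systematic device
#' differences), and `Residuals` (replicate digitization error).
#'
#' @param decomposition A `symmetry_decomposition`.
#' @param n_perm,seed,exact Passed to [procrustes_anova()].
#' @return A `procrustes_anova` tibble with terms renamed
#'   `Individual, Side, Ind:Side, Device, Residuals, Total`.
#' @export
symmetry_anova <- function(decomposition, n_perm = 999, seed = NULL, exact = FALSE) {
  spec <- decomposition$specimens
  cell <- table(paste(spec$individual, spec$device))
  if (all(cell < 2)) {
    stop("residual undefined: every (individual, device) cell has a single replicate")
  }
  joint <- decomposition$joint
  has_device <- length(unique(spec$device)) > 1
  form <- if (has_device) {
    ~ individual + side + individual:side + device
  } else {
    ~ individual + side + individual:side
  }
  tab <- procrustes_anova(joint, form, n_perm = n_perm, seed = seed, exact = exact)
  rename <- c(
    individual = "Individual", side = "Side", `individual:side` = "Ind:Side",
    device = "Device", Residuals = "Residuals", Total = "Total"
  )
  tab$term <- unname(rename[tab$term])
  tab
}

#' Percent variance per factor from an ANOVA table
#'
#' Each factor's (and the residual's) sum of squares divided by the total
#' sum of squares over all rows, times 100.
#'
#' @param x A `procrustes_anova` tibble, any data frame with `term` and `SS`
#'   columns, or a (possibly named) numeric vector of sums of squares.
#' @return A tibble with columns `term`, `SS`, `pct_var`; percentages sum to
#'   100.
#' @examples
#' percent_variance(c(Individual = 6.21e-2, Side = 2.37e-2, Residual = 1.70e-2))
#' @export
percent_variance <- function(x) {
  if (is.numeric(x)) {
    tab <- tibble::tibble(
      term = if (is.null(names(x))) paste0("term", seq_along(x)) else names(x),
      SS = as.numeric(x)
    )
  } else {
    tab <- tibble::as_tibble(x)[, c("term", "SS")]
    tab <- tab[tab$term != "Total", ]
  }
  total <- sum(tab$SS)
  if (total <= 0) stop("zero total sum of squares")
  tab$pct_var <- 100 * tab$SS / total
  tab
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (sequential SS, residual-randomization permutation)\n")
  if (!is.null(attr(x, "n_perm")) && !is.na(attr(x, "n_perm"))) {
    cat("  permutations:", attr(x, "n_perm"), " seed:", attr(x, "seed") %||% NA, "\n")
  }
  NextMethod()
}

#' @export
tidy.procrustes_anova <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @export
glance.procrustes_anova <- function(x, ...) {
  fac <- x[!x$term %in% c("Residuals", "Total"), ]
  tibble::tibble(
    n_terms = nrow(fac),
    total_SS = x$SS[x$term == "Total"],
    residual_Rsq = x$Rsq[x$term == "Residuals"],
    largest_term = fac$term[which.max(fac$SS)],
    n_perm = attr(x, "n_perm") %||% NA_integer_
  )
}
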