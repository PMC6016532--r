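#' Run the full measurement-error analysis pipeline
#'
#' Orchestrates the whole analysis over a real or synthetic dataset:
#' superimposition (with semilandmark sliding), object-symmetry
#' decomposition, the asymmetry-inclusive Procrustes ANOVA, the
#' symmetric-component Procrustes ANOVA, exploratory PCA, per-device
#' repeatability over three landmark subsets (each re-aligned from scratch),
#' the per-device Procrustes-variance permutation comparison, and — when a
#' grouping variable such as sex is available — the dimorphism ANOVA plus
#' per-device between-group PCA with leave-one-out cross-validated
#' classification (on replicate-averaged shapes).
#'
#' @param dataset A [landmark_dataset()], or `NULL` to simulate one from
#'   `params`.
#' @param sliders,bilateral Topology tables; taken from the synthetic
#'   template when simulating.
#' @param params [synthetic_params()] used when `dataset` is `NULL`.
#' @param sliding Slide semilandmarks before analysis.
#' @param n_cycles Sliding cycles.
#' @param axis Mirror axis for the symmetry decomposition.
#' @param n_perm Permutations for all permutation tests.
#' @param seed Integer seed (mandatory: drives simulation and permutations).
#' @param group_var Specimen factor used for classification (`"sex"`), or
#'   `NULL` to skip the classification stage.
#' @param output_dir If non-`NULL`, writes all result tables (CSV), score
#'   files and a run log there.
#' @return An object of class `gm_analysis`: list with `fit`,
#'   `decomposition`, `symmetry_anova`, `symmetric_anova`, `pca`,
#'   `repeatability`, `disparity`, `disparity_test`, `dimorphism_anova`,
#'   `classification` (per device), `truth` (when simulated), `config`.
#' @export
run_full_analysis <- function(dataset = NULL, sliders = NULL, bilateral = NULL,
                              params = synthetic_params(), sliding = TRUE,
                              n_cycles = 3, axis = "x", n_perm = 999,
                              seed = 1, group_var = "sex", output_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  truth <- NULL
  if (is.null(dataset)) {
    params$seed <- seed
    sim <- simulate_landmarks(params)
    dataset <- sim$dataset
    sliders <- sliders %||% sim$template$sliders
    bilateral <- bilateral %||% sim$template$bilateral
    truth <- sim$truth
  }
  if (is.null(bilateral)) stop("a bilateral map is required for the symmetry stages")
  issues <- validate_landmarks(dataset, sliders, bilateral)
  if (nrow(issues)) {
    stop(
      "stage validation: ", issues$component[1], ": ", issues$message[1],
      if (nrow(issues) > 1) paste0(" (and ", nrow(issues) - 1, " more)") else ""
    )
  }

  fit <- if (sliding && !is.null(sliders)) {
    slide_gpa(dataset, sliders, n_cycles = n_cycles)
  } else {
    gpa(dataset)
  }
  aligned_ds <- landmark_dataset(fit$aligned, dataset$points, dataset$specimens)
  dec <- decompose_symmetry(aligned_ds, bilateral, axis = axis)
  tab1 <- symmetry_anova(dec, n_perm = n_perm, seed = seed + 1)

  y_sym <- tangent_coords_at(dec$symmetric, dec$consensus)
  spec <- dataset$specimens
  tab2 <- procrustes_anova(
    y_sym, ~ individual + individual:device,
    data = spec, n_perm = n_perm, seed = seed + 2
  )
  pca <- shape_pca(y_sym, data = spec)

  devices <- unique(spec$device)
  rep_tab <- purrr::map_dfr(devices, function(d) {
    purrr::map_dfr(c("all", "fixed_curves", "fixed_only"), function(ls) {
      repeatability(
        dataset, device = d, landmark_subset = ls,
        bilateral = bilateral, sliders = if (sliding) sliders else NULL,
        n_cycles = n_cycles
      )
    })
  })

  disp <- procrustes_variance_by_group(fit)
  disp_test <- if (length(devices) == 2) {
    compare_group_variance(disp, n_perm = n_perm, seed = seed + 3)
  } else {
    NULL
  }

  tab4 <- NULL
  classif <- NULL
  bg_scores <- NULL
  if (!is.null(group_var) && group_var %in% names(spec) &&
    sum(!is.na(spec[[group_var]])) > 0) {
    keep <- !is.na(spec[[group_var]])
    if (length(unique(spec[[group_var]][keep])) >= 2) {
      tab4 <- procrustes_anova(
        y_sym[keep, , drop = FALSE],
        stats::reformulate(c("device", group_var)),
        data = spec[keep, ], n_perm = n_perm, seed = seed + 4
      )
      avg <- average_replicates(y_sym[keep, , drop = FALSE], spec[keep, ])
      classif <- list()
      bg_list <- list()
      for (d in devices) {
        rows <- avg$data$device == d
        grp <- avg$data[[group_var]][rows]
        if (all(table(grp) >= 2)) {
          classif[[d]] <- loocv_classify(avg$y[rows, , drop = FALSE], grp)
          b <- bgpca(avg$y[rows, , drop = FALSE], grp)
          bg_list[[d]] <- dplyr::bind_cols(
            tibble::tibble(device = d, individual = avg$data$individual[rows]),
            b$scores
          )
        }
      }
      bg_scores <- dplyr::bind_rows(bg_list)
    }
  }

  config <- list(
    sliding = sliding, n_cycles = n_cycles, axis = axis, n_perm = n_perm,
    seed = seed, group_var = group_var, simulated = !is.null(truth),
    params = if (!is.null(truth)) truth$params else NULL
  )
  out <- structure(
    list(
      fit = fit, decomposition = dec,
      symmetry_anova = tab1, symmetric_anova = tab2, pca = pca,
      repeatability = rep_tab, disparity = disp, disparity_test = disp_test,
      dimorphism_anova = tab4, classification = classif,
      bgpca_scores = bg_scores, truth = truth, config = config
    ),
    class = "gm_analysis"
  )
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

write_analysis <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  readr::write_csv(tibble::as_tibble(x$symmetry_anova), pth("table1_symmetry_anova.csv"))
  readr::write_csv(tibble::as_tibble(x$symmetric_anova), pth("table2_symmetric_anova.csv"))
  readr::write_csv(tibble::as_tibble(x$repeatability), pth("table3_repeatability.csv"))
  tab4 <- x$dimorphism_anova %||%
    tibble::tibble(term = character(), df = integer(), SS = double())
  readr::write_csv(tibble::as_tibble(tab4), pth("table4_dimorphism_anova.csv"))
  tab5 <- if (length(x$classification)) {
    purrr::imap_dfr(x$classification, function(cl, d) {
      dplyr::bind_cols(tibble::tibble(device = d), tidy(cl),
        glance(cl)[rep(1, nrow(tidy(cl))), c("accuracy_pct", "kappa")])
    })
  } else {
    tibble::tibble(device = character())
  }
  readr::write_csv(tab5, pth("table5_classification.csv"))
  readr::write_csv(x$pca$scores, pth("pca_scores.csv"))
  bg <- x$bgpca_scores %||% tibble::tibble(device = character())
  readr::write_csv(bg, pth("bgpca_scores.csv"))
  cfg <- x$config
  writeLines(c(
    paste0("gmerror run log ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed: ", cfg$seed),
    paste0("n_perm: ", cfg$n_perm),
    paste0("sliding: ", cfg$sliding, " (", cfg$n_cycles, " cycles)"),
    paste0("mirror axis: ", cfg$axis),
    paste0("simulated: ", cfg$simulated),
    paste0("R version: ", R.version.string)
  ), pth("run_log.txt"))
  invisible(dir)
}

#' @export
print.gm_analysis <- function(x, ...) {
  cat("<gm_analysis>\n")
  cat("  specimens:", dim(x$fit$aligned)[3], " points:", dim(x$fit$aligned)[1], "\n")
  pv <- percent_variance(x$symmetry_anova)
  cat("  symmetry ANOVA %Var: ",
    paste(sprintf("%s %.1f", pv$term, pv$pct_var), collapse = ", "), "\n",
    sep = ""
  )
  rp <- x$repeatability[x$repeatability$landmark_subset == "all", ]
  cat("  repeatability (all landmarks): ",
    paste(sprintf("%s %.3f", rp$device, rp$r_value), collapse = ", "), "\n",
    sep = ""
  )
  if (!is.null(x$disparity_test)) {
    cat(sprintf(
      "  Procrustes variance: %s %.3g vs %s %.3g (p = %.3g)\n",
      x$disparity_test$device_a, x$disparity_test$mean_a,
      x$disparity_test$device_b, x$disparity_test$mean_b, x$disparity_test$p
    ))
  }
  for (d in names(x$classification)) {
    g <- glance(x$classification[[d]])
    cat(sprintf(
      "  %s classification: accuracy %.1f%%, kappa %.3f\n",
      d, g$accuracy_pct, g$kappa
    ))
  }
  invisible(x)
}
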