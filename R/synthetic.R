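#' Parameters for the synthetic replicate-digitization study
#'
#' Defines a repeated-measure landmark study: `n_individuals` crania, each
#' digitized `replicates` times on each of two devices, on a template of
#' `2 * n_pairs + n_midline` points (defaults give the 289-point,
#' 19 x 2 x 3 = 114-configuration design). Variance components are
#' per-coordinate standard deviations in template length units (mm by
#' convention, on a template about 20 mm across):
#' \describe{
#'   \item{`sigma_individual`}{symmetric between-individual shape variation.}
#'   \item{`da_magnitude`}{directional asymmetry: one asymmetric displacement
#'     field shared by all individuals.}
#'   \item{`sigma_fa`}{fluctuating asymmetry: per-individual asymmetric
#'     fields.}
#'   \item{`device_offset_scale`}{systematic device error: a fixed smooth
#'     (low-order polynomial, symmetrized) displacement field applied to
#'     every configuration of the second device, so device error is a
#'     coherent shape shift rather than extra noise.}
#'   \item{`sigma_digitization`}{per-device digitization noise, independent
#'     per replicate (first device noisier by default, like a low-resolution
#'     surface scanner vs a uCT scanner).}
#' }
#' Each drawn field is rescaled to make its realized mean per-coordinate
#' variance exactly the stated sigma squared, so analytical expectations
#' (e.g. [expected_repeatability()]) are exact rather than approximate.
#' Every configuration is finally hit with a random nuisance rotation,
#' translation (up to one template diameter) and scale (0.5-2x), which the
#' Procrustes superimposition must remove.
#'
#' @param n_individuals,replicates Design counts.
#' @param devices Character vector of two device labels.
#' @param n_pairs,n_midline Template point counts (pairs are mirrored
#'   right/left; midline points sit on the symmetry plane).
#' @param sigma_individual,da_magnitude,sigma_fa,device_offset_scale Effect
#'   sizes as above.
#' @param sigma_digitization Length-2 vector of per-device noise sd, named
#'   or in `devices` order.
#' @param digitization_mode `"isotropic"` (default) or `"tangential"` (noise
#'   only at sliding points, directed along their template tangent
#'   directions — used to verify that sliding removes tangential error).
#' @param sex_effect Symmetric dimorphism displacement added to males.
#' @param n_sexed,n_female Individuals with sex information and how many of
#'   those are female.
#' @param nuisance Logical: apply random rotation/translation/scale.
#' @param template_seed Seed for the deterministic template geometry.
#' @param seed Seed for the effect and noise draws.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_individuals = 19, replicates = 3,
                             devices = c("scan3d", "uct"),
                             n_pairs = 116, n_midline = 57,
                             sigma_individual = 0.110,
                             da_magnitude = 0.068,
                             sigma_fa = 0.032,
                             device_offset_scale = 0.128,
                             sigma_digitization = c(scan3d = 0.070, uct = 0.042),
                             digitization_mode = c("isotropic", "tangential"),
                             sex_effect = 0.090,
                             n_sexed = 11, n_female = 7,
                             nuisance = TRUE,
                             template_seed = 1, seed = 1) {
  digitization_mode <- match.arg(digitization_mode)
  stopifnot(
    n_individuals >= 1, replicates >= 1, length(devices) >= 1,
    n_pairs >= 1, n_midline >= 1,
    sigma_individual >= 0, da_magnitude >= 0, sigma_fa >= 0,
    device_offset_scale >= 0, all(sigma_digitization >= 0)
  )
  if (is.null(names(sigma_digitization))) {
    sigma_digitization <- stats::setNames(
      rep_len(sigma_digitization, length(devices)), devices
    )
  }
  structure(
    list(
      n_individuals = n_individuals, replicates = replicates, devices = devices,
      n_pairs = n_pairs, n_midline = n_midline,
      sigma_individual = sigma_individual, da_magnitude = da_magnitude,
      sigma_fa = sigma_fa, device_offset_scale = device_offset_scale,
      sigma_digitization = sigma_digitization,
      digitization_mode = digitization_mode,
      sex_effect = sex_effect, n_sexed = n_sexed, n_female = n_female,
      nuisance = nuisance, template_seed = template_seed, seed = seed
    ),
    class = "synthetic_params"
  )
}

#' Bilaterally symmetric template configuration with slider topology
#'
#' Samples points on a smooth bilaterally symmetric surface (a hemiellipsoid,
#' standing in for a cranial vault) with exact mirror pairs about the
#' `x = 0` plane. Points are assigned roles deterministically: fixed
#' landmarks anchor the midline chain and the paired curve chains, curve
#' semilandmarks fill the chains (sliding neighbors = chain-adjacent
#' points), and patch points are scattered on each side with their tangent
#' planes defined by the 6 nearest sliding/patch points. Default counts give
#' 58 fixed + 145 curve + 86 patch = 289 points.
#'
#' @param n_pairs Number of mirrored right/left point pairs.
#' @param n_midline Number of midline (x = 0) points.
#' @param seed Integer seed for the deterministic point placement.
#' @return List with `coords` (`p x 3`), `points` (role table),
#'   `sliders` ([sliding_definition()]), `bilateral` ([bilateral_map()]).
#' @export
make_template <- function(n_pairs = 116, n_midline = 57, seed = 1) {
  stopifnot(n_pairs >= 1, n_midline >= 2)
  set.seed(as.integer(seed))
  ax <- c(10, 14, 8) # semi-axes: lateral (x), antero-posterior (y), dorso-ventral (z)
  surf <- function(u, v) {
    cbind(ax[1] * sin(u) * sin(v), ax[2] * cos(u), ax[3] * sin(u) * cos(v))
  }

  # role budget, scaled from the default 12/23/50/43 split
  m_f <- max(2L, round(n_midline * 12 / 57))
  f_p <- max(1L, round(n_pairs * 23 / 116))
  pa_p <- max(0L, round(n_pairs * 43 / 116))
  c_p <- n_pairs - f_p - pa_p
  if (c_p < 0) {
    pa_p <- pa_p + c_p
    c_p <- 0L
  }

  # --- midline chain (v = 0 meridian, x exactly 0) ---
  u_mid <- seq(0.12 * pi, 0.88 * pi, length.out = n_midline)
  mid_xyz <- surf(u_mid, 0)
  mid_xyz[, 1] <- 0
  fixed_mid <- unique(round(seq(1, n_midline, length.out = m_f)))
  role_mid <- ifelse(seq_len(n_midline) %in% fixed_mid, "fixed", "semilandmark")
  slid_mid <- setdiff(seq_len(n_midline), fixed_mid)
  cur_mid <- tibble::tibble(
    before = slid_mid - 1L, slider = slid_mid, after = slid_mid + 1L
  )

  # --- right side: fixed anchors ---
  u_rf <- stats::runif(f_p, 0.2 * pi, 0.8 * pi)
  v_rf <- stats::runif(f_p, 0.25, 1.30)
  rf_xyz <- surf(u_rf, v_rf)

  # --- right side: curve chains between fixed anchors ---
  cur_right <- NULL
  rc_xyz <- NULL
  if (c_p > 0) {
    n_chains <- max(1L, round(c_p / 10))
    sizes <- rep(c_p %/% n_chains, n_chains)
    extra <- c_p - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    chain_rows <- list()
    pts <- list()
    offset <- 0L
    base_rc <- n_midline + f_p
    for (j in seq_len(n_chains)) {
      e1 <- ((2L * j - 2L) %% f_p) + 1L
      e2 <- ((2L * j - 1L) %% f_p) + 1L
      if (e2 == e1) e2 <- (e1 %% f_p) + 1L
      L <- sizes[j]
      tfrac <- seq_len(L) / (L + 1)
      uu <- u_rf[e1] + tfrac * (u_rf[e2] - u_rf[e1])
      vv <- v_rf[e1] + tfrac * (v_rf[e2] - v_rf[e1])
      pts[[j]] <- surf(uu, vv)
      ids <- base_rc + offset + seq_len(L)
      before <- c(n_midline + e1, ids[-L])
      after <- c(ids[-1], n_midline + e2)
      chain_rows[[j]] <- tibble::tibble(before = before, slider = ids, after = after)
      offset <- offset + L
    }
    rc_xyz <- do.call(rbind, pts)
    cur_right <- dplyr::bind_rows(chain_rows)
  }

  # --- right side: patch points ---
  rp_xyz <- NULL
  if (pa_p > 0) {
    u_rp <- stats::runif(pa_p, 0.25 * pi, 0.75 * pi)
    v_rp <- stats::runif(pa_p, 0.30, 1.25)
    rp_xyz <- surf(u_rp, v_rp)
  }

  right_xyz <- rbind(rf_xyz, rc_xyz, rp_xyz)
  role_right <- c(rep("fixed", f_p), rep("semilandmark", c_p), rep("patch", pa_p))
  n_right <- nrow(right_xyz)

  # --- left side: exact mirror of the right block ---
  left_xyz <- right_xyz
  left_xyz[, 1] <- -left_xyz[, 1]

  coords <- rbind(mid_xyz, right_xyz, left_xyz)
  p <- nrow(coords)
  role <- c(role_mid, role_right, role_right)
  points <- tibble::tibble(
    point = seq_len(p),
    name = sprintf(
      "%s%03d", c(rep("M", n_midline), rep("R", n_right), rep("L", n_right)),
      c(seq_len(n_midline), seq_len(n_right), seq_len(n_right))
    ),
    role = role
  )

  off <- n_right # left index = right index + off
  shift <- function(i) ifelse(i > n_midline, i + off, i)
  cur_left <- NULL
  if (!is.null(cur_right) && nrow(cur_right)) {
    cur_left <- tibble::tibble(
      before = shift(cur_right$before),
      slider = cur_right$slider + off,
      after = shift(cur_right$after)
    )
  }
  curves <- dplyr::bind_rows(cur_mid, cur_right, cur_left)

  patches <- NULL
  if (pa_p > 0) {
    patch_idx <- c(
      n_midline + f_p + c_p + seq_len(pa_p),
      n_midline + n_right + f_p + c_p + seq_len(pa_p)
    )
    candidates <- which(role != "fixed")
    nb_rows <- lapply(patch_idx, function(pt) {
      cand <- setdiff(candidates, pt)
      d2 <- rowSums((coords[cand, , drop = FALSE] -
        matrix(coords[pt, ], length(cand), 3, byrow = TRUE))^2)
      tibble::tibble(point = pt, neighbor = cand[order(d2)[1:6]])
    })
    patches <- dplyr::bind_rows(nb_rows)
  }

  pairs <- tibble::tibble(
    right = n_midline + seq_len(n_right),
    left = n_midline + off + seq_len(n_right)
  )
  list(
    coords = coords, points = points,
    sliders = sliding_definition(curves, patches),
    bilateral = bilateral_map(pairs, midline = seq_len(n_midline))
  )
}

# mirror a displacement field (p x 3) under the template's bilateral map
mirror_field <- function(field, bilateral) {
  mirror_relabel(field, bilateral, axis = "x")
}

# rescale a field so its mean per-coordinate square is exactly sigma^2
calibrate_field <- function(field, sigma, active = NULL) {
  if (sigma == 0) return(field * 0)
  if (is.null(active)) active <- seq_len(nrow(field))
  nrm <- sqrt(sum(field[active, ]^2))
  if (nrm == 0) return(field)
  field * (sigma * sqrt(3 * length(active)) / nrm)
}

# project a displacement field onto the orthocomplement of the similarity
# nuisance directions at `coords` (3 translations, 3 infinitesimal rotations,
# 1 scaling), so superimposition cannot absorb any of it
orthogonalize_similarity <- function(field, coords) {
  p <- nrow(coords)
  cen <- sweep(coords, 2, colMeans(coords))
  nuis <- cbind(
    as.vector(matrix(rep(c(1, 0, 0), each = p), p, 3)),
    as.vector(matrix(rep(c(0, 1, 0), each = p), p, 3)),
    as.vector(matrix(rep(c(0, 0, 1), each = p), p, 3)),
    as.vector(cbind(-cen[, 2], cen[, 1], 0)),
    as.vector(cbind(-cen[, 3], 0, cen[, 1])),
    as.vector(cbind(0, -cen[, 3], cen[, 2])),
    as.vector(cen)
  )
  Q <- qr.Q(qr(nuis))
  f <- as.vector(field)
  matrix(f - Q %*% crossprod(Q, f), p, 3)
}

draw_symmetric_field <- function(p, bilateral, sigma) {
  g <- matrix(stats::rnorm(p * 3), p, 3)
  s <- (g + mirror_field(g, bilateral)) / 2
  calibrate_field(s, sigma)
}

draw_asymmetric_field <- function(p, bilateral, sigma) {
  g <- matrix(stats::rnorm(p * 3), p, 3)
  a <- (g - mirror_field(g, bilateral)) / 2
  calibrate_field(a, sigma)
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  R <- R %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate a replicate landmark dataset with known variance components
#'
#' For each individual: a symmetric individual effect (shared by all of that
#' individual's configurations), plus the study-wide directional-asymmetry
#' field, plus the individual's fluctuating-asymmetry field. Configurations
#' of the second device are additionally displaced by the fixed systematic
#' device field. Each replicate digitization then adds independent noise
#' with its device's sd, and each configuration receives a random nuisance
#' rotation/translation/scale.
#'
#' @param params A [synthetic_params()] list.
#' @return List with `dataset` (a [landmark_dataset()]), `template` (from
#'   [make_template()]), and `truth` — the exact effect fields drawn, the
#'   expected per-device repeatability and the expected percent-variance
#'   shares of the symmetry ANOVA.
#' @export
simulate_landmarks <- function(params = synthetic_params()) {
  tpl <- make_template(params$n_pairs, params$n_midline, seed = params$template_seed)
  p <- nrow(tpl$coords)
  bil <- tpl$bilateral
  set.seed(as.integer(params$seed))

  n_ind <- params$n_individuals
  devs <- params$devices
  reps <- params$replicates

  ind_fields <- lapply(seq_len(n_ind), function(i) {
    draw_symmetric_field(p, bil, params$sigma_individual)
  })
  da_field <- draw_asymmetric_field(p, bil, params$da_magnitude)
  fa_fields <- lapply(seq_len(n_ind), function(i) {
    draw_asymmetric_field(p, bil, params$sigma_fa)
  })

  # smooth systematic device field: pure quadratic polynomial in the template
  # coordinates (no constant/linear part, which superimposition would absorb
  # as translation/rotation/scale), symmetrized, exactly calibrated
  Xs <- scale(tpl$coords, scale = apply(tpl$coords, 2, stats::sd))
  basis <- cbind(Xs^2, Xs[, 1] * Xs[, 2], Xs[, 1] * Xs[, 3], Xs[, 2] * Xs[, 3])
  raw_dev <- basis %*% matrix(stats::rnorm(ncol(basis) * 3, sd = 0.1), ncol(basis), 3)
  raw_dev <- orthogonalize_similarity(raw_dev, tpl$coords)
  dev_field <- calibrate_field(
    orthogonalize_similarity(
      (raw_dev + mirror_field(raw_dev, bil)) / 2, tpl$coords
    ),
    params$device_offset_scale
  )

  sex_field <- draw_symmetric_field(p, bil, params$sex_effect)
  sexes <- rep(NA_character_, n_ind)
  if (params$n_sexed > 0) {
    ns <- min(params$n_sexed, n_ind)
    nf <- min(params$n_female, ns)
    sexes[seq_len(ns)] <- c(rep("f", nf), rep("m", ns - nf))
  }

  sl_pts <- sliding_points(tpl$sliders)
  frames <- if (params$digitization_mode == "tangential") {
    estimate_tangents(tpl$coords, tpl$sliders)
  } else {
    NULL
  }
  diam <- max(dist(tpl$coords[chull_safe(tpl$coords), , drop = FALSE]))

  n_total <- n_ind * length(devs) * reps
  coords <- array(NA_real_, c(p, 3, n_total))
  spec <- vector("list", n_total)
  k <- 0L
  for (i in seq_len(n_ind)) {
    base_i <- tpl$coords + ind_fields[[i]] + da_field + fa_fields[[i]]
    if (!is.na(sexes[i]) && sexes[i] == "m") base_i <- base_i + sex_field
    for (d in seq_along(devs)) {
      base_d <- if (d == 2) base_i + dev_field else base_i
      sd_d <- params$sigma_digitization[[devs[d]]]
      for (r in seq_len(reps)) {
        k <- k + 1L
        if (params$digitization_mode == "tangential") {
          noise <- matrix(0, p, 3)
          for (nm in names(frames)) {
            pt <- as.integer(nm)
            Tb <- frames[[nm]]
            noise[pt, ] <- as.vector(Tb %*% stats::rnorm(ncol(Tb)))
          }
          noise <- calibrate_field(noise, sd_d, active = sl_pts)
        } else {
          noise <- calibrate_field(matrix(stats::rnorm(p * 3), p, 3), sd_d)
        }
        cfg <- base_d + noise
        if (isTRUE(params$nuisance)) {
          cfg <- cfg %*% random_rotation()
          cfg <- cfg * stats::runif(1, 0.5, 2)
          cfg <- sweep(cfg, 2, stats::runif(3, -diam, diam), `+`)
        }
        coords[, , k] <- cfg
        spec[[k]] <- tibble::tibble(
          specimen = sprintf("ind%02d_%s_r%d", i, devs[d], r),
          individual = sprintf("ind%02d", i),
          device = devs[d], replicate = r, sex = sexes[i]
        )
      }
    }
  }
  specimens <- dplyr::bind_rows(spec)
  dataset <- landmark_dataset(coords, tpl$points, specimens)

  s2i <- params$sigma_individual^2
  shares <- c(
    Individual = s2i,
    Side = params$da_magnitude^2,
    `Ind:Side` = params$sigma_fa^2,
    Device = if (length(devs) > 1) params$device_offset_scale^2 / 4 else 0,
    Residuals = mean(params$sigma_digitization[devs]^2)
  )
  truth <- list(
    params = params,
    individual_fields = ind_fields, da_field = da_field, fa_fields = fa_fields,
    device_field = dev_field, sex_field = sex_field, sexes = sexes,
    expected_repeatability = vapply(
      devs,
      function(d) s2i / (s2i + params$sigma_digitization[[d]]^2), numeric(1)
    ),
    expected_var_shares = 100 * shares / sum(shares)
  )
  list(dataset = dataset, template = tpl, truth = truth)
}

chull_safe <- function(x) seq_len(nrow(x)) # diameter over all points; p is small

#' Expected repeatability implied by generator parameters
#'
#' The per-coordinate intraclass correlation
#' `sigma_ind^2 / (sigma_ind^2 + sigma_dig^2)` for a given device — exact
#' for the generator's calibrated fields up to the few degrees of freedom
#' absorbed by superimposition, and referring to the analysis without
#' symmetric-component extraction (which would halve the noise term).
#'
#' @param params A [synthetic_params()].
#' @param device Device label (default: first device).
#' @return Scalar in `[0, 1]`.
#' @export
expected_repeatability <- function(params, device = params$devices[1]) {
  s2i <- params$sigma_individual^2
  s2d <- params$sigma_digitization[[device]]^2
  if (s2i == 0 && s2d == 0) {
    stop("both sigma_individual and sigma_digitization are zero")
  }
  s2i / (s2i + s2d)
}
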