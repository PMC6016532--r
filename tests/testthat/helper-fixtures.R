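# Shared fixture builders. Everything is generated in code at test time.

# random non-degenerate configuration
rand_config <- function(p = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * 3), p, 3)
}

# small dataset of jittered copies of one base configuration
small_dataset <- function(n = 5, p = 10, noise = 0.05, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(p * 3, sd = 2), p, 3)
  coords <- array(NA_real_, c(p, 3, n))
  for (i in seq_len(n)) coords[, , i] <- base + matrix(rnorm(p * 3, sd = noise), p, 3)
  landmark_dataset(coords)
}

# apply a random similarity transform (proper rotation, scale, translation)
similarity_transform <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(config %*% R * runif(1, 0.5, 2), 2, rnorm(3, sd = 3), `+`)
}

# all permutations of 1..n, written independently of the package internals
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (s in combinat_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(s, n, after = pos)
  }
  out
}

# 3D vector cross product
crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# center and unit-scale, written independently of the package internals
center_scale_ref <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# tiny synthetic study, fast enough to simulate repeatedly
tiny_params <- function(seed = 1, n_sexed = 0, n_individuals = 6, ...) {
  synthetic_params(
    n_individuals = n_individuals, replicates = 3, n_pairs = 12, n_midline = 7,
    n_sexed = n_sexed, seed = seed, ...
  )
}

# independent brute-force GPA oracle: alternating minimization with plain
# matrix algebra, run from a random rotation start
oracle_gpa <- function(coords, tol = 1e-12, max_iter = 2000, start_seed = 1) {
  set.seed(start_seed)
  n <- dim(coords)[3]
  X <- coords
  for (i in seq_len(n)) {
    cen <- sweep(X[, , i], 2, colMeans(X[, , i]))
    X[, , i] <- cen / sqrt(sum(cen^2))
    qrd <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    X[, , i] <- X[, , i] %*% R
  }
  cons <- X[, , 1]
  repeat_count <- 0
  repeat {
    for (i in seq_len(n)) {
      sv <- svd(crossprod(X[, , i], cons))
      R <- sv$u %*% t(sv$v)
      if (det(R) < 0) {
        u <- sv$u
        u[, 3] <- -u[, 3]
        R <- u %*% t(sv$v)
      }
      X[, , i] <- X[, , i] %*% R
    }
    newc <- apply(X, c(1, 2), mean)
    newc <- sweep(newc, 2, colMeans(newc))
    newc <- newc / sqrt(sum(newc^2))
    if (sqrt(sum((newc - cons)^2)) < tol || repeat_count > max_iter) {
      cons <- newc
      break
    }
    cons <- newc
    repeat_count <- repeat_count + 1
  }
  list(aligned = X, consensus = cons,
    objective = sum(sweep(X, c(1, 2), cons)^2))
}
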