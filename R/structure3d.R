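# Poisson metric-scaling inference of a 3D beads-on-a-string structure
# from a contact map, and Procrustes comparison of structures.
#
# The model: contact counts C_ij between beads i and j are independent
# Poisson with rate beta * d_ij(X)^alpha, where d_ij is the Euclidean
# distance between beads and alpha < 0 (default -3). The log likelihood
#   L(X, beta) = sum_{i<j} C_ij alpha log d_ij + C_ij log beta
#                - beta d_ij^alpha
# is maximized by alternating a closed-form beta update with
# quasi-Newton ascent on X, from several random initializations.

#' Closed-form scale update for the Poisson structure model
#'
#' The unique zero of dL/dbeta:
#' `beta = sum_{i<j} C_ij / sum_{i<j} d_ij^alpha`.
#'
#' @param X n x 3 coordinate matrix.
#' @param counts symmetric count matrix (or `contact_map`).
#' @param alpha distance-decay exponent.
#' @return scalar beta; 0 with attribute `degenerate = TRUE` when all
#'   counts are zero.
#' @export
beta_update <- function(X, counts, alpha = -3) {
  m <- if (inherits(counts, "contact_map")) counts$counts else counts
  d <- as.matrix(stats::dist(X))
  ut <- upper.tri(d)
  denom <- sum(d[ut]^alpha)
  if (denom == 0) stop("zero denominator in beta update (degenerate distances)")
  num <- sum(m[ut])
  b <- num / denom
  if (num == 0) attr(b, "degenerate") <- TRUE
  b
}

poisson_loglik <- function(x, C_ut, ut_idx, alpha, beta, n, floor. = 1e-6) {
  X <- matrix(x, n, 3)
  dx <- X[ut_idx[, 1], ] - X[ut_idx[, 2], ]
  d <- pmax(sqrt(rowSums(dx^2)), floor.)
  sum(C_ut * alpha * log(d) + C_ut * log(beta) - beta * d^alpha)
}

poisson_grad <- function(x, C_ut, ut_idx, alpha, beta, n, floor. = 1e-6) {
  X <- matrix(x, n, 3)
  dx <- X[ut_idx[, 1], ] - X[ut_idx[, 2], ]
  d <- pmax(sqrt(rowSums(dx^2)), floor.)
  # dL/dx_i = alpha * sum_j (C_ij / d^2 - beta d^(alpha-2)) (x_i - x_j)
  coef <- alpha * (C_ut / d^2 - beta * d^(alpha - 2))
  g <- matrix(0, n, 3)
  contrib <- coef * dx
  for (k in 1:3) {
    g[, k] <- g[, k] +
      tapply(contrib[, k], factor(ut_idx[, 1], levels = seq_len(n)),
             sum, default = 0) -
      tapply(contrib[, k], factor(ut_idx[, 2], levels = seq_len(n)),
             sum, default = 0)
  }
  as.numeric(g)
}

# classical-MDS initialization from the distance-decay transform of the
# counts: d_hat ~ C^(1/alpha) for observed pairs, missing entries set to
# the largest observed estimate
mds_init <- function(C, alpha) {
  n <- nrow(C)
  dh <- matrix(NA_real_, n, n)
  pos <- C > 0
  dh[pos] <- C[pos]^(1 / alpha)
  dh[pos] <- dh[pos] / stats::median(dh[pos])
  dh[!pos] <- max(dh[pos]) * 1.5
  diag(dh) <- 0
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dh), k = 3))
  if (ncol(fit) < 3) fit <- cbind(fit, matrix(0, n, 3 - ncol(fit)))
  fit
}

#' Infer a 3D structure from a contact map
#'
#' Maximizes the Poisson metric-scaling likelihood over bead coordinates
#' and the scale, keeping the best of `n_starts` initializations (a
#' distance-decay MDS embedding plus per-start Gaussian jitter). Bins
#' that are masked or have zero marginal counts are excluded from the
#' likelihood; their coordinates are filled afterwards by linear
#' interpolation between flanking valid beads and flagged invalid. The
#' returned structure has its valid beads centered at the origin.
#'
#' @param map a `contact_map` (square, symmetric, non-negative).
#' @param alpha distance-decay exponent (default -3).
#' @param n_starts number of random initializations (default 5).
#' @param max_iter L-BFGS iterations per coordinate-ascent sweep.
#' @param n_sweeps alternations of beta update and coordinate ascent.
#' @param seed integer RNG seed.
#' @param dist_floor lower bound on inter-bead distances in the
#'   likelihood, guarding the d -> 0 singularity.
#' @return a `structure3d` with attributes `model` (list: alpha, beta,
#'   loglik, converged) and `loglik_trace`.
#' @export
infer_structure <- function(map, alpha = -3, n_starts = 5, max_iter = 200,
                            n_sweeps = 4, seed = 1L, dist_floor = 1e-6) {
  m <- if (inherits(map, "contact_map")) map$counts else as.matrix(map)
  mask <- if (inherits(map, "contact_map")) map$mask else rep(TRUE, nrow(m))
  n_all <- nrow(m)
  valid <- mask & rowSums(m) > 0
  if (sum(valid) < 4) stop("fewer than 4 valid bins: structure unidentifiable")
  C <- m[valid, valid]
  n <- nrow(C)
  if (sum(C) == 0) stop("all-zero map: structure unidentifiable")
  ut_idx <- which(upper.tri(C), arr.ind = TRUE)
  C_ut <- C[ut_idx]
  base_init <- mds_init(C, alpha)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    jitter_sd <- if (s == 1) 0.01 else 0.1 * s
    X <- base_init + matrix(stats::rnorm(n * 3, sd = jitter_sd), n, 3)
    trace <- numeric(0)
    conv <- FALSE
    for (sw in seq_len(n_sweeps)) {
      beta <- beta_update(X, C, alpha)
      trace <- c(trace, poisson_loglik(as.numeric(X), C_ut, ut_idx,
                                       alpha, beta, n, dist_floor))
      opt <- stats::optim(as.numeric(X), fn = poisson_loglik,
                          gr = poisson_grad, C_ut = C_ut, ut_idx = ut_idx,
                          alpha = alpha, beta = beta, n = n,
                          floor. = dist_floor, method = "L-BFGS-B",
                          control = list(fnscale = -1, maxit = max_iter))
      X <- matrix(opt$par, n, 3)
      trace <- c(trace, opt$value)
      conv <- opt$convergence == 0
    }
    beta <- beta_update(X, C, alpha)
    ll <- poisson_loglik(as.numeric(X), C_ut, ut_idx, alpha, beta, n,
                         dist_floor)
    if (is.null(best) || ll > best$ll)
      best <- list(X = X, beta = beta, ll = ll, trace = trace, conv = conv)
  }
  X <- sweep(best$X, 2, colMeans(best$X))
  coords <- matrix(NA_real_, n_all, 3)
  coords[valid, ] <- X
  # linear interpolation for invalid beads between flanking valid beads
  vidx <- which(valid)
  for (k in 1:3)
    coords[, k] <- stats::approx(vidx, X[, k], xout = seq_len(n_all),
                                 rule = 2)$y
  out <- structure(list(coords = coords, valid = valid, mode = NULL,
                        hinge_index = NULL),
                   class = "structure3d")
  attr(out, "model") <- list(alpha = alpha, beta = best$beta,
                             loglik = best$ll, converged = best$conv)
  attr(out, "loglik_trace") <- best$trace
  out
}

#' Procrustes RMSD between two structures
#'
#' Root-mean-square deviation after optimal translation, rotation,
#' reflection, and uniform scaling of `Y` onto `X` (closed-form
#' orthogonal Procrustes via SVD), restricted to beads valid in both
#' structures.
#'
#' @param X,Y n x 3 coordinate matrices or `structure3d` objects.
#' @return RMSD in the units of `X`.
#' @export
procrustes_rmsd <- function(X, Y) {
  vx <- if (inherits(X, "structure3d")) X$valid else rep(TRUE, nrow(X))
  vy <- if (inherits(Y, "structure3d")) Y$valid else rep(TRUE, nrow(Y))
  cx <- if (inherits(X, "structure3d")) X$coords else as.matrix(X)
  cy <- if (inherits(Y, "structure3d")) Y$coords else as.matrix(Y)
  if (nrow(cx) != nrow(cy)) stop("structures must have equal bead counts")
  keep <- vx & vy
  if (sum(keep) < 3) stop("fewer than 3 shared valid beads")
  A <- scale(cx[keep, , drop = FALSE], scale = FALSE)
  B <- scale(cy[keep, , drop = FALSE], scale = FALSE)
  sv <- svd(crossprod(A, B))
  R <- sv$v %*% t(sv$u)                 # reflection permitted
  s <- sum(sv$d) / sum(B^2)
  resid <- A - s * B %*% R
  sqrt(sum(resid^2) / nrow(A))
}

#' Radius of gyration of a structure's valid beads
#' @param struct a `structure3d` or coordinate matrix.
#' @return scalar radius of gyration.
#' @export
radius_of_gyration <- function(struct) {
  cx <- if (inherits(struct, "structure3d"))
    struct$coords[struct$valid, , drop = FALSE] else as.matrix(struct)
  cc <- scale(cx, scale = FALSE)
  sqrt(mean(rowSums(cc^2)))
}
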