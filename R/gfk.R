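# Geodesic flow kernel core: PCA subspaces, principal angles, the closed-form
# kernel G, subspace-disagreement dimension selection and the rank-of-domain
# source-ranking metric.

#' PCA subspace of a feature matrix
#'
#' The basis holds the top-`d` principal directions of the column-centered
#' data; the complement completes an orthonormal basis of R^D.
#'
#' @param X numeric n x D matrix (standardized features in the pipeline).
#' @param d subspace dimension, `1 <= d <= min(n - 1, D)`.
#' @return An object of class `subspace` with fields `basis` (D x d),
#'   `complement` (D x (D - d)), `d`, `D`.
#' @export
pca_basis <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- ncol(X)
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d > min(n - 1, D) ||
      d != round(d)) {
    stop("`d` must be an integer in [1, min(n - 1, D)]", call. = FALSE)
  }
  d <- as.integer(d)
  Xc <- sweep(X, 2, colMeans(X), `-`)
  P <- svd(Xc, nu = 0, nv = d)$v
  Q <- qr.Q(qr(P), complete = TRUE)
  # qr may flip signs of the leading columns; keep the exact PCA directions
  # and take the complement from the completed factor.
  structure(list(basis = P,
                 complement = if (d < D) Q[, (d + 1L):D, drop = FALSE] else
                   matrix(numeric(), D, 0),
                 d = d, D = D),
            class = "subspace")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Principal angles between two subspaces
#'
#' From the SVD `PS' PT = U1 Gamma V'` and the induced factor
#' `RS' PT = -U2 Sigma V'` (same right factor V), with singular values
#' clipped to [0, 1] before `acos`.  Angles are nondecreasing in
#' [0, pi/2].  Columns of `U2` whose sine is numerically zero are set to
#' zero: they never enter the geodesic flow.
#'
#' @param PS,PT `subspace` objects with equal `D` and `d`, `d <= D - d`.
#' @return An object of class `principal_angles` with fields `U1`, `U2`, `V`,
#'   `theta`, `cosines`, `sines`, and the source subspace dimensions.
#' @export
principal_angles <- function(PS, PT) {
  stopifnot(inherits(PS, "subspace"), inherits(PT, "subspace"))
  if (PS$D != PT$D || PS$d != PT$d) {
    stop("subspace dimension mismatch", call. = FALSE)
  }
  if (PS$d > PS$D - PS$d) {
    stop("need d <= D - d for the complement factor", call. = FALSE)
  }
  s1 <- svd(crossprod(PS$basis, PT$basis))
  cosines <- clip01(s1$d)
  theta <- acos(cosines)
  sines <- sqrt(clip01(1 - cosines^2))
  M2 <- crossprod(PS$complement, PT$basis %*% s1$v)
  U2 <- matrix(0, PS$D - PS$d, PS$d)
  nz <- sines > 1e-12
  if (any(nz)) {
    U2[, nz] <- -sweep(M2[, nz, drop = FALSE], 2, sines[nz], `/`)
  }
  structure(list(U1 = s1$u, U2 = U2, V = s1$v, theta = theta,
                 cosines = cosines, sines = sines, d = PS$d, D = PS$D),
            class = "principal_angles")
}

# Closed-form entries of the 2x2-block integral matrix Lambda:
#   a_i = int_0^1 cos^2(t theta) dt = 1/2 + sin(2 theta)/(4 theta)
#   b_i = -int_0^1 cos(t theta) sin(t theta) dt = (cos(2 theta) - 1)/(4 theta)
#   c_i = int_0^1 sin^2(t theta) dt = 1/2 - sin(2 theta)/(4 theta)
# with the theta -> 0 limits (1, 0, 0).
lambda_entries <- function(theta) {
  a <- b <- cc <- numeric(length(theta))
  small <- theta < 1e-8
  a[small] <- 1
  b[small] <- 0
  cc[small] <- 0
  th <- theta[!small]
  a[!small] <- 0.5 + sin(2 * th) / (4 * th)
  b[!small] <- (cos(2 * th) - 1) / (4 * th)
  cc[!small] <- 0.5 - sin(2 * th) / (4 * th)
  list(a = a, b = b, c = cc)
}

#' Closed-form geodesic flow kernel
#'
#' Integrates the projector flow `G = int_0^1 phi(t) phi(t)' dt` with
#' `phi(t) = PS U1 Gamma(t) - RS U2 Sigma(t)` in closed form as
#' `G = Omega Lambda Omega'`, `Omega = [PS U1, RS U2]`.  `G` is symmetric
#' positive semidefinite; when all angles are zero it equals the projector
#' `PS PS'` onto the shared subspace.
#'
#' @param dec a `principal_angles` decomposition.
#' @param PS the source `subspace` the decomposition was computed from.
#' @return An object of class `geodesic_kernel` with fields `G` (D x D),
#'   `decomposition`, `d`.
#' @export
geodesic_kernel <- function(dec, PS) {
  stopifnot(inherits(dec, "principal_angles"), inherits(PS, "subspace"))
  lam <- lambda_entries(dec$theta)
  O1 <- PS$basis %*% dec$U1
  O2 <- PS$complement %*% dec$U2
  Omega <- cbind(O1, O2)
  d <- dec$d
  Lambda <- matrix(0, 2 * d, 2 * d)
  Lambda[cbind(1:d, 1:d)] <- lam$a
  Lambda[cbind(1:d, d + 1:d)] <- lam$b
  Lambda[cbind(d + 1:d, 1:d)] <- lam$b
  Lambda[cbind(d + 1:d, d + 1:d)] <- lam$c
  G <- Omega %*% Lambda %*% t(Omega)
  G <- (G + t(G)) / 2
  structure(list(G = G, decomposition = dec, d = d), class = "geodesic_kernel")
}

#' Kernel inner products under the geodesic kernel
#'
#' Entry (i, j) is `x_i' G y_j`.
#'
#' @param kernel a `geodesic_kernel` (or a bare D x D matrix).
#' @param X,Y matrices with D columns.
#' @return The n x m kernel matrix `X G Y'`.
#' @export
kernel_dot <- function(kernel, X, Y) {
  G <- if (inherits(kernel, "geodesic_kernel")) kernel$G else as.matrix(kernel)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (ncol(X) != nrow(G) || ncol(Y) != nrow(G)) {
    stop("feature dimension mismatch with kernel", call. = FALSE)
  }
  X %*% G %*% t(Y)
}

# Largest principal angle between the leading-d column blocks of two
# orthonormal bases.
largest_angle <- function(B1, B2, d) {
  s <- svd(crossprod(B1[, seq_len(d), drop = FALSE],
                     B2[, seq_len(d), drop = FALSE]), nu = 0, nv = 0)$d
  acos(clip01(min(s)))
}

#' Subspace disagreement measure and dimension selection
#'
#' For each candidate dimension d the PCA subspaces of the source, the
#' target and the combined data are compared through their largest principal
#' angles `alpha_d` (source vs combined) and `beta_d` (target vs combined):
#' `D(d) = 0.5 (sin alpha_d + sin beta_d)`, which lies in [0, 1].  The
#' selected dimension `d_star` is the smallest d at which D(d) saturates at
#' 1 (within `eps`), i.e. the largest usable subspace before source and
#' target disagree completely; if D never saturates, `d_max` is used.
#'
#' @param XS,XT standardized source / target feature matrices.
#' @param d_max largest dimension scanned; must not exceed
#'   `floor(min(D, n_S - 1, n_T - 1) / 2)`.
#' @param eps saturation tolerance (default 1e-6).
#' @return An object of class `sdm_profile` with fields `d`, `D_d`, `alpha`,
#'   `beta`, `d_star`.
#' @export
select_dimension <- function(XS, XT, d_max = NULL, eps = 1e-6) {
  XS <- as.matrix(XS)
  XT <- as.matrix(XT)
  if (ncol(XS) != ncol(XT)) stop("feature dimension mismatch", call. = FALSE)
  cap <- floor(min(ncol(XS), nrow(XS) - 1, nrow(XT) - 1) / 2)
  if (is.null(d_max)) d_max <- cap
  if (d_max < 1) stop("`d_max` must be >= 1", call. = FALSE)
  if (d_max > cap) {
    stop("`d_max` exceeds floor(min(D, n_S - 1, n_T - 1) / 2)", call. = FALSE)
  }
  BS <- pca_basis(XS, d_max)$basis
  BT <- pca_basis(XT, d_max)$basis
  BC <- pca_basis(rbind(XS, XT), d_max)$basis
  alpha <- beta <- D_d <- numeric(d_max)
  for (d in seq_len(d_max)) {
    alpha[d] <- largest_angle(BS, BC, d)
    beta[d] <- largest_angle(BT, BC, d)
    D_d[d] <- 0.5 * (sin(alpha[d]) + sin(beta[d]))
  }
  sat <- which(D_d >= 1 - eps)
  d_star <- if (length(sat)) sat[1] else d_max
  structure(list(d = seq_len(d_max), D_d = D_d, alpha = alpha, beta = beta,
                 d_star = as.integer(d_star)),
            class = "sdm_profile")
}

#' @export
print.sdm_profile <- function(x, ...) {
  cat(sprintf("<sdm_profile> d_max = %d, selected d* = %d, D(d*) = %.4f\n",
              max(x$d), x$d_star, x$D_d[x$d_star]))
  invisible(x)
}

#' Plot a subspace disagreement profile
#'
#' @param x an `sdm_profile`.
#' @param ... passed to [graphics::plot].
#' @export
plot.sdm_profile <- function(x, ...) {
  graphics::plot(x$d, x$D_d, type = "b", xlab = "subspace dimension d",
                 ylab = "D(d)", ylim = c(0, 1), ...)
  graphics::abline(v = x$d_star, lty = 2)
  invisible(x)
}

# Symmetrized KL divergence between two univariate Gaussians.
sym_kl_gauss <- function(m1, v1, m2, v2) {
  kl <- function(ma, va, mb, vb) {
    0.5 * (log(vb / va) + (va + (ma - mb)^2) / vb - 1)
  }
  kl(m1, v1, m2, v2) + kl(m2, v2, m1, v1)
}

#' Rank of domain (ROD) between two feature sets
#'
#' `R(S, T) = (1/d) sum_i theta_i [KL(S_i || T_i) + KL(T_i || S_i)]` where
#' `theta_i` are the principal angles between the two PCA subspaces and
#' `S_i`, `T_i` are univariate Gaussians fitted to the source data projected
#' on the i-th aligned source principal direction (`PS U1 e_i`) and the
#' target data projected on the i-th aligned target direction (`PT V e_i`).
#' Identical datasets score 0; lower scores mark domain pairs more likely to
#' adapt well.  Projection variances are floored at 1e-12.
#'
#' @param XS,XT standardized source / target feature matrices.
#' @param d subspace dimension; defaults to the SDM-selected `d_star`.
#' @return An object of class `rod_score` with fields `value`, `d`, `theta`.
#' @export
rod <- function(XS, XT, d = NULL) {
  XS <- as.matrix(XS)
  XT <- as.matrix(XT)
  if (ncol(XS) != ncol(XT)) stop("feature dimension mismatch", call. = FALSE)
  if (is.null(d)) d <- select_dimension(XS, XT)$d_star
  PS <- pca_basis(XS, d)
  PT <- pca_basis(XT, d)
  s <- svd(crossprod(PS$basis, PT$basis))
  theta <- acos(clip01(s$d))
  dirS <- PS$basis %*% s$u
  dirT <- PT$basis %*% s$v
  projS <- XS %*% dirS
  projT <- XT %*% dirT
  val <- 0
  for (i in seq_len(d)) {
    vS <- max(stats::var(projS[, i]), 1e-12)
    vT <- max(stats::var(projT[, i]), 1e-12)
    val <- val + theta[i] *
      sym_kl_gauss(mean(projS[, i]), vS, mean(projT[, i]), vT)
  }
  structure(list(value = val / d, d = as.integer(d), theta = theta),
            class = "rod_score")
}

#' @export
print.rod_score <- function(x, ...) {
  cat(sprintf("<rod_score> R = %.4g (d = %d)\n", x$value, x$d))
  invisible(x)
}
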