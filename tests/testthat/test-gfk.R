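test_that("pca_basis recovers exact low-rank structure and is orthonormal", {
  set.seed(5)
  # points exactly in a 2-plane of R^5
  B <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  X <- matrix(rnorm(60), 30, 2) %*% t(B)
  sub <- pca_basis(X, 2)
  Xc <- sweep(X, 2, colMeans(X))
  resid <- Xc - Xc %*% sub$basis %*% t(sub$basis)
  expect_lt(max(abs(resid)), 1e-10)
  expect_lt(max(abs(crossprod(sub$basis) - diag(2))), 1e-10)
  expect_lt(max(abs(crossprod(sub$complement, sub$basis))), 1e-10)
  expect_error(pca_basis(X, 6), "must be an integer")
})

test_that("pca_basis agrees with a covariance eigendecomposition oracle", {
  set.seed(6)
  X <- matrix(rnorm(300), 50, 6)
  sub <- pca_basis(X, 3)
  Xc <- sweep(X, 2, colMeans(X))
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  oracle <- eig$vectors[, 1:3]
  angles <- acos(pmin(1, svd(crossprod(sub$basis, oracle))$d))
  expect_lt(max(angles), 1e-7)
})

test_that("principal angles on closed-form configurations", {
  mk <- function(cols) structure(
    list(basis = cols,
         complement = qr.Q(qr(cols), complete = TRUE)[, -seq_len(ncol(cols)),
                                                      drop = FALSE],
         d = ncol(cols), D = nrow(cols)), class = "subspace")
  e <- diag(4)
  same <- principal_angles(mk(e[, 1, drop = FALSE]), mk(e[, 1, drop = FALSE]))
  expect_equal(same$theta, 0, tolerance = 1e-12)
  orth <- principal_angles(mk(e[, 1, drop = FALSE]), mk(e[, 2, drop = FALSE]))
  expect_equal(orth$theta, pi / 2, tolerance = 1e-12)
  g <- 0.3
  rot <- principal_angles(mk(e[, 1, drop = FALSE]),
                          mk(cbind(cos(g) * e[, 1] + sin(g) * e[, 2])))
  expect_equal(rot$theta, 0.3, tolerance = 1e-12)
  expect_error(principal_angles(mk(e[, 1:2]), mk(diag(6)[, 1:2])), "mismatch")
})

test_that("angle decomposition reproduces both SVD factors of the bases", {
  set.seed(7)
  for (i in 1:20) {
    D <- sample(6:16, 1)
    d <- sample(seq_len(D %/% 2), 1)
    PS <- pca_basis(matrix(rnorm(40 * D), 40), d)
    PT <- pca_basis(matrix(rnorm(40 * D), 40), d)
    dec <- principal_angles(PS, PT)
    expect_true(all(diff(dec$theta) >= -1e-12))
    expect_true(all(dec$theta >= 0 & dec$theta <= pi / 2 + 1e-12))
    # PS' PT = U1 Gamma V'
    expect_lt(max(abs(crossprod(PS$basis, PT$basis) -
                        dec$U1 %*% diag(dec$cosines, d) %*% t(dec$V))), 1e-10)
    # RS' PT = -U2 Sigma V'
    expect_lt(max(abs(crossprod(PS$complement, PT$basis) +
                        dec$U2 %*% diag(dec$sines, d) %*% t(dec$V))), 1e-10)
  }
})

test_that("geodesic kernel reduces to the shared projector at zero angles", {
  set.seed(8)
  PS <- pca_basis(matrix(rnorm(30 * 8), 30), 3)
  g0 <- geodesic_kernel(principal_angles(PS, PS), PS)
  expect_lt(max(abs(g0$G - tcrossprod(PS$basis))), 1e-10)
})

test_that("closed-form kernel matches Simpson quadrature of the flow", {
  set.seed(9)
  worst <- 0
  for (i in 1:10) {
    D <- sample(6:20, 1)
    d <- sample(seq_len(D %/% 2), 1)
    PS <- pca_basis(matrix(rnorm(50 * D), 50), d)
    PT <- pca_basis(matrix(rnorm(50 * D), 50), d)
    dec <- principal_angles(PS, PT)
    gk <- geodesic_kernel(dec, PS)
    worst <- max(worst, max(abs(gk$G - simpson_gfk(PS, dec))))
    expect_lt(max(abs(gk$G - t(gk$G))), 1e-10)
    expect_gt(min(eigen(gk$G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("kernel_dot computes x' G y (identity and triple-loop oracle)", {
  set.seed(10)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(15), 5, 3)
  expect_equal(kernel_dot(diag(3), X, Y), X %*% t(Y))
  G <- crossprod(matrix(rnorm(9), 3))
  K <- kernel_dot(G, X, Y)
  for (i in 1:4) for (j in 1:5) {
    acc <- 0
    for (a in 1:3) for (b in 1:3) acc <- acc + X[i, a] * G[a, b] * Y[j, b]
    expect_equal(K[i, j], acc, tolerance = 1e-12)
  }
  Kxx <- kernel_dot(G, X, X)
  expect_equal(Kxx, t(Kxx), tolerance = 1e-12)
  expect_gt(min(eigen(Kxx, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  expect_error(kernel_dot(G, matrix(0, 2, 4), Y), "mismatch")
})

test_that("SDM is zero for identical domains and bounded in [0, 1]", {
  set.seed(12)
  X <- matrix(rnorm(200 * 12), 200)
  prof <- select_dimension(X, X, d_max = 5)
  expect_lt(max(prof$D_d), 1e-7)
  expect_equal(prof$d_star, 5L)
  Y <- matrix(rnorm(200 * 12), 200)
  prof2 <- select_dimension(X, Y)
  expect_true(all(prof2$D_d >= 0 & prof2$D_d <= 1))
  expect_error(select_dimension(X, Y, d_max = 0), ">= 1")
  expect_error(select_dimension(X, Y, d_max = 50), "exceeds")
})

test_that("SDM profile matches a compositional pca/angle oracle", {
  set.seed(13)
  XS <- matrix(rnorm(200 * 20), 200)
  XT <- matrix(rnorm(200 * 20), 200) + 0.5
  prof <- select_dimension(XS, XT, d_max = 5)
  for (d in 1:5) {
    a <- max(principal_angles(pca_basis(XS, d),
                              pca_basis(rbind(XS, XT), d))$theta)
    b <- max(principal_angles(pca_basis(XT, d),
                              pca_basis(rbind(XS, XT), d))$theta)
    expect_equal(prof$D_d[d], 0.5 * (sin(a) + sin(b)), tolerance = 1e-10)
  }
})

test_that("ROD is zero on identical data and symmetric", {
  set.seed(14)
  X <- matrix(rnorm(100 * 8), 100)
  expect_equal(rod(X, X, d = 3)$value, 0, tolerance = 1e-12)
  Y <- matrix(rnorm(100 * 8), 100) %*% diag(seq(0.5, 4, length.out = 8))
  expect_equal(rod(X, Y, d = 3)$value, rod(Y, X, d = 3)$value,
               tolerance = 1e-10)
  expect_gte(rod(X, Y, d = 3)$value, 0)
})

test_that("median ROD increases with the size of a rotated mean shift", {
  meds <- vapply(c(0.5, 1, 2), function(sh) {
    stats::median(vapply(1:10, function(s) {
      set.seed(900 + s)
      D <- 10
      vars <- seq(1, 3, length.out = D)
      Q <- qr.Q(qr(matrix(rnorm(D * D), D)))
      XS <- sweep(matrix(rnorm(300 * D), 300), 2, sqrt(vars), `*`) %*% Q
      XT <- sweep(matrix(rnorm(300 * D), 300), 2, sqrt(vars), `*`)
      XT[, 1] <- XT[, 1] + sh * sqrt(vars[1])
      rod(XS, XT %*% Q, d = 3)$value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
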