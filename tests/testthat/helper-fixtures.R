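# Shared fixtures, generated in code at test time.

# Three linearly separable Gaussian classes in `D` dimensions.
separable_blobs <- function(n_per = 40, D = 6, gap = 5, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(0:2, function(k) {
    matrix(stats::rnorm(n_per * D, mean = k * gap), n_per, D)
  }))
  list(X = X, y = rep(c("A", "B", "C")[1:3], each = n_per))
}

# A quick small labelled domain via the full synthetic front end.
tiny_domain <- function(subject = subject_profile("T1"),
                        sensor = sensor_uniform_g64(),
                        tasks = c("H", "Sd", "W"), block_s = 40,
                        window_s = 10, seed = 1) {
  build_domain(subject, sensor, scenario_separate(tasks = tasks,
                                                  block_s = block_s),
               window_s, seed = seed)
}

# Composite-Simpson quadrature of the geodesic projector flow; the
# independent oracle for the closed-form kernel.
simpson_gfk <- function(PS, dec, nodes = 2001) {
  d <- dec$d
  ts <- seq(0, 1, length.out = nodes)
  w <- c(1, rep(c(4, 2), length.out = nodes - 2), 1)
  w <- w * (1 / (nodes - 1)) / 3
  O1 <- PS$basis %*% dec$U1
  O2 <- PS$complement %*% dec$U2
  G <- matrix(0, PS$D, PS$D)
  for (i in seq_len(nodes)) {
    phi <- O1 %*% diag(cos(ts[i] * dec$theta), d) -
      O2 %*% diag(sin(ts[i] * dec$theta), d)
    G <- G + w[i] * tcrossprod(phi)
  }
  G
}

# Independent re-implementation of the 12 band statistics from the direct
# formulas (kept deliberately different in style from band_stats()).
band_stats_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  en <- sum(x * x)
  ent <- 0
  if (en > 0) {
    for (v in x) {
      p <- v * v / en
      if (p > 0) ent <- ent - p * log(p)
    }
  }
  zc <- 0
  mc <- 0
  for (i in seq_len(n - 1)) {
    if (x[i] * x[i + 1] < 0) zc <- zc + 1
    if ((x[i] - mu) * (x[i + 1] - mu) < 0) mc <- mc + 1
  }
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(mu, sqrt(en / n), sum(abs(x - mu)) / n,
    if (n > 1) sqrt(sum((x - mu)^2) / (n - 1)) else 0,
    min(x), max(x), qs[2], qs[1], qs[3], ent, zc, mc)
}
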