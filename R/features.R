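# DWT time-frequency features: periodized Daubechies-4 decomposition,
# 12 summary statistics per band, 3 axes x 6 bands x 12 stats = 216 features.

# Daubechies-4 (4 vanishing moments, 8 taps) scaling filter in time order,
# normalized so that sum(g) = sqrt(2) and sum(g^2) = 1.
db4_scaling_filter <- function() {
  c(0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
    -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
    0.032883011666982945, -0.010597401784997278)
}

# Quadrature-mirror high-pass counterpart: h[i] = (-1)^(i-1) g[L-i+1].
db4_wavelet_filter <- function() {
  g <- db4_scaling_filter()
  L <- length(g)
  (-1)^(seq_len(L) - 1) * g[L:1]
}

# One periodized analysis step: even-length x -> (approximation, detail),
# each of length N/2.  Circular indexing keeps the step exactly orthogonal,
# so energy is conserved at every level.
dwt_step <- function(x) {
  N <- length(x)
  g <- db4_scaling_filter()
  h <- db4_wavelet_filter()
  k <- seq_len(N %/% 2L)
  a <- numeric(N %/% 2L)
  d <- numeric(N %/% 2L)
  base <- 2L * (k - 1L)
  for (j in seq_along(g)) {
    idx <- (base + (j - 1L)) %% N + 1L
    a <- a + g[j] * x[idx]
    d <- d + h[j] * x[idx]
  }
  list(a = a, d = d)
}

#' Periodized db4 wavelet decomposition
#'
#' Decomposes a single-axis window into detail coefficients at levels 1..5
#' and the level-5 approximation, using the Daubechies wavelet with 4
#' vanishing moments and periodic boundary extension.  Periodic extension
#' keeps the transform orthogonal, so total coefficient energy equals signal
#' energy and band lengths halve exactly per level.
#'
#' @param x numeric signal; its length must be a positive multiple of
#'   `2^levels`.
#' @param levels decomposition depth (default 5).
#' @return A named list `d1`..`d5`, `a5` of coefficient vectors.
#' @export
dwt_bands <- function(x, levels = 5) {
  n <- length(x)
  if (n < 2^levels || n %% 2^levels != 0) {
    stop("signal length must be a multiple of 2^levels (and >= 2^levels) ",
         "for a ", levels, "-level periodized decomposition", call. = FALSE)
  }
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    st <- dwt_step(cur)
    out[[lev]] <- st$d
    cur <- st$a
  }
  out[[levels + 1L]] <- cur
  out
}

#' Twelve summary statistics of a coefficient band
#'
#' Returns, in order: mean, root mean square, mean absolute deviation (about
#' the mean), standard deviation, minimum, maximum, median, 25th percentile,
#' 75th percentile, energy entropy, zero-crossing count and mean-crossing
#' count.  Entropy is the Shannon entropy of the normalized coefficient
#' energy distribution p_j = c_j^2 / sum(c^2) (0 log 0 := 0; an all-zero band
#' has entropy 0).  Crossings are strict sign changes between consecutive
#' coefficients (of c, resp. c - mean(c)); exact zeros do not count.
#'
#' @param coeffs nonempty numeric vector.
#' @return A named numeric vector of length 12.
#' @export
band_stats <- function(coeffs) {
  n <- length(coeffs)
  if (n == 0L) stop("empty coefficient array", call. = FALSE)
  m <- mean(coeffs)
  e2 <- sum(coeffs^2)
  if (e2 > 0) {
    p <- coeffs^2 / e2
    p <- p[p > 0]
    entropy <- -sum(p * log(p))
  } else {
    entropy <- 0
  }
  centred <- coeffs - m
  q <- stats::quantile(coeffs, c(0.25, 0.5, 0.75), names = FALSE)
  c(mean = m,
    rms = sqrt(mean(coeffs^2)),
    mad = mean(abs(centred)),
    sd = if (n > 1L) stats::sd(coeffs) else 0,
    min = min(coeffs),
    max = max(coeffs),
    median = q[2],
    p25 = q[1],
    p75 = q[3],
    entropy = entropy,
    zc = if (n > 1L) sum(coeffs[-n] * coeffs[-1] < 0) else 0,
    mc = if (n > 1L) sum(centred[-n] * centred[-1] < 0) else 0)
}

feature_names <- function() {
  axes <- c("x", "y", "z")
  bands <- c(paste0("d", 1:5), "a5")
  stats <- c("mean", "rms", "mad", "sd", "min", "max", "median", "p25", "p75",
             "entropy", "zc", "mc")
  as.vector(vapply(axes, function(a) {
    vapply(bands, function(b) paste(a, b, stats, sep = "_"),
           character(length(stats)))
  }, matrix(character(), length(stats), length(bands))))
}

#' Extract the 216-value time-frequency feature vector of one window
#'
#' Axis-major ordering (x, y, z), then band (d1..d5, a5), then the 12
#' statistics of [band_stats].  The length is 216 for any admissible window
#' length (both 320-sample 10 s and 128-sample 4 s windows at 32 Hz).
#'
#' @param window a `labelled_window` from [segment_windows], or a bare
#'   n x 3 sample matrix.
#' @return A named numeric vector of length 216.
#' @export
extract_features <- function(window) {
  samples <- if (inherits(window, "labelled_window")) window$samples else
    as.matrix(window)
  if (ncol(samples) != 3L) stop("window must have three axes", call. = FALSE)
  out <- unlist(lapply(1:3, function(axis) {
    bands <- dwt_bands(samples[, axis])
    unlist(lapply(bands, band_stats), use.names = FALSE)
  }), use.names = FALSE)
  names(out) <- feature_names()
  out
}

#' Domain dataset constructor
#'
#' A feature matrix for one (subject, sensor, scenario) domain with optional
#' labels and, once [standardize] has been applied, the per-column location
#' and scale used.
#'
#' @param X numeric feature matrix (rows = windows).
#' @param labels optional character/factor task labels, one per row.
#' @param meta free-form metadata list (subject, sensor, scenario, ...).
#' @return An object of class `domain_dataset`.
#' @export
domain_dataset <- function(X, labels = NULL, meta = list()) {
  X <- as.matrix(X)
  if (!is.null(labels) && length(labels) != nrow(X)) {
    stop("label length must match the number of rows", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  structure(list(X = X, labels = if (is.null(labels)) NULL else
                   as.character(labels),
                 meta = meta, center = NULL, scale = NULL,
                 standardized = FALSE),
            class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset> %d windows x %d features%s%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$labels)) ", unlabelled" else
                sprintf(", %d task labels", length(unique(x$labels))),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Build a domain dataset from labelled windows
#'
#' @param windows list of `labelled_window` objects.
#' @param meta metadata list stored on the domain.
#' @return A [domain_dataset] with one feature row per window.
#' @export
features_from_windows <- function(windows, meta = list()) {
  if (length(windows) == 0L) stop("no windows to featurize", call. = FALSE)
  X <- t(vapply(windows, extract_features, numeric(216)))
  domain_dataset(X, labels = vapply(windows, `[[`, character(1), "label"),
                 meta = meta)
}

#' Standardize a domain's features
#'
#' Per-column z-scoring using the domain's own mean and standard deviation
#' (each domain carries its own statistics; source and target are scaled
#' independently).  Columns with near-zero spread are centered only.
#'
#' @param domain a [domain_dataset] with at least two rows.
#' @return The domain with standardized `X` and stored `center` / `scale`.
#' @export
standardize <- function(domain) {
  stopifnot(inherits(domain, "domain_dataset"))
  if (nrow(domain$X) < 2L) {
    stop("need at least 2 rows to standardize", call. = FALSE)
  }
  ctr <- colMeans(domain$X)
  scl <- apply(domain$X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  domain$X <- sweep(sweep(domain$X, 2, ctr, `-`), 2, scl, `/`)
  domain$center <- ctr
  domain$scale <- scl
  domain$standardized <- TRUE
  domain
}
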