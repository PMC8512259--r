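# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators never disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
subseed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 1000003 + abs(p) + 1) %% 2147483629
  as.integer(h)
}

# Convert an arbitrary string to a small integer for sub-seeding.
string_seed <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 65521L
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; `axis` need not be normalized.
#' @param axis length-3 numeric axis of rotation.
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix with determinant +1.
#' @export
rotation_about_axis <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(diag(3))
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Standard gravity, m/s^2.
STANDARD_GRAVITY <- 9.80665
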