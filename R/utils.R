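# Unit conversion: 1 mmHg = 133.322 Pa.
MMHG_PA <- 133.322

mmhg_to_pa <- function(x) x * MMHG_PA
pa_to_mmhg <- function(x) x / MMHG_PA

#' Draw from a truncated normal distribution
#'
#' Rejection sampler used for modelled flow rates and cohort parameter
#' sampling. Deterministic given the current RNG state.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower > upper) abort("truncation bounds reversed (lower > upper)")
  out <- numeric(n)
  need <- seq_len(n)
  for (iter in 1:1000) {
    draws <- rnorm(length(need), mean, sd)
    ok <- draws >= lower & draws <= upper
    out[need[ok]] <- draws[ok]
    need <- need[!ok]
    if (length(need) == 0L) return(out)
  }
  # Pathological bounds: fall back to inverse-CDF sampling.
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  out[need] <- stats::qnorm(runif(length(need), pl, pu), mean, sd)
  out
}

# Evaluate expr with a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stable per-stage seed derivation: keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (as.double(seed) * 48271 + h * 9973 + as.double(index) * 7919) %% (2^31 - 2)
  as.integer(val) + 1L
}

# Shoelace area of a closed planar polygon given as an n x 2 matrix.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Rotation matrix mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))
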