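# Internal helpers shared across modules: argument validation, seeded RNG
# scoping, Otsu thresholding, and ordinary least squares on two vectors.

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         finite = TRUE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single non-missing number")
  if (finite && !is.finite(x)) stop_field(field, "must be finite")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_field(field, "must be a whole number")
  invisible(x)
}

# Run code with a temporary RNG state so generators are deterministic per
# seed without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Otsu's method on a 256-bin histogram of the supplied intensities.
# Returns the threshold on the original intensity scale; pixels strictly
# above the threshold are foreground.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stop("cannot threshold: intensities are constant", call. = FALSE)
  rng <- range(x)
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nb * diff(rng)
}

# Ordinary least squares of y on x; returns c(intercept, slope).
ols_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need >= 2 finite points for regression",
                           call. = FALSE)
  if (diff(range(x)) == 0) stop("all abscissae identical; slope undefined",
                                call. = FALSE)
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(intercept = ym - b * xm, slope = b)
}

r_squared <- function(x, y, coefs) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  fit <- coefs[1] + coefs[2] * x
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}
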