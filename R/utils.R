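# Internal numerical helpers shared across modules.

# Mean and SD of a normal truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the truncation of N(mu, sigma) to [lo, hi]
# has the requested mean and SD. Solved once per configuration by
# Nelder-Mead on the squared moment mismatch.
truncnorm_match <- function(target_mean, target_sd, lo, hi) {
  stopifnot(target_mean > lo, target_mean < hi, target_sd > 0)
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    sum((mm - c(target_mean, target_sd))^2)
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
    method = "Nelder-Mead",
    control = list(reltol = 1e-13, maxit = 10000)
  )
  if (fit$value > 1e-8) {
    stop("could not match truncated-normal moments for [", lo, ", ", hi, "]")
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi)
}

# Inverse-CDF sampler for the truncated normal; exact for any truncation.
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, plo, phi), mu, sigma)
}

# Analytic circularity 4*pi*A/P^2 of an ellipse with semi-axes a >= b,
# using Ramanujan's second perimeter approximation.
ellipse_circularity <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  p <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * a * b) / p^2
}

# Percent rounded to the nearest integer, halves away from zero.
round_percent <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5)
}

# Seed scoped to a generator call: derive a reproducible sub-stream without
# clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed),
      kind = "Mersenne-Twister", normal.kind = "Inversion",
      sample.kind = "Rejection"
    )
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x surprise: always samples from the vector x.
sample_vec <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
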