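#' Draw from a lower-truncated normal distribution
#'
#' Samples from N(mean, sd^2) conditioned on being at least `lower`.
#' Inverse-CDF sampling on the upper tail is used for moderate truncation;
#' for extreme truncation (standardized bound above 6) the exponential
#' rejection sampler of Robert (1995) takes over, which stays exact where
#' the tail probability underflows.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the untruncated normal (vectors recycled to
#'   length `n`).
#' @param lower truncation bound (vector recycled to length `n`).
#' @return numeric vector of `n` draws, all `>= lower`.
#' @export
rtnorm_lower <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  lower <- rep_len(lower, n)
  alpha <- (lower - mean) / sd
  z <- numeric(n)
  easy <- alpha < 6
  if (any(easy)) {
    p <- pnorm(alpha[easy], lower.tail = FALSE)
    z[easy] <- qnorm(runif(sum(easy)) * p, lower.tail = FALSE)
  }
  if (any(!easy)) {
    for (i in which(!easy)) {
      a <- alpha[i]
      lam <- (a + sqrt(a^2 + 4)) / 2
      repeat {
        x <- a + rexp(1L, lam)
        if (runif(1L) <= exp(-(x - lam)^2 / 2)) break
      }
      z[i] <- x
    }
  }
  # guard against qnorm(0) = Inf at the very edge of double precision
  z[!is.finite(z)] <- alpha[!is.finite(z)]
  mean + sd * z
}

# Inverse-gamma draw: if g ~ Gamma(shape, rate = 1) then rate_param/g is
# InvGamma(shape, rate_param) with density x^-(shape+1) exp(-rate_param/x).
rinvgamma1 <- function(shape, rate) {
  rate / rgamma(1L, shape = shape)
}

group_label <- function(genotype, treatment) {
  paste(genotype, treatment, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
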