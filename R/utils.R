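#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when presenting dollar amounts, as
#' opposed to the banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Normal draws truncated below at zero (inverse-CDF method).  sd = 0
## degenerates to the mean.
rnorm_trunc0 <- function(n, mean, sd) {
  stopifnot(all(sd >= 0))
  out <- rep(mean, length.out = n)
  sd <- rep(sd, length.out = n)
  mean <- rep(mean, length.out = n)
  pos <- sd > 0
  if (any(pos)) {
    lo <- pnorm(0, mean[pos], sd[pos])
    out[pos] <- qnorm(lo + runif(sum(pos)) * (1 - lo), mean[pos], sd[pos])
  }
  out
}

## One draw from a Dirichlet distribution.  Infinite total concentration
## degenerates to the normalized alpha (used for zero-variance analyses).
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha >= 0), any(alpha > 0))
  if (any(is.infinite(alpha))) {
    w <- is.infinite(alpha)
    return(as.numeric(w) / sum(w))
  }
  x <- rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) { # all-zero draw possible for tiny alphas
    x[which.max(alpha)] <- 1
  }
  x / sum(x)
}

## Method-of-moments Beta parameters from a mean and standard error.
beta_from_moments <- function(mean, se) {
  stopifnot(mean > 0, mean < 1, se >= 0)
  if (se == 0) return(c(shape1 = Inf, shape2 = Inf))
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0) {
    stop("standard error ", se, " too large for a Beta with mean ", mean)
  }
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

## Day offset of the k-th birthday from birth; both the synthetic generator
## and the utilization estimator use this convention so that age-period
## assignment is calendar-free.
birthday_offset <- function(k) as.integer(round(k * 365.25))

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
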