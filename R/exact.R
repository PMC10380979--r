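# Exact scaled-integer arithmetic for line coefficients.
#
# Cost-line and boundary-line coefficients are polynomial in the inputs
# (se, sp, alpha, rho). When every input is an exact decimal fraction the
# coefficients are integers over a power-of-ten scale; as long as those
# integers stay below 2^53 they are represented exactly by doubles, which
# lets coincident and parallel lines be detected by exact comparison rather
# than by tolerance. When an input is not a short decimal, or a magnitude
# bound would be exceeded, all callers fall back to plain floating point
# with the documented tolerances.

.MAX_EXACT <- 2^53

# Smallest k in 0..max_digits with x * 10^k integral, or NA_integer_.
.decimal_digits <- function(x, max_digits = 9L) {
  out <- rep(NA_integer_, length(x))
  for (k in 0:max_digits) {
    scaled <- x * 10^k
    ok <- is.na(out) & abs(scaled - round(scaled)) <= 1e-9 * pmax(1, abs(scaled))
    out[ok] <- k
  }
  out
}

# Euclid on integer-valued doubles (exact below 2^53).
.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  max(a, 1)
}

# Exact integer lifts of the per-classifier cost-surface coefficients.
# Returns NULL when exactness cannot be guaranteed, otherwise a list with
# integer-valued matrices at a common scale:
#   misc:    slope, intercept        (scale S*P)
#   miscrej: g0, g1, const           (scale S*P*A)
# where rc_misc = slope*rc1 + intercept and
#       rc_miscrej = g0*rc0 + g1*rc1 + const (after dividing by the scale).
.exact_coeffs <- function(se, sp, alpha, rho) {
  kr <- .decimal_digits(rho)
  kp <- suppressWarnings(max(.decimal_digits(c(se, sp))))
  ka <- suppressWarnings(max(.decimal_digits(alpha)))
  if (anyNA(c(kr, kp, ka))) return(NULL)
  # digit budget keeps every product strictly below 2^53
  if (kr + 2L * kp + ka > 15L) return(NULL)
  S <- 10^kr; P <- 10^kp; A <- 10^ka
  R <- round(rho * S)
  E <- round((1 - se) * P)
  F_ <- round((1 - sp) * P)
  a <- round(alpha * A)
  slope <- (S - R) * F_ - R * E            # scale S*P
  intercept <- R * E                       # scale S*P
  g0 <- a * R * E + (a - A) * S * P        # scale S*P*A
  g1 <- a * (S - R) * F_ + (a - A) * S * P # scale S*P*A
  const <- (A - a) * S * P                 # scale S*P*A
  vals <- c(slope, intercept, g0, g1, const)
  if (any(abs(vals) >= .MAX_EXACT)) return(NULL)
  list(
    slope = slope, intercept = intercept,
    g0 = g0, g1 = g1, const = const,
    scale_misc = S * P, scale_miscrej = S * P * A
  )
}

# Exact equality of two integer ratios n1/d1 == n2/d2, with gcd reduction
# and an overflow guard; returns NA when exactness cannot be guaranteed.
.ratio_equal <- function(n1, d1, n2, d2) {
  g1 <- .gcd(n1, d1); g2 <- .gcd(n2, d2)
  n1 <- n1 / g1; d1 <- d1 / g1
  n2 <- n2 / g2; d2 <- d2 / g2
  if (abs(n1 * d2) >= .MAX_EXACT || abs(n2 * d1) >= .MAX_EXACT) return(NA)
  n1 * d2 == n2 * d1
}
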