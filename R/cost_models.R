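# Cost models.
#
# Misclassification-only model (MISC):
#   c  = rho (1 - se) c0 + (1 - rho)(1 - sp) c1
#   rc = [(1 - rho)(1 - sp) - rho (1 - se)] rc1 + rho (1 - se)
# with rc0 = 1 - rc1 implied; the clinical space is the interval I = (0, 1)
# of rc1 values.
#
# Misclassification + rejection model (MISC+REJ):
#   c  = alpha rho (1 - se) c0 + alpha (1 - rho)(1 - sp) c1 + (1 - alpha) c2
#   rc = [alpha rho (1 - se) + alpha - 1] rc0
#      + [alpha (1 - rho)(1 - sp) + alpha - 1] rc1 + 1 - alpha
# with rc2 = 1 - rc0 - rc1 implied; the clinical space is the triangle T
# with vertices (0,0), (1,0), (0,1) in the rc0-rc1 plane.

# Per-classifier MISC line coefficients: rc = slope * rc1 + intercept.
.misc_coeffs <- function(profiles, rho) {
  list(slope = (1 - rho) * (1 - profiles$sp) - rho * (1 - profiles$se),
       intercept = rho * (1 - profiles$se))
}

# Per-classifier MISC+REJ plane coefficients: rc = g0*rc0 + g1*rc1 + const.
.miscrej_coeffs <- function(profiles, rho) {
  a <- profiles$alpha
  list(g0 = a * rho * (1 - profiles$se) + a - 1,
       g1 = a * (1 - rho) * (1 - profiles$sp) + a - 1,
       const = 1 - a)
}

#' Expected misclassification cost of a classifier
#'
#' Average cost, in the units of `c0`/`c1`, of deploying a classifier with
#' the given sensitivity and specificity in a population with pathogenic
#' fraction `rho`:
#' `c = rho * (1 - se) * c0 + (1 - rho) * (1 - sp) * c1`.
#'
#' @param profile a one-row [profile_set()] (or anything coercible).
#' @param rho pathogenic-variant frequency, in (0, 1).
#' @param c0 cost of calling a pathogenic variant benign (false negative).
#' @param c1 cost of calling a benign variant pathogenic (false positive).
#' @return The expected cost (single number).
#' @examples
#' misc_expected_cost(predictor_profile("REVEL", 0.92, 0.94), rho = 0.5,
#'                    c0 = 1, c1 = 1)
#' @export
misc_expected_cost <- function(profile, rho, c0, c1) {
  profile <- as_profile_set(profile)
  stopifnot(nrow(profile) == 1L)
  rho <- .check_rho(rho)
  if (!is.numeric(c0) || !is.numeric(c1) || anyNA(c(c0, c1)) ||
      any(!is.finite(c(c0, c1))) || c0 < 0 || c1 < 0) {
    stop("costs c0, c1 must be finite and non-negative")
  }
  if (c0 + c1 <= 0) stop("cost magnitude c0 + c1 must be positive")
  rho * (1 - profile$se) * c0 + (1 - rho) * (1 - profile$sp) * c1
}

#' Normalized misclassification-only cost at a clinical scenario
#'
#' Evaluates the MISC normalized cost `rc` at scenario `rc1` (the normalized
#' false-positive cost; `rc0 = 1 - rc1` implied). Values of `rc1` on the
#' boundary of the clinical space (0 or 1) are accepted for evaluation even
#' though partitions are defined on the open interior.
#'
#' @inheritParams misc_expected_cost
#' @param rc1 scenario coordinate(s) in \[0, 1\]; vectorized.
#' @return Normalized cost(s) in \[0, 1\].
#' @examples
#' misc_normalized_cost(predictor_profile("REVEL", 0.92, 0.94), 0.5, rc1 = 0.5)
#' @export
misc_normalized_cost <- function(profile, rho, rc1) {
  profile <- as_profile_set(profile)
  stopifnot(nrow(profile) == 1L)
  rho <- .check_rho(rho)
  if (!is.numeric(rc1) || anyNA(rc1) || any(!is.finite(rc1)) ||
      any(rc1 < 0 | rc1 > 1)) {
    stop("scenario rc1 must lie in [0, 1]")
  }
  k <- .misc_coeffs(profile, rho)
  k$slope * rc1 + k$intercept
}

#' Normalized misclassification + rejection cost at a clinical scenario
#'
#' Evaluates the MISC+REJ normalized cost `rc` at scenario `(rc0, rc1)`
#' inside the triangle T (`rc2 = 1 - rc0 - rc1` implied). Boundary points of
#' T are accepted for evaluation.
#'
#' @inheritParams misc_expected_cost
#' @param rc0 normalized false-negative cost(s); vectorized with `rc1`.
#' @param rc1 normalized false-positive cost(s).
#' @return Normalized cost(s) in \[0, 1\].
#' @examples
#' miscrej_normalized_cost(predictor_profile("A", 0.92, 0.94), 0.5,
#'                         rc0 = 0.3, rc1 = 0.3)
#' @export
miscrej_normalized_cost <- function(profile, rho, rc0, rc1) {
  profile <- as_profile_set(profile)
  stopifnot(nrow(profile) == 1L)
  rho <- .check_rho(rho)
  if (!is.numeric(rc0) || !is.numeric(rc1) || length(rc0) != length(rc1) ||
      anyNA(c(rc0, rc1)) || any(!is.finite(c(rc0, rc1)))) {
    stop("scenario (rc0, rc1) must be finite numeric of equal length")
  }
  if (any(rc0 < -1e-12 | rc1 < -1e-12 | rc0 + rc1 > 1 + 1e-12)) {
    stop("scenario (rc0, rc1) must lie inside the triangle T: ",
         "rc0 >= 0, rc1 >= 0, rc0 + rc1 <= 1")
  }
  k <- .miscrej_coeffs(profile, rho)
  k$g0 * rc0 + k$g1 * rc1 + k$const
}

# Vectorized cost matrices used by the partitioners and the oracle:
# rows = scenarios, columns = classifiers.
.misc_cost_matrix <- function(profiles, rho, rc1) {
  k <- .misc_coeffs(profiles, rho)
  outer(rc1, k$slope) + rep(k$intercept, each = length(rc1))
}

.miscrej_cost_matrix <- function(profiles, rho, rc0, rc1) {
  k <- .miscrej_coeffs(profiles, rho)
  outer(rc0, k$g0) + outer(rc1, k$g1) + rep(k$const, each = length(rc0))
}

#' Equal-cost boundary line between two classifiers
#'
#' Under the rejection model, the locus where two classifiers have equal
#' normalized cost is the straight line
#' `a * rc0 + b * rc1 + c = 0` with
#' `a = rho * (alpha_i (1 - se_i) - alpha_j (1 - se_j)) + alpha_i - alpha_j`,
#' `b = (1 - rho) * (alpha_i (1 - sp_i) - alpha_j (1 - sp_j)) + alpha_i - alpha_j`,
#' `c = alpha_j - alpha_i`.
#' Classifier pairs whose cost surfaces coincide everywhere (identical
#' `(se, sp, alpha)` contributions) have no dividing line and are flagged
#' `coincident`. Coincidence is detected by exact comparison when the inputs
#' are exact decimal fractions, by a 1e-15-scale tolerance otherwise.
#'
#' @param p_i,p_j one-row [profile_set()]s of the two classifiers.
#' @param rho pathogenic-variant frequency, in (0, 1).
#' @return An object of class `boundary_line`: a list with coefficients
#'   `a`, `b`, `c`, the compared `pair` of names, and a logical `coincident`.
#' @examples
#' boundary_line(predictor_profile("A", 0.9, 0.7),
#'               predictor_profile("B", 0.7, 0.9), rho = 0.5)
#' @export
boundary_line <- function(p_i, p_j, rho) {
  p_i <- as_profile_set(p_i); p_j <- as_profile_set(p_j)
  stopifnot(nrow(p_i) == 1L, nrow(p_j) == 1L)
  if (identical(p_i$name, p_j$name)) {
    stop("boundary_line needs two distinct classifier identities")
  }
  rho <- .check_rho(rho)
  both <- rbind(as.data.frame(p_i), as.data.frame(p_j))
  ex <- .exact_coeffs(both$se, both$sp, both$alpha, rho)
  if (!is.null(ex)) {
    a <- (ex$g0[1] - ex$g0[2]) / ex$scale_miscrej
    b <- (ex$g1[1] - ex$g1[2]) / ex$scale_miscrej
    cc <- (ex$const[1] - ex$const[2]) / ex$scale_miscrej
    coincident <- (ex$g0[1] == ex$g0[2]) && (ex$g1[1] == ex$g1[2]) &&
      (ex$const[1] == ex$const[2])
  } else {
    k <- .miscrej_coeffs(both, rho)
    a <- k$g0[1] - k$g0[2]
    b <- k$g1[1] - k$g1[2]
    cc <- k$const[1] - k$const[2]
    coincident <- all(abs(c(a, b, cc)) <= 1e-15)
  }
  structure(list(a = a, b = b, c = cc,
                 pair = c(p_i$name, p_j$name),
                 coincident = coincident),
            class = "boundary_line")
}

#' @export
print.boundary_line <- function(x, ...) {
  if (x$coincident) {
    cat("Boundary line ", x$pair[1], " vs ", x$pair[2],
        ": coincident cost surfaces (no dividing line)\n", sep = "")
  } else {
    cat("Boundary line ", x$pair[1], " vs ", x$pair[2], ": ",
        format(x$a), " * rc0 + ", format(x$b), " * rc1 + ",
        format(x$c), " = 0\n", sep = "")
  }
  invisible(x)
}

# All pairwise boundary lines for a profile set; returns a data.frame with
# columns a, b, c, i, j, coincident (one row per unordered pair).
.all_boundary_lines <- function(profiles, rho) {
  n <- nrow(profiles)
  if (n < 2L) {
    return(data.frame(a = numeric(0), b = numeric(0), c = numeric(0),
                      i = integer(0), j = integer(0), coincident = logical(0)))
  }
  ex <- .exact_coeffs(profiles$se, profiles$sp, profiles$alpha, rho)
  if (!is.null(ex)) {
    g0 <- ex$g0; g1 <- ex$g1; cst <- ex$const; sc <- ex$scale_miscrej
  } else {
    k <- .miscrej_coeffs(profiles, rho)
    g0 <- k$g0; g1 <- k$g1; cst <- k$const; sc <- 1
  }
  ij <- utils::combn(n, 2L)
  i <- ij[1L, ]; j <- ij[2L, ]
  a <- g0[i] - g0[j]; b <- g1[i] - g1[j]; cc <- cst[i] - cst[j]
  coincident <- if (!is.null(ex)) {
    a == 0 & b == 0 & cc == 0
  } else {
    abs(a) <= 1e-15 & abs(b) <= 1e-15 & abs(cc) <= 1e-15
  }
  data.frame(a = a / sc, b = b / sc, c = cc / sc,
             i = i, j = j, coincident = coincident)
}
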