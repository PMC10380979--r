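# Partition of the 1-D clinical space I = (0, 1) under the
# misclassification-only model.
#
# Each classifier's normalized cost is a line in rc1. The procedure:
#   1. solve rc(M_i) = rc(M_j) for every pair,
#   2. discard crossings outside I, sort and de-duplicate the rest,
#   3. pick the classifier with the lowest cost at each sub-interval
#      midpoint (between consecutive crossings no two lines cross, so the
#      midpoint winner wins the whole sub-interval),
#   4. unify adjacent sub-intervals with the same winner.

#' Crossing point of two classifiers' cost lines (misclassification model)
#'
#' Solves `rc(M_i) = rc(M_j)` in the scenario coordinate `rc1`. Coverage is
#' ignored (treated as 1) in this model.
#'
#' @param p_i,p_j one-row [profile_set()]s.
#' @param rho pathogenic-variant frequency in (0, 1).
#' @return A list with `status` and, where applicable, `rc1`:
#'   * `"crossing"` — the lines cross at `rc1` inside the open interval (0, 1);
#'   * `"outside"`  — they cross, but at `rc1` outside (0, 1) (the location is
#'     reported; one classifier dominates throughout the interval);
#'   * `"parallel"` — equal slopes, different intercepts: no crossing, the
#'     lower line dominates;
#'   * `"coincident"` — identical cost lines.
#' @examples
#' pairwise_crossing(predictor_profile("A", 0.9, 0.7),
#'                   predictor_profile("B", 0.7, 0.9), rho = 0.5)
#' @export
pairwise_crossing <- function(p_i, p_j, rho) {
  p_i <- as_profile_set(p_i); p_j <- as_profile_set(p_j)
  stopifnot(nrow(p_i) == 1L, nrow(p_j) == 1L)
  rho <- .check_rho(rho)
  both <- rbind(as.data.frame(p_i), as.data.frame(p_j))
  ex <- .exact_coeffs(both$se, both$sp, both$alpha, rho)
  if (!is.null(ex)) {
    ds <- ex$slope[1] - ex$slope[2]
    di <- ex$intercept[2] - ex$intercept[1]
    if (ds == 0 && di == 0) return(list(status = "coincident", rc1 = NA_real_))
    if (ds == 0) return(list(status = "parallel", rc1 = NA_real_))
  } else {
    k <- .misc_coeffs(both, rho)
    ds <- k$slope[1] - k$slope[2]
    di <- k$intercept[2] - k$intercept[1]
    if (abs(ds) <= 1e-15) {
      if (abs(di) <= 1e-15) return(list(status = "coincident", rc1 = NA_real_))
      return(list(status = "parallel", rc1 = NA_real_))
    }
  }
  x <- di / ds
  status <- if (x > 0 && x < 1) "crossing" else "outside"
  list(status = status, rc1 = x)
}

#' Partition the 1-D clinical space among classifiers
#'
#' Splits the open interval (0, 1) of `rc1` scenarios into maximal
#' sub-intervals, each owned by the classifier with the lowest
#' misclassification cost throughout that sub-interval.
#'
#' @param profiles a [profile_set()] (coverage ignored in this model).
#' @param rho pathogenic-variant frequency in (0, 1).
#' @param tol tie tolerance for cost comparison at midpoints.
#' @return An object of class `interval_partition`: a data frame with
#'   columns `lo`, `hi`, `predictor`, `length` and a list-column `ties`
#'   (co-optimal classifiers, including the winner, when the midpoint
#'   minimum is tied; empty otherwise). Attributes carry `rho` and the
#'   per-classifier `fractions` summary (total owned length).
#' @examples
#' ps <- profile_set(c("A", "B"), se = c(0.9, 0.7), sp = c(0.7, 0.9))
#' partition_interval(ps, rho = 0.5)
#' @export
partition_interval <- function(profiles, rho, tol = 1e-12) {
  profiles <- as_profile_set(profiles)
  rho <- .check_rho(rho)
  if (nrow(profiles) < 1L) stop("need at least one classifier profile")

  cuts <- .misc_crossings(profiles, rho)
  bounds <- c(0, sort(cuts), 1)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  cost <- .misc_cost_matrix(profiles, rho, mids)
  winner <- max.col(-cost, ties.method = "first")
  ties <- lapply(seq_along(mids), function(r) {
    tied <- which(cost[r, ] <= cost[r, winner[r]] + tol)
    if (length(tied) > 1L) profiles$name[tied] else character(0)
  })

  # Step 4: unify adjacent intervals with the same winner.
  keep <- c(TRUE, winner[-1] != winner[-length(winner)])
  grp <- cumsum(keep)
  lo <- tapply(bounds[-length(bounds)], grp, min)
  hi <- tapply(bounds[-1], grp, max)
  wpred <- profiles$name[winner[keep]]
  gties <- lapply(split(ties, grp), function(tt) {
    sort(unique(unlist(tt)))
  })

  out <- data.frame(lo = as.numeric(lo), hi = as.numeric(hi),
                    predictor = wpred, stringsAsFactors = FALSE)
  out$length <- out$hi - out$lo
  out$ties <- I(unname(gties))
  fractions <- tapply(out$length, out$predictor, sum)
  fractions <- stats::setNames(as.numeric(fractions), names(fractions))
  structure(out,
            class = c("interval_partition", "data.frame"),
            rho = rho, fractions = fractions)
}

# All pairwise crossing values strictly inside (0, 1), de-duplicated
# (exactly, via integer-ratio comparison, when the inputs are exact
# decimals; within tol otherwise).
.misc_crossings <- function(profiles, rho, tol = 1e-12) {
  n <- nrow(profiles)
  if (n < 2L) return(numeric(0))
  ex <- .exact_coeffs(profiles$se, profiles$sp, profiles$alpha, rho)
  if (!is.null(ex)) {
    slope <- ex$slope; intercept <- ex$intercept
  } else {
    k <- .misc_coeffs(profiles, rho)
    slope <- k$slope; intercept <- k$intercept
  }
  ij <- utils::combn(n, 2L)
  ds <- slope[ij[1L, ]] - slope[ij[2L, ]]
  di <- intercept[ij[2L, ]] - intercept[ij[1L, ]]
  ok <- if (!is.null(ex)) ds != 0 else abs(ds) > 1e-15
  x <- di[ok] / ds[ok]
  # open interval: crossings exactly at 0 or 1 are discarded
  inside <- x > 0 & x < 1
  x <- x[inside]
  if (length(x) == 0L) return(numeric(0))
  if (!is.null(ex)) {
    num <- di[ok][inside]; den <- ds[ok][inside]
    o <- order(x)
    x <- x[o]; num <- num[o]; den <- den[o]
    keep <- rep(TRUE, length(x))
    for (r in seq_along(x)[-1]) {
      eq <- .ratio_equal(num[r - 1], den[r - 1], num[r], den[r])
      if (is.na(eq)) eq <- abs(x[r] - x[r - 1]) <= tol
      if (eq) keep[r] <- FALSE
    }
    x[keep]
  } else {
    x <- sort(x)
    x[c(TRUE, diff(x) > tol)]
  }
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("Clinical-space partition, misclassification-only model (rho = ",
      attr(x, "rho"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$ties <- vapply(df$ties, function(t) paste(t, collapse = ","), "")
  print(df, row.names = FALSE, ...)
  fr <- attr(x, "fractions")
  cat("Fraction of clinical scenarios owned:\n")
  for (nm in names(sort(fr, decreasing = TRUE))) {
    cat(sprintf("  %-20s %6.1f%%\n", nm, 100 * fr[[nm]]))
  }
  invisible(x)
}

#' Per-classifier fractions of the clinical space
#'
#' @param x an [interval_partition()] or [partition_triangle()] result.
#' @return Named numeric vector: fraction of clinical scenarios where each
#'   classifier is cost-optimal (classifiers owning nothing are absent).
#' @export
scenario_fractions <- function(x) {
  UseMethod("scenario_fractions")
}

#' @export
scenario_fractions.interval_partition <- function(x) {
  attr(x, "fractions")
}
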