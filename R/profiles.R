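#' Build a set of classifier performance profiles
#'
#' A profile set is the atomic input of the cost framework: one row per
#' classifier with its sensitivity `se`, specificity `sp` and coverage
#' `alpha` (the fraction of inputs for which the classifier emits a call;
#' rejection rate = `1 - alpha`).
#'
#' @param name character vector of unique classifier identifiers.
#' @param se sensitivities, in \[0, 1\].
#' @param sp specificities, in \[0, 1\].
#' @param alpha coverages, in (0, 1\] (under the misclassification-only model
#'   coverage is ignored and treated as 1). `alpha = 0` (everything rejected)
#'   is accepted so that degenerate classifiers can still be compared under
#'   the rejection model.
#' @return A data frame of class `profile_set` with columns
#'   `name`, `se`, `sp`, `alpha`.
#' @examples
#' profile_set(c("A", "B"), se = c(0.9, 0.7), sp = c(0.7, 0.9))
#' @export
profile_set <- function(name, se, sp, alpha = rep(1, length(name))) {
  name <- as.character(name)
  stopifnot(length(name) == length(se), length(se) == length(sp),
            length(sp) == length(alpha))
  if (anyDuplicated(name)) {
    stop("duplicate classifier names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  .check_fraction(se, "se")
  .check_fraction(sp, "sp")
  .check_fraction(alpha, "alpha")
  out <- data.frame(name = name, se = as.numeric(se), sp = as.numeric(sp),
                    alpha = as.numeric(alpha), stringsAsFactors = FALSE)
  class(out) <- c("profile_set", "data.frame")
  out
}

#' Build a single classifier profile
#'
#' Convenience wrapper around [profile_set()] for one classifier.
#'
#' @inheritParams profile_set
#' @return A one-row `profile_set`.
#' @examples
#' predictor_profile("REVEL", se = 0.92, sp = 0.94)
#' @export
predictor_profile <- function(name, se, sp, alpha = 1) {
  profile_set(name, se, sp, alpha)
}

.check_fraction <- function(x, what, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric")
  }
  if (any(x < lo | x > hi)) {
    stop(what, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

#' Coerce a profile-like object into a profile set
#'
#' Accepts a `profile_set` (returned unchanged) or any data frame with
#' `name`, `se`/`sensitivity`, `sp`/`specificity` and optional
#' `alpha`/`coverage` columns.
#'
#' @param x object to coerce.
#' @return A validated [profile_set()].
#' @export
as_profile_set <- function(x) {
  if (inherits(x, "profile_set")) return(x)
  if (is.data.frame(x)) {
    cols <- names(x)
    nm <- if ("name" %in% cols) x$name else stop("profile table needs a 'name' column")
    se <- if ("se" %in% cols) x$se else x$sensitivity
    sp <- if ("sp" %in% cols) x$sp else x$specificity
    al <- if ("alpha" %in% cols) x$alpha else if ("coverage" %in% cols) x$coverage else rep(1, nrow(x))
    if (is.null(se) || is.null(sp)) stop("profile table needs se/sensitivity and sp/specificity columns")
    return(profile_set(nm, se, sp, al))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a profile set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Classifier profile set (", nrow(x), " classifier",
      if (nrow(x) != 1) "s", ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# Validate a prevalence value.
.check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho <= 0 || rho >= 1) {
    stop("rho (pathogenic-variant frequency) must be a single number in (0, 1)")
  }
  as.numeric(rho)
}
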