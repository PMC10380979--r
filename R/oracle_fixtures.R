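# Independent verification oracle (Monte-Carlo winner counting) and
# synthetic-data generators. The oracle never touches the geometric
# partition code: it samples scenarios, evaluates the cost formulas
# directly and counts winners, which makes it a brute-force cross-check
# for the interval and triangle partitions.

#' Monte-Carlo winner fractions across the clinical space
#'
#' Samples clinical scenarios uniformly (rc1 on (0, 1) for the
#' misclassification model; (rc0, rc1) uniformly on the triangle T for the
#' rejection model), evaluates every classifier's normalized cost at each
#' sample and counts, per classifier, the fraction of samples where it has
#' the minimal cost (ties broken by input order, mirroring the partition's
#' tie-break).
#'
#' @param profiles a [profile_set()].
#' @param rho pathogenic-variant frequency in (0, 1).
#' @param model `"misc"` or `"miscrej"`.
#' @param n_samples number of sampled scenarios.
#' @param seed integer seed; the result is reproducible given the seed.
#' @return An object of class `oracle_estimate`: list with named
#'   `fractions` (one entry per classifier, summing to 1), `n_samples`,
#'   `model`, `rho`, `seed`.
#' @examples
#' ps <- profile_set(c("A", "B"), se = c(0.9, 0.7), sp = c(0.7, 0.9))
#' oracle_fractions(ps, 0.5, "misc", n_samples = 1e4, seed = 1)
#' @export
oracle_fractions <- function(profiles, rho, model = c("miscrej", "misc"),
                             n_samples = 1e6, seed = 1L) {
  profiles <- as_profile_set(profiles)
  rho <- .check_rho(rho)
  model <- match.arg(model)
  stopifnot(n_samples >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (model == "misc") {
    rc1 <- stats::runif(n_samples)
    cost <- .misc_cost_matrix(profiles, rho, rc1)
  } else {
    pts <- sample_triangle(n_samples)
    cost <- .miscrej_cost_matrix(profiles, rho, pts[, 1], pts[, 2])
  }
  win <- max.col(-cost, ties.method = "first")
  counts <- tabulate(win, nbins = nrow(profiles))
  structure(list(fractions = stats::setNames(counts / n_samples, profiles$name),
                 n_samples = n_samples, model = model, rho = rho, seed = seed),
            class = "oracle_estimate")
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat("Monte-Carlo winner fractions (", x$model, ", rho = ", x$rho,
      ", n = ", format(x$n_samples, scientific = FALSE),
      ", seed = ", x$seed, ")\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Uniform samples on the clinical triangle
#'
#' Draws points uniformly on T = \{rc0, rc1 >= 0, rc0 + rc1 <= 1\} by the
#' square-fold construction: sample the unit square and reflect points with
#' `rc0 + rc1 > 1` through the center of the hypotenuse. Rejection-free and
#' exactly uniform.
#'
#' @param n number of points.
#' @return An n x 2 matrix of (rc0, rc1).
#' @export
sample_triangle <- function(n) {
  u <- stats::runif(n); v <- stats::runif(n)
  fold <- u + v > 1
  u[fold] <- 1 - u[fold]
  v[fold] <- 1 - v[fold]
  cbind(rc0 = u, rc1 = v)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate random classifier profiles
#'
#' Draws `n` synthetic classifier profiles with independent uniform
#' sensitivities, specificities and coverages. The default ranges emulate
#' realistic pathogenicity predictors: accuracies above chance
#' (se, sp in (0.5, 1)) and moderate-to-full coverage (alpha in (0.4, 1),
#' spanning the coverage range reported for published predictors).
#'
#' @param n number of profiles.
#' @param seed integer seed.
#' @param se_range,sp_range,alpha_range sampling ranges, subsets of (0, 1\].
#' @return A [profile_set()] with names `P01`, `P02`, ...
#' @export
generate_profiles <- function(n, seed = 1L,
                              se_range = c(0.5, 1),
                              sp_range = c(0.5, 1),
                              alpha_range = c(0.4, 1)) {
  stopifnot(n >= 0)
  for (r in list(se_range, sp_range, alpha_range)) {
    stopifnot(length(r) == 2L, r[1] <= r[2], r[1] >= 0, r[2] <= 1)
  }
  if (n == 0L) {
    return(profile_set(character(0), numeric(0), numeric(0), numeric(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  profile_set(sprintf("P%02d", seq_len(n)),
              se = stats::runif(n, se_range[1], se_range[2]),
              sp = stats::runif(n, sp_range[1], sp_range[2]),
              alpha = stats::runif(n, alpha_range[1], alpha_range[2]))
}

#' Generate a synthetic labeled prediction table
#'
#' Emulates the statistical structure of a curated variant benchmark: true
#' labels are drawn with pathogenic frequency `rho`; for each classifier a
#' variant is accepted with probability `alpha` and, if accepted, called
#' correctly with probability `se` (pathogenic variants) or `sp` (benign
#' variants); unaccepted variants are `rejected`. Estimating profiles from
#' the output recovers the generating parameters up to binomial noise.
#'
#' @param n_variants number of rows.
#' @param rho pathogenic fraction, in (0, 1).
#' @param profiles_truth a [profile_set()] of generating parameters.
#' @param seed integer seed.
#' @return A data frame with columns `variant_id`, `label` and one
#'   `<name>_call` column per classifier (values `pathogenic`, `benign`,
#'   `rejected`).
#' @export
generate_labeled_table <- function(n_variants, rho, profiles_truth, seed = 1L) {
  profiles_truth <- as_profile_set(profiles_truth)
  rho <- .check_rho(rho)
  stopifnot(n_variants >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  label <- ifelse(stats::runif(n_variants) < rho, "pathogenic", "benign")
  out <- data.frame(variant_id = sprintf("v%06d", seq_len(n_variants)),
                    label = label, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profiles_truth))) {
    p <- profiles_truth[i, ]
    accepted <- stats::runif(n_variants) < p$alpha
    p_correct <- ifelse(label == "pathogenic", p$se, p$sp)
    correct <- stats::runif(n_variants) < p_correct
    call <- ifelse(!accepted, "rejected",
                   ifelse(correct, label,
                          ifelse(label == "pathogenic", "benign", "pathogenic")))
    out[[paste0(p$name, "_call")]] <- call
  }
  out
}
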