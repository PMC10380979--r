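# Estimation of (se, sp, alpha) from labeled prediction tables, and
# plug-in score-rejection rules.
#
#   se    = TP / Np      (covered pathogenic variants only)
#   sp    = TN / Nb      (covered benign variants only)
#   alpha = N  / N_tot   (covered / all rows)
#
# Error rates are conditional on acceptance: the rejection-model cost
# multiplies them by alpha separately, so counting rejected variants in the
# denominators would double-count rejection.

#' Plug-in score-rejection rule
#'
#' Converts a continuous prediction score into calls with a rejection band:
#' scores strictly between the two thresholds are rejected, scores at or
#' beyond them are called (e.g. REVEL calls with scores between 0.249 and
#' 0.733 discarded under the ClinGen ATM guideline). Band-boundary scores
#' are called by default; set `inclusive = FALSE` to reject them instead.
#'
#' @param benign_max highest score still called benign
#'   (`higher_is_pathogenic` orientation).
#' @param pathogenic_min lowest score called pathogenic.
#' @param orientation `"higher_is_pathogenic"` (default) or
#'   `"lower_is_pathogenic"`. Under the latter, `pathogenic_min` is the
#'   highest score still called pathogenic and `benign_max` the lowest score
#'   called benign (the axis is reversed), and `pathogenic_min <= benign_max`
#'   is required.
#' @param inclusive call scores equal to a threshold (default TRUE).
#' @return An object of class `plugin_rule`.
#' @examples
#' plugin_rule(benign_max = 0.249, pathogenic_min = 0.733)
#' @export
plugin_rule <- function(benign_max, pathogenic_min,
                        orientation = c("higher_is_pathogenic",
                                        "lower_is_pathogenic"),
                        inclusive = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(benign_max), is.numeric(pathogenic_min),
            length(benign_max) == 1L, length(pathogenic_min) == 1L,
            is.finite(benign_max), is.finite(pathogenic_min))
  if (orientation == "higher_is_pathogenic" && benign_max > pathogenic_min) {
    stop("benign_max must not exceed pathogenic_min")
  }
  if (orientation == "lower_is_pathogenic" && pathogenic_min > benign_max) {
    stop("pathogenic_min must not exceed benign_max")
  }
  structure(list(benign_max = benign_max, pathogenic_min = pathogenic_min,
                 orientation = orientation, inclusive = inclusive),
            class = "plugin_rule")
}

#' @export
print.plugin_rule <- function(x, ...) {
  cat("Plug-in rule (", x$orientation, "): benign ",
      if (x$orientation == "higher_is_pathogenic") "<=" else ">=", " ",
      x$benign_max, ", pathogenic ",
      if (x$orientation == "higher_is_pathogenic") ">=" else "<=", " ",
      x$pathogenic_min, ", scores between rejected",
      if (!x$inclusive) " (thresholds rejected too)", "\n", sep = "")
  invisible(x)
}

#' Apply a plug-in rule to prediction scores
#'
#' @param scores numeric scores; `NA` scores yield `rejected` (a missing
#'   prediction counts as a rejection).
#' @param rule a [plugin_rule()].
#' @return Character vector of calls: `pathogenic`, `benign` or `rejected`.
#' @examples
#' r <- plugin_rule(0.249, 0.733)
#' apply_plugin_rule(c(0.10, 0.50, 0.80), r)
#' @export
apply_plugin_rule <- function(scores, rule) {
  stopifnot(inherits(rule, "plugin_rule"))
  if (length(scores) == 0L) return(character(0))
  if (any(!is.finite(scores) & !is.na(scores))) {
    stop("scores must be finite or NA")
  }
  s <- if (rule$orientation == "higher_is_pathogenic") scores else -scores
  bmax <- if (rule$orientation == "higher_is_pathogenic") rule$benign_max else -rule$benign_max
  pmin_ <- if (rule$orientation == "higher_is_pathogenic") rule$pathogenic_min else -rule$pathogenic_min
  out <- rep("rejected", length(scores))
  if (rule$inclusive) {
    out[!is.na(s) & s <= bmax] <- "benign"
    out[!is.na(s) & s >= pmin_] <- "pathogenic"
  } else {
    out[!is.na(s) & s < bmax] <- "benign"
    out[!is.na(s) & s > pmin_] <- "pathogenic"
  }
  out
}

#' Estimate a classifier profile from a labeled prediction table
#'
#' Computes `(se, sp, alpha)` and the underlying confusion counts for one
#' classifier column of a labeled table. Call columns (`<name>_call`) are
#' used directly; score columns (`<name>_score`) require a [plugin_rule()].
#' Missing entries count as rejected. Sensitivity and specificity are
#' conditional on acceptance; coverage is `N / N_tot`.
#'
#' @param table a labeled prediction table: data frame with `variant_id`,
#'   `label` (`pathogenic`/`benign`) and per-classifier `<name>_call` or
#'   `<name>_score` columns (see [read_labeled_table()]).
#' @param predictor classifier name (column prefix).
#' @param rule optional [plugin_rule()]; required for score columns.
#' @return List with `profile` (one-row [profile_set()]; `se`/`sp` are `NA`
#'   when no covered variant of the class exists), `counts` (list: TP, TN,
#'   FP, FN, Np, Nb, N, N_tot, rejected) and `flags` (character vector
#'   naming degeneracies: `"all_rejected"`, `"no_covered_pathogenic"`,
#'   `"no_covered_benign"`).
#' @export
estimate_profile <- function(table, predictor, rule = NULL) {
  stopifnot(is.data.frame(table))
  if (!all(c("variant_id", "label") %in% names(table))) {
    stop("labeled table needs 'variant_id' and 'label' columns")
  }
  if (anyNA(table$label) || !all(table$label %in% c("pathogenic", "benign"))) {
    stop("label must be 'pathogenic' or 'benign' with no missing values")
  }
  call_col <- paste0(predictor, "_call")
  score_col <- paste0(predictor, "_score")
  if (call_col %in% names(table)) {
    call <- as.character(table[[call_col]])
    call[is.na(call)] <- "rejected"
    bad <- !call %in% c("pathogenic", "benign", "rejected")
    if (any(bad)) {
      stop("invalid call value(s) for ", predictor, " at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
  } else if (score_col %in% names(table)) {
    if (is.null(rule)) {
      stop("classifier ", predictor, " has scores; a plugin_rule is required")
    }
    call <- apply_plugin_rule(as.numeric(table[[score_col]]), rule)
  } else {
    stop("no column '", call_col, "' or '", score_col, "' in table")
  }

  n_tot <- nrow(table)
  pathog <- table$label == "pathogenic"
  covered <- call != "rejected"
  TP <- sum(covered & pathog & call == "pathogenic")
  FN <- sum(covered & pathog & call == "benign")
  TN <- sum(covered & !pathog & call == "benign")
  FP <- sum(covered & !pathog & call == "pathogenic")
  Np <- TP + FN
  Nb <- TN + FP
  N <- Np + Nb
  alpha <- if (n_tot > 0) N / n_tot else 0

  flags <- character(0)
  if (n_tot > 0 && N == 0) flags <- c(flags, "all_rejected")
  if (Np == 0) flags <- c(flags, "no_covered_pathogenic")
  if (Nb == 0) flags <- c(flags, "no_covered_benign")
  se <- if (Np > 0) TP / Np else NA_real_
  sp <- if (Nb > 0) TN / Nb else NA_real_

  profile <- data.frame(name = predictor, se = se, sp = sp, alpha = alpha,
                        stringsAsFactors = FALSE)
  if (!anyNA(profile[, c("se", "sp")])) {
    profile <- profile_set(predictor, se, sp, alpha)
  } else {
    class(profile) <- c("profile_set", "data.frame")
  }
  list(profile = profile,
       counts = list(TP = TP, TN = TN, FP = FP, FN = FN,
                     Np = Np, Nb = Nb, N = N, N_tot = n_tot,
                     rejected = n_tot - N),
       flags = flags)
}

#' Estimate profiles for every classifier in a labeled table
#'
#' @inheritParams estimate_profile
#' @param rules named list of [plugin_rule()]s (one per score classifier),
#'   e.g. from [read_rules()].
#' @return A [profile_set()] with one row per classifier column; classifiers
#'   with undefined rates are kept with `NA` entries and reported via the
#'   `flags` attribute.
#' @export
estimate_profiles <- function(table, rules = list()) {
  cols <- names(table)
  preds <- sub("_(call|score)$", "",
               grep("_(call|score)$", cols, value = TRUE))
  if (length(preds) == 0L) stop("no classifier columns ('<name>_call'/'<name>_score') found")
  ests <- lapply(preds, function(p) {
    estimate_profile(table, p, rule = rules[[p]])
  })
  out <- do.call(rbind, lapply(ests, function(e) as.data.frame(e$profile)))
  class(out) <- c("profile_set", "data.frame")
  flags <- lapply(ests, `[[`, "flags")
  names(flags) <- preds
  attr(out, "flags") <- Filter(length, flags)
  out
}
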