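# Readers/writers and the analysis driver. CSV vs TSV is auto-detected from
# the file extension (.csv -> comma, anything else -> tab); UTF-8, '.'
# decimal separator.

.sep_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a classifier profile table
#'
#' Expects a header `name,sensitivity,specificity,coverage` (the `coverage`
#' column is optional and defaults to 1, the misclassification-only
#' convention). Out-of-range values are rejected with the offending row
#' number.
#'
#' @param path CSV or TSV file.
#' @return A [profile_set()].
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("name", "sensitivity", "specificity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("profile table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(profile_set(character(0), numeric(0), numeric(0), numeric(0)))
  }
  if (!"coverage" %in% names(df)) df$coverage <- 1
  for (col in c("sensitivity", "specificity", "coverage")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad)) {
      stop("invalid ", col, " value ", v[bad[1]], " at data row ", bad[1],
           " of ", path)
    }
  }
  profile_set(df$name, df$sensitivity, df$specificity, df$coverage)
}

#' Write a classifier profile table
#'
#' @param profiles a [profile_set()].
#' @param path output CSV/TSV path (dialect from extension).
#' @export
write_profiles <- function(profiles, path) {
  profiles <- as_profile_set(profiles)
  out <- data.frame(name = profiles$name, sensitivity = profiles$se,
                    specificity = profiles$sp, coverage = profiles$alpha)
  utils::write.table(out, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled prediction table
#'
#' One row per variant: columns `variant_id`, `label`
#' (`pathogenic`/`benign`), then per classifier either `<name>_call`
#' (`pathogenic`/`benign`/`rejected`) or `<name>_score` (numeric). A
#' classifier column must be all-calls or all-scores, never mixed.
#'
#' @param path CSV or TSV file.
#' @return The validated data frame.
#' @export
read_labeled_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("variant_id", "label") %in% names(df))) {
    stop("labeled table ", path, " needs 'variant_id' and 'label' columns")
  }
  bad <- which(is.na(df$label) | !df$label %in% c("pathogenic", "benign"))
  if (length(bad)) {
    stop("invalid label '", df$label[bad[1]], "' at data row ", bad[1],
         " of ", path)
  }
  df
}

#' Write a labeled prediction table
#'
#' @param table data frame as produced by [generate_labeled_table()].
#' @param path output CSV/TSV path.
#' @export
write_labeled_table <- function(table, path) {
  utils::write.table(table, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read plug-in rules from JSON
#'
#' Expects a JSON array of objects
#' `{predictor, benign_max, pathogenic_min, orientation}` (orientation
#' optional, default `higher_is_pathogenic`).
#'
#' @param path JSON file.
#' @return Named list of [plugin_rule()]s.
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$predictor)) raw <- list(raw)  # single object
  rules <- lapply(raw, function(r) {
    plugin_rule(r$benign_max, r$pathogenic_min,
                orientation = if (is.null(r$orientation))
                  "higher_is_pathogenic" else r$orientation,
                inclusive = if (is.null(r$inclusive)) TRUE else r$inclusive)
  })
  names(rules) <- vapply(raw, `[[`, "", "predictor")
  rules
}

# --- analysis driver --------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the inputs of a full analysis run. Exactly one input mode is
#' used: a profile table (`profiles`) or a labeled table (`table`, with
#' optional `rules`) from which profiles are estimated first.
#'
#' @param model `"misc"` or `"miscrej"`.
#' @param rho prevalence value, or a vector for a sweep.
#' @param profiles a [profile_set()] or path to a profile table.
#' @param table a labeled table data frame or path.
#' @param rules named list of [plugin_rule()]s or path to a rules JSON.
#' @param group_size optional group size for [partition_grouped()].
#' @param seed integer seed echoed in reports (used by oracle verification).
#' @param tol tie tolerance.
#' @return A `run_config` list.
#' @export
run_config <- function(model = c("miscrej", "misc"), rho = 0.5,
                       profiles = NULL, table = NULL, rules = NULL,
                       group_size = NULL, seed = 1L, tol = 1e-12) {
  model <- match.arg(model)
  if (is.null(profiles) == is.null(table)) {
    stop("exactly one input mode: give 'profiles' or 'table'")
  }
  for (r in rho) .check_rho(r)
  structure(list(model = model, rho = rho, profiles = profiles,
                 table = table, rules = rules, group_size = group_size,
                 seed = as.integer(seed), tol = tol),
            class = "run_config")
}

#' Run a full clinical-space analysis
#'
#' Resolves the configured inputs (reading and estimating as needed), runs
#' the partition for each requested prevalence value and returns a
#' JSON-serializable report: the partition(s), per-classifier scenario
#' fractions, the echoed inputs, tolerances, package version and seed. The
#' report is deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @param out optional path; when given the report is also written as JSON.
#' @return The report, invisibly when `out` is given.
#' @export
run_analysis <- function(config, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  profiles <- config$profiles
  rules <- config$rules
  if (is.character(rules)) rules <- read_rules(rules)
  if (is.null(profiles)) {
    table <- config$table
    if (is.character(table)) table <- read_labeled_table(table)
    profiles <- estimate_profiles(table, rules = if (is.null(rules)) list() else rules)
    if (anyNA(profiles$se) || anyNA(profiles$sp)) {
      stop("undefined se/sp for classifier(s): ",
           paste(profiles$name[is.na(profiles$se) | is.na(profiles$sp)],
                 collapse = ", "))
    }
  } else if (is.character(profiles)) {
    profiles <- read_profiles(profiles)
  } else {
    profiles <- as_profile_set(profiles)
  }

  partitions <- lapply(config$rho, function(r) {
    if (config$model == "misc") {
      part <- partition_interval(profiles, r, tol = config$tol)
      list(rho = r,
           intervals = lapply(seq_len(nrow(part)), function(i) {
             list(lo = part$lo[i], hi = part$hi[i],
                  predictor = part$predictor[i], length = part$length[i],
                  ties = part$ties[[i]])
           }),
           fractions = as.list(scenario_fractions(part)))
    } else {
      part <- if (!is.null(config$group_size) &&
                  nrow(profiles) > config$group_size) {
        partition_grouped(profiles, r, group_size = config$group_size,
                          tol = config$tol)
      } else {
        partition_triangle(profiles, r, tol = config$tol)
      }
      list(rho = r,
           regions = lapply(seq_len(nrow(part$summary)), function(i) {
             pred <- part$summary$predictor[i]
             list(predictor = pred,
                  area = part$summary$area[i],
                  fraction = part$summary$fraction[i],
                  polygons = lapply(part$regions[[pred]], function(p) {
                    m <- p[, 1:2, drop = FALSE]
                    dimnames(m) <- list(NULL, c("rc0", "rc1"))
                    m
                  }))
           }),
           fractions = as.list(scenario_fractions(part)),
           ties = part$ties)
    }
  })

  report <- list(
    software = "costspace",
    version = as.character(utils::packageVersion("costspace")),
    model = config$model,
    rho = config$rho,
    seed = config$seed,
    tolerance = config$tol,
    group_size = config$group_size,
    profiles = as.data.frame(profiles),
    partitions = partitions
  )
  if (!is.null(out)) {
    write_report(report, out)
    return(invisible(report))
  }
  report
}

#' Write an analysis report as JSON
#'
#' @param report a [run_analysis()] report (or any JSON-serializable list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Sweep the prevalence parameter
#'
#' Partitions the clinical space at each prevalence value and collects the
#' per-classifier scenario fractions into a matrix, making transitions of
#' the cost-optimal classifier visible as `rho` varies.
#'
#' @param profiles a [profile_set()].
#' @param rho_values numeric vector of prevalence values in (0, 1).
#' @param model `"misc"` or `"miscrej"`.
#' @param tol tie tolerance.
#' @return List with `fractions` (matrix: rows = rho values, columns =
#'   classifiers) and `partitions` (one partition object per rho).
#' @export
sweep_rho <- function(profiles, rho_values, model = c("miscrej", "misc"),
                      tol = 1e-12) {
  profiles <- as_profile_set(profiles)
  model <- match.arg(model)
  parts <- lapply(rho_values, function(r) {
    if (model == "misc") partition_interval(profiles, r, tol = tol)
    else partition_triangle(profiles, r, tol = tol)
  })
  frac <- matrix(0, nrow = length(rho_values), ncol = nrow(profiles),
                 dimnames = list(format(rho_values), profiles$name))
  for (i in seq_along(parts)) {
    f <- scenario_fractions(parts[[i]])
    frac[i, names(f)] <- f
  }
  list(fractions = frac, partitions = parts, rho = rho_values, model = model)
}
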