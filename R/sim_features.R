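#' Simulate a labeled feature table from cohort statistics
#'
#' Draws each participant's variables independently from the class-conditional
#' Gaussian (mean, sd) of the cohort cell named in the composition row —
#' exactly the independence assumption of the downstream naive Bayes
#' classifier. Variables with a bounded native range (relative power and ITPC
#' lie in [0, 1]) are clipped to the bound; [clipped_normal_mean()] gives the
#' resulting exact expectation. Deterministic under a fixed seed.
#'
#' @param stats a cohort statistics tibble as returned by [cohort_stats()],
#'   or any tibble with columns `variable`, `cohort`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @param composition tibble with columns `group`, `sex`, `mosaic`, `n`,
#'   `cohort` (see [default_composition()]); every `cohort` value must be
#'   present in `stats` for every variable.
#' @param seed integer seed.
#' @param variables optional character vector restricting/ordering the
#'   simulated variables (default: all variables in `stats`).
#' @return a tibble (`FeatureTable`): columns `participant`, `group`, `sex`,
#'   `mosaic`, then one numeric column per variable.
#' @export
#' @examples
#' tab <- simulate_feature_table(cohort_stats("alphapeak"),
#'                               default_composition("rest"), seed = 1)
#' dplyr::count(tab, group, sex)
simulate_feature_table <- function(stats, composition = default_composition("rest"),
                                   seed = 1L, variables = NULL) {
  stopifnot(all(c("variable", "cohort", "mean", "sd") %in% names(stats)),
            all(c("group", "sex", "mosaic", "n", "cohort") %in% names(composition)))
  if (is.null(stats$lower)) stats$lower <- -Inf
  if (is.null(stats$upper)) stats$upper <- Inf
  if (any(stats$sd < 0)) stop_fx("negative sd in cohort statistics")
  if (any(composition$n < 0)) stop_fx("negative subgroup count in composition")
  variables <- variables %||% unique(stats$variable)

  for (v in variables) {
    for (ch in unique(composition$cohort)) {
      if (!any(stats$variable == v & stats$cohort == ch))
        stop_fx("no statistics for variable '%s' in cohort '%s'", v, ch)
    }
  }

  set.seed(seed)
  rows <- vector("list", nrow(composition))
  pid <- 0L
  for (i in seq_len(nrow(composition))) {
    ni <- composition$n[i]
    if (ni == 0L) next
    cell <- stats[stats$cohort == composition$cohort[i], ]
    cell <- cell[match(variables, cell$variable), ]
    draws <- matrix(stats::rnorm(ni * length(variables)), nrow = ni)
    draws <- sweep(sweep(draws, 2, cell$sd, `*`), 2, cell$mean, `+`)
    for (j in seq_along(variables))
      draws[, j] <- clip(draws[, j], cell$lower[j], cell$upper[j])
    colnames(draws) <- variables
    rows[[i]] <- tibble::tibble(
      participant = sprintf("S%04d", pid + seq_len(ni)),
      group  = composition$group[i],
      sex    = composition$sex[i],
      mosaic = composition$mosaic[i],
      tibble::as_tibble(draws)
    )
    pid <- pid + ni
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  out
}

#' Write / read a feature table as delimited text
#'
#' CSV with a header row: `participant`, `group`, `sex`, `mosaic`, then one
#' column per EEG variable, named exactly as the study's report row labels
#' (e.g. `"Frontal Theta"`, `"Low Gamma ITPC"`).
#'
#' @param table a feature table.
#' @param path file path.
#' @return `read_feature_table` returns the tibble; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$mosaic <- as.logical(df$mosaic)
  tibble::as_tibble(df)
}
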