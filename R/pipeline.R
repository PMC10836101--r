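# Study orchestration: a-priori variable-set enumeration, diagnostic-group
# and subgroup classification, dense-array to clinical montage reduction,
# and the consolidated report.

.family_task <- c(absolute = "rest", relative = "rest",
                  alphapeak = "rest", chirp = "chirp")

#' Enumerate the a-priori variable sets of a task family
#'
#' Resting absolute and relative power each yield 25 sets (per region: an
#' "all variables" combination plus the 7 single bands; plus the 21-variable
#' grand combination); alpha peak yields 4 (three regions plus their
#' combination); chirp yields 11 (7 singles, all ITPC, all power, the
#' gamma-power / low-gamma-ITPC pair, and all 7 combined). Set names match
#' the report row labels; members are the bare variable labels of the
#' family's feature namespace.
#'
#' @param family `"absolute"`, `"relative"`, `"alphapeak"` or `"chirp"`
#'   (the `rest-` prefixed forms are accepted).
#' @return named list of character vectors, in report row order.
#' @export
build_variable_sets <- function(family) {
  family <- sub("^rest-", "", family)
  if (!family %in% names(.family_task)) stop_fx("unknown task family '%s'", family)
  if (family %in% c("absolute", "relative")) {
    sets <- list()
    for (r in .region_labels) {
      sets[[sprintf("All %s Variables", r)]] <- paste(r, .band_labels)
      for (b in .band_labels) sets[[paste(r, b)]] <- paste(r, b)
    }
    sets[["All Variables"]] <- as.vector(t(outer(.region_labels, .band_labels, paste)))
    return(sets)
  }
  if (family == "alphapeak") {
    sets <- stats::setNames(as.list(.region_labels), .region_labels)
    sets[["All Variables"]] <- .region_labels
    return(sets)
  }
  itpc_vars <- grep("ITPC", .chirp_var_names, value = TRUE)
  power_vars <- setdiff(.chirp_var_names, itpc_vars)
  sets <- stats::setNames(as.list(.chirp_var_names), .chirp_var_names)
  sets[["All ITPC Variables"]] <- itpc_vars
  sets[["All Power Variables"]] <- power_vars
  sets[["Gamma Power/Low Gamma ITPC"]] <- c("Gamma Power", "Low Gamma ITPC")
  sets[["All Variables"]] <- .chirp_var_names
  sets
}

#' Restrict a feature table to a genetically mediated subgroup
#'
#' `males` and `females` keep one sex in both groups (case and control are
#' never compared across sexes); `non-mosaic-males` keeps fully methylated
#' non-mosaic FXS males versus all CON males.
#'
#' @param table feature table with `group`, `sex`, `mosaic` columns.
#' @param subgroup `"all"`, `"males"`, `"females"` or `"non-mosaic-males"`.
#' @return the filtered tibble.
#' @export
apply_subgroup <- function(table, subgroup = c("all", "males", "females",
                                               "non-mosaic-males")) {
  subgroup <- match.arg(subgroup)
  out <- switch(subgroup,
    all = table,
    males = table[table$sex == "M", , drop = FALSE],
    females = table[table$sex == "F", , drop = FALSE],
    `non-mosaic-males` = table[table$sex == "M" &
                                 (table$group != "FXS" | !table$mosaic), , drop = FALSE])
  counts <- table(factor(out$group, levels = unique(table$group)))
  if (any(counts == 0))
    stop_fx("subgroup '%s' empties class '%s'", subgroup,
            names(counts)[counts == 0][1])
  out
}

# Individual-level resting simulation parameters: draws each participant's
# oscillator amplitudes and alpha peak around the group preset.
.sample_resting_params <- function(group, seed, fs, duration, channels) {
  set.seed(seed)
  base <- resting_group_presets(group, fs = fs, duration = duration,
                                channels = channels, seed = seed + 1L)
  osc <- base$oscillations
  osc$amp <- osc$amp * exp(stats::rnorm(nrow(osc), 0, 0.25))
  alpha_f <- clip(stats::rnorm(1, base$alpha_freq, 0.4), 6.5, 12)
  resting_sim_params(channels = channels, fs = fs, duration = duration,
                     exponent = base$exponent, pink_amp = base$pink_amp,
                     oscillations = osc, alpha_freq = alpha_f,
                     alpha_amp = base$alpha_amp * exp(stats::rnorm(1, 0, 0.25)),
                     noise_amp = base$noise_amp, seed = seed + 2L)
}

#' Configuration for [run_full_study()]
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param families task families to evaluate.
#' @param top_n sets carried to subgroup analysis per family (default 2,
#'   selected by full-dataset AUC, ties broken by CV error then name).
#' @param subgroups subgroup analyses to run.
#' @param absolute_subgroups run subgroup analyses for absolute power too
#'   (skipped by default: at the diagnostic-group level absolute power is
#'   outperformed by the other resting families).
#' @param compositions list with `rest` and `chirp` composition tibbles.
#' @param stats list of cohort statistics per family (default the bundled
#'   reference statistics).
#' @param montage list: `enabled`, `n_per_group`, `duration` (s), `fs` (Hz)
#'   for the signal-level 20-channel reduction stage; omitted entries keep
#'   their defaults.
#' @return a config list.
#' @export
study_config <- function(seed = 1L,
                         families = c("absolute", "relative", "alphapeak", "chirp"),
                         top_n = 2,
                         subgroups = c("males", "females", "non-mosaic-males"),
                         absolute_subgroups = FALSE,
                         compositions = list(rest = default_composition("rest"),
                                             chirp = default_composition("chirp")),
                         stats = NULL,
                         montage = list(enabled = TRUE, n_per_group = 20,
                                        duration = 20, fs = 250)) {
  stats <- stats %||% stats::setNames(lapply(families, cohort_stats), families)
  montage <- utils::modifyList(list(enabled = TRUE, n_per_group = 20,
                                    duration = 20, fs = 250), montage)
  list(seed = as.integer(seed), families = families, top_n = top_n,
       subgroups = subgroups, absolute_subgroups = absolute_subgroups,
       compositions = compositions, stats = stats, montage = montage)
}

.rest_montage_features <- function(config) {
  mg <- config$montage
  chans <- hydrocel_working_set()
  rows <- list()
  i <- 0L
  for (grp in c("FXS", "CON")) for (p in seq_len(mg$n_per_group)) {
    i <- i + 1L
    pars <- .sample_resting_params(grp,
                                   seed = derive_seed(config$seed, sprintf("montage-%s-%d", grp, p)),
                                   fs = mg$fs, duration = mg$duration, channels = chans)
    rec <- simulate_resting_eeg(pars)
    red <- reduce_montage(rec)
    v <- resting_feature_vector(red, region_map("standard1020-20", red$labels))
    rows[[i]] <- tibble::tibble(participant = sprintf("M%03d", i), group = grp,
                                sex = "M", mosaic = FALSE, tibble::as_tibble(t(v)))
  }
  dplyr::bind_rows(rows)
}

.family_montage_columns <- function(family) {
  prefix <- c(relative = "Relative ", absolute = "Absolute ",
              alphapeak = "Alpha Peak ")[family]
  if (family == "alphapeak") {
    stats::setNames(paste0(prefix, .region_labels), .region_labels)
  } else {
    stats::setNames(paste0(prefix, .rest_var_names), .rest_var_names)
  }
}

#' Run the complete classification study on simulated cohorts
#'
#' Stage 1 evaluates every a-priori variable set of every family on the
#' full simulated cohort; stage 2 selects the top `top_n` sets per family
#' by full-dataset AUC; stage 3 re-runs those sets on the male, female and
#' non-mosaic-male subgroups (absolute power excluded by default); stage 4
#' re-runs the best resting set/subgroup on features extracted from a
#' signal-level mini-cohort reduced to the 20-channel clinical montage.
#' Every number in the report is reproducible bit-identically from the
#' config's seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `report` (tibble:
#'   `family`, `subgroup`, `variable_set`, AUCs, CV error, confusion
#'   counts, `top_set` flag, `stage`), `roc` (named list of full-dataset
#'   ROC curves for stage-1 rows), `config`.
#' @export
run_full_study <- function(config = study_config()) {
  rows <- list()
  rocs <- list()
  tables <- list()

  for (family in config$families) {
    task <- .family_task[[family]]
    tab <- simulate_feature_table(config$stats[[family]],
                                  config$compositions[[task]],
                                  seed = derive_seed(config$seed, paste0("sim-", family)))
    tables[[family]] <- tab
    sets <- build_variable_sets(family)
    for (nm in names(sets)) {
      ev <- evaluate_variable_set(tab, sets[[nm]], name = nm,
                                  seed = derive_seed(config$seed,
                                                     paste("eval", family, "all", nm)))
      rows[[length(rows) + 1L]] <- tibble::tibble(family = family, subgroup = "all",
                                                  stage = "diagnostic", ev$summary)
      rocs[[paste(family, nm, sep = " | ")]] <- ev$roc
    }
  }
  report <- dplyr::bind_rows(rows)

  # stage 2: top-n per family by full-dataset AUC; CV error then name break ties
  report$top_set <- FALSE
  top_sets <- list()
  for (family in config$families) {
    fam_rows <- report[report$family == family & report$stage == "diagnostic", ]
    ord <- order(-fam_rows$auc_full, fam_rows$cv_error, fam_rows$variable_set)
    top <- fam_rows$variable_set[ord[seq_len(min(config$top_n, nrow(fam_rows)))]]
    top_sets[[family]] <- top
    report$top_set[report$family == family & report$variable_set %in% top] <- TRUE
  }

  # stage 3: subgroup analyses for the selected sets
  sub_rows <- list()
  for (family in config$families) {
    if (family == "absolute" && !config$absolute_subgroups) next
    sets <- build_variable_sets(family)
    for (sg in config$subgroups) {
      sub_tab <- apply_subgroup(tables[[family]], sg)
      for (nm in top_sets[[family]]) {
        ev <- evaluate_variable_set(sub_tab, sets[[nm]], name = nm,
                                    seed = derive_seed(config$seed,
                                                       paste("eval", family, sg, nm)))
        sub_rows[[length(sub_rows) + 1L]] <-
          tibble::tibble(family = family, subgroup = sg, stage = "subgroup",
                         ev$summary, top_set = TRUE)
      }
    }
  }
  report <- dplyr::bind_rows(report, dplyr::bind_rows(sub_rows))

  # stage 4: 20-channel montage reduction for the best resting family rows
  if (isTRUE(config$montage$enabled)) {
    mg_families <- intersect(config$families, c("relative", "alphapeak"))
    if (length(mg_families) > 0) {
      feats <- .rest_montage_features(config)
      mg_rows <- list()
      for (family in mg_families) {
        fam_rows <- report[report$family == family, ]
        best <- fam_rows[order(-fam_rows$auc_full, fam_rows$cv_error), ][1, ]
        cols <- .family_montage_columns(family)
        members <- build_variable_sets(family)[[best$variable_set]]
        fam_tab <- feats[, c("participant", "group", "sex", "mosaic")]
        for (bare in names(cols)) fam_tab[[bare]] <- feats[[cols[[bare]]]]
        ev <- evaluate_variable_set(fam_tab, members, name = best$variable_set,
                                    seed = derive_seed(config$seed,
                                                       paste("montage", family)))
        mg_rows[[family]] <- tibble::tibble(
          family = family,
          subgroup = sprintf("%s: 20-channel montage", best$subgroup),
          stage = "montage", ev$summary, top_set = TRUE)
      }
      report <- dplyr::bind_rows(report, dplyr::bind_rows(mg_rows))
    }
  }

  structure(list(report = report, roc = rocs, top_sets = top_sets,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d rows, seed %d\n", nrow(x$report), x$config$seed))
  print(dplyr::count(x$report, family, stage), ...)
  invisible(x)
}

#' Write the consolidated study report as delimited tables
#'
#' One CSV per family with the published-style column headings (see
#' [report_column_names()]) plus subgroup, stage and seed columns, and a
#' plain-text run manifest echoing the master seed for reproducibility.
#'
#' @param study a [run_full_study()] result.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_study_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cn <- report_column_names()
  paths <- character(0)
  for (family in unique(study$report$family)) {
    out <- study$report[study$report$family == family, ]
    exp <- tibble::tibble(out["subgroup"], out["stage"])
    for (ic in names(cn)) exp[[cn[[ic]]]] <- out[[ic]]
    exp$Seed <- out$seed
    exp$`Top Set` <- out$top_set
    p <- file.path(dir, sprintf("report_%s.csv", family))
    utils::write.csv(exp, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(sprintf("seed: %d", study$config$seed),
               sprintf("families: %s", paste(study$config$families, collapse = ", ")),
               sprintf("subgroups: %s", paste(study$config$subgroups, collapse = ", ")),
               sprintf("montage stage: %s", isTRUE(study$config$montage$enabled)),
               sprintf("package version: %s",
                       as.character(utils::packageVersion("fxseeg")))),
             manifest)
  invisible(c(paths, manifest))
}
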