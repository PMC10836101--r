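# Bundled reference cohort summary statistics.
#
# Group-level means and standard deviations of every EEG variable, by
# diagnostic group (FXS / CON) and by genetically mediated subgroup
# (males, females, non-mosaic fully methylated males), for a large published
# FXS-vs-control cohort: resting absolute band power (picovolt scale),
# resting relative band power (proportion of total analyzed power),
# resting peak alpha frequency (Hz), and auditory-chirp time-frequency
# variables (log power in dB re microvolt^2; ITPC in [0,1]).
#
# These are the generative parameters of the feature-level simulator: each
# simulated participant draws each variable from the class-conditional
# Gaussian of its cohort cell.

.cohort_cols <- c("fxs", "con", "fxs_male", "fxs_female",
                  "fxs_nonmosaic_male", "con_male", "con_female")

.rest_n  <- c(fxs = 70L, con = 71L, fxs_male = 38L, fxs_female = 32L,
              fxs_nonmosaic_male = 27L, con_male = 41L, con_female = 30L)
.chirp_n <- c(fxs = 57L, con = 57L, fxs_male = 37L, fxs_female = 20L,
              fxs_nonmosaic_male = 26L, con_male = 34L, con_female = 23L)

.band_labels   <- c("Delta", "Theta", "Alpha 1", "Alpha 2", "Beta", "Gamma 1", "Gamma 2")
.region_labels <- c("Frontal", "Posterior", "Whole Head")

.rest_var_names <- as.vector(t(outer(.region_labels, .band_labels, paste)))

# columns: mean,sd x (fxs, con, fxs_male, fxs_female, fxs_nonmosaic_male, con_male, con_female)
.abs_cells <- matrix(c(
  3.45, 2.96, 2.15, 1.74, 4.13, 3.44, 2.65, 2.04, 4.30, 3.56, 2.48, 1.95, 1.70, 1.32,
  2.63, 2.12, 1.44, 1.24, 3.11, 2.37, 2.05, 1.65, 3.42, 2.59, 1.58, 1.28, 1.27, 1.18,
  1.54, 1.18, 1.39, 1.34, 1.73, 1.39, 1.31, 0.84, 1.79, 1.39, 1.47, 1.19, 1.29, 1.53,
  1.24, 0.97, 1.07, 0.77, 1.38, 1.10, 1.07, 0.77, 1.45, 1.14, 1.19, 0.75, 0.90, 0.77,
  0.94, 0.85, 0.57, 0.40, 1.09, 0.91, 0.74, 0.74, 1.16, 0.91, 0.64, 0.42, 0.48, 0.36,
  0.83, 0.84, 0.44, 0.31, 0.99, 0.89, 0.64, 0.73, 1.04, 0.89, 0.48, 0.30, 0.38, 0.31,
  0.79, 0.81, 0.42, 0.29, 0.94, 0.86, 0.61, 0.72, 0.99, 0.86, 0.45, 0.29, 0.36, 0.31,
  3.86, 3.84, 2.11, 2.23, 4.85, 4.52, 2.69, 2.41, 5.02, 4.66, 2.57, 2.69, 1.49, 1.17,
  2.91, 2.83, 1.47, 1.57, 3.80, 3.41, 1.85, 1.38, 4.09, 3.69, 1.75, 1.88, 1.07, 0.91,
  1.82, 1.38, 1.57, 1.71, 2.19, 1.63, 1.39, 0.85, 2.22, 1.51, 1.94, 2.07, 1.06, 0.82,
  1.51, 1.18, 1.23, 0.98, 1.79, 1.39, 1.16, 0.73, 1.82, 1.29, 1.52, 1.13, 0.84, 0.53,
  1.00, 1.00, 0.56, 0.51, 1.26, 1.19, 0.71, 0.60, 1.24, 1.02, 0.68, 0.61, 0.40, 0.24,
  0.90, 0.97, 0.45, 0.44, 1.14, 1.16, 0.62, 0.60, 1.12, 0.97, 0.54, 0.54, 0.32, 0.20,
  0.86, 0.93, 0.43, 0.44, 1.09, 1.10, 0.59, 0.59, 1.06, 0.92, 0.52, 0.53, 0.31, 0.19,
  3.95, 4.24, 2.07, 1.82, 4.49, 4.22, 3.29, 4.24, 4.48, 3.84, 2.47, 2.13, 1.53, 1.13,
  2.58, 2.40, 1.24, 1.21, 3.12, 2.67, 1.94, 1.89, 3.35, 2.76, 1.42, 1.35, 0.99, 0.96,
  1.13, 0.81, 1.23, 1.38, 1.24, 0.94, 1.01, 0.62, 1.23, 0.76, 1.41, 1.52, 0.99, 1.15,
  0.76, 0.49, 0.87, 0.67, 0.81, 0.55, 0.71, 0.40, 0.81, 0.47, 1.02, 0.72, 0.66, 0.54,
  0.30, 0.23, 0.21, 0.14, 0.36, 0.27, 0.23, 0.15, 0.35, 0.19, 0.25, 0.16, 0.16, 0.08,
  0.18, 0.19, 0.08, 0.04, 0.23, 0.22, 0.12, 0.12, 0.21, 0.13, 0.09, 0.05, 0.07, 0.03,
  0.13, 0.13, 0.06, 0.04, 0.16, 0.16, 0.08, 0.09, 0.15, 0.08, 0.06, 0.04, 0.05, 0.03
), ncol = 14, byrow = TRUE)

.rel_cells <- matrix(c(
  0.40, 0.11, 0.36, 0.09, 0.41, 0.09, 0.39, 0.12, 0.40, 0.09, 0.36, 0.09, 0.35, 0.11,
  0.30, 0.06, 0.24, 0.05, 0.32, 0.05, 0.29, 0.07, 0.33, 0.06, 0.24, 0.05, 0.24, 0.05,
  0.19, 0.04, 0.22, 0.06, 0.18, 0.03, 0.19, 0.05, 0.17, 0.03, 0.22, 0.05, 0.22, 0.07,
  0.15, 0.03, 0.19, 0.04, 0.14, 0.02, 0.16, 0.03, 0.14, 0.02, 0.19, 0.04, 0.18, 0.04,
  0.10, 0.02, 0.09, 0.02, 0.10, 0.02, 0.09, 0.02, 0.11, 0.02, 0.09, 0.02, 0.09, 0.02,
  0.08, 0.02, 0.08, 0.02, 0.09, 0.02, 0.08, 0.02, 0.09, 0.02, 0.07, 0.02, 0.08, 0.02,
  0.08, 0.02, 0.07, 0.02, 0.08, 0.02, 0.07, 0.02, 0.08, 0.02, 0.07, 0.02, 0.07, 0.02,
  0.39, 0.11, 0.33, 0.11, 0.39, 0.09, 0.39, 0.13, 0.39, 0.09, 0.32, 0.11, 0.34, 0.11,
  0.29, 0.06, 0.23, 0.06, 0.31, 0.05, 0.27, 0.06, 0.32, 0.05, 0.23, 0.06, 0.24, 0.05,
  0.20, 0.04, 0.25, 0.06, 0.19, 0.03, 0.22, 0.05, 0.19, 0.03, 0.25, 0.06, 0.24, 0.05,
  0.17, 0.03, 0.21, 0.05, 0.16, 0.02, 0.18, 0.04, 0.15, 0.02, 0.21, 0.05, 0.20, 0.05,
  0.10, 0.02, 0.09, 0.02, 0.10, 0.02, 0.10, 0.02, 0.10, 0.02, 0.09, 0.02, 0.09, 0.02,
  0.09, 0.02, 0.07, 0.02, 0.09, 0.02, 0.08, 0.03, 0.09, 0.02, 0.07, 0.02, 0.08, 0.05,
  0.08, 0.02, 0.07, 0.02, 0.08, 0.02, 0.08, 0.03, 0.08, 0.02, 0.07, 0.02, 0.07, 0.02,
  0.39, 0.11, 0.35, 0.09, 0.39, 0.09, 0.38, 0.13, 0.39, 0.09, 0.35, 0.09, 0.35, 0.11,
  0.28, 0.09, 0.21, 0.05, 0.29, 0.07, 0.26, 0.09, 0.31, 0.08, 0.20, 0.06, 0.21, 0.05,
  0.15, 0.06, 0.21, 0.09, 0.14, 0.04, 0.17, 0.08, 0.13, 0.04, 0.21, 0.08, 0.20, 0.09,
  0.11, 0.04, 0.16, 0.07, 0.09, 0.03, 0.12, 0.05, 0.09, 0.03, 0.17, 0.06, 0.16, 0.07,
  0.04, 0.02, 0.04, 0.02, 0.04, 0.02, 0.04, 0.01, 0.04, 0.03, 0.04, 0.02, 0.05, 0.02,
  0.02, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01,
  0.02, 0.01, 0.01, 0.01, 0.02, 0.01, 0.01, 0.01, 0.02, 0.01, 0.01, 0.01, 0.02, 0.01
), ncol = 14, byrow = TRUE)

.paf_cells <- matrix(c(
  8.55, 0.39, 8.46, 0.33, 8.56, 0.41, 8.54, 0.39, 8.56, 0.45, 8.49, 0.34, 8.42, 0.31,
  8.17, 0.52, 8.57, 0.29, 8.18, 0.53, 8.16, 0.51, 8.21, 0.57, 8.59, 0.28, 8.53, 0.31,
  8.35, 0.27, 8.53, 0.18, 8.31, 0.22, 8.31, 0.31, 8.32, 0.22, 8.53, 0.19, 8.54, 0.17
), ncol = 14, byrow = TRUE)

.chirp_var_names <- c("Gamma Power", "Theta Power", "Alpha Power",
                      "Low Gamma ITPC", "High Gamma ITPC",
                      "Stimulus Onset ITPC", "Stimulus Offset ITPC")

.chirp_cells <- matrix(c(
   7.07, 1.80,  5.45, 1.88,  7.65, 1.79,  6.01, 1.27,  8.09, 1.78,  5.64, 1.36,  5.21, 2.47,
  24.25, 2.94, 22.19, 2.25, 24.14, 2.85, 24.45, 3.17, 24.39, 2.87, 22.48, 2.07, 21.76, 2.47,
  -0.21, 0.33, -0.06, 0.32, -0.21, 0.36, -0.21, 0.28, -0.22, 0.37, -0.04, 0.33, -0.08, 0.31,
   0.10, 0.06,  0.14, 0.08,  0.09, 0.06,  0.13, 0.06,  0.08, 0.06,  0.15, 0.08,  0.13, 0.07,
   0.04, 0.03,  0.03, 0.02,  0.03, 0.03,  0.04, 0.03,  0.04, 0.04,  0.04, 0.03,  0.03, 0.02,
   0.14, 0.08,  0.08, 0.06,  0.14, 0.08,  0.12, 0.07,  0.14, 0.08,  0.08, 0.06,  0.08, 0.06,
   0.05, 0.04,  0.04, 0.04,  0.06, 0.04,  0.05, 0.04,  0.06, 0.04,  0.05, 0.04,  0.04, 0.05
), ncol = 14, byrow = TRUE)

.cells_to_long <- function(cells, vars, family, n_by_cohort, bounded) {
  k <- length(.cohort_cols)
  out <- tibble::tibble(
    family   = family,
    variable = rep(vars, each = k),
    cohort   = rep(.cohort_cols, times = length(vars)),
    mean     = as.vector(t(cells[, seq(1, 2 * k, by = 2), drop = FALSE])),
    sd       = as.vector(t(cells[, seq(2, 2 * k, by = 2), drop = FALSE])),
    n        = rep(unname(n_by_cohort[.cohort_cols]), times = length(vars))
  )
  out$lower <- if (bounded) 0 else -Inf
  out$upper <- if (bounded) 1 else Inf
  out
}

#' Reference cohort statistics for each variable family
#'
#' Returns the bundled per-cohort mean/SD table for one family of EEG
#' variables. `cohort` distinguishes the full diagnostic groups (`fxs`,
#' `con`) from subgroup cells (`fxs_male`, `fxs_female`,
#' `fxs_nonmosaic_male`, `con_male`, `con_female`). Bounded families
#' (relative power; the ITPC members of the chirp family) carry `lower`/
#' `upper` columns giving the native range to which simulated draws are
#' clipped; unbounded families have infinite bounds.
#'
#' @param family one of `"absolute"`, `"relative"`, `"alphapeak"`, `"chirp"`.
#' @return a tibble with columns `family`, `variable`, `cohort`, `mean`,
#'   `sd`, `n`, `lower`, `upper`.
#' @export
#' @examples
#' head(cohort_stats("relative"))
cohort_stats <- function(family = c("absolute", "relative", "alphapeak", "chirp")) {
  family <- match.arg(family)
  switch(family,
    absolute  = .cells_to_long(.abs_cells, .rest_var_names, "absolute", .rest_n, FALSE),
    relative  = .cells_to_long(.rel_cells, .rest_var_names, "relative", .rest_n, TRUE),
    alphapeak = .cells_to_long(.paf_cells, .region_labels, "alphapeak", .rest_n, FALSE),
    chirp     = {
      s <- .cells_to_long(.chirp_cells, .chirp_var_names, "chirp", .chirp_n, FALSE)
      itpc <- grepl("ITPC", s$variable)
      s$lower[itpc] <- 0
      s$upper[itpc] <- 1
      s
    }
  )
}

#' Default cohort composition for a task
#'
#' Subgroup head-counts mirroring the reference cohorts: resting 70 FXS
#' (38 male, of whom 27 non-mosaic; 32 female) vs 71 CON (41 male, 30
#' female); chirp 57 FXS (37 male, 26 non-mosaic; 20 female) vs 57 CON
#' (34 male, 23 female). Counts are parameters, not constants: pass any
#' composition tibble of the same shape to the simulator.
#'
#' @param task `"rest"` or `"chirp"`.
#' @return tibble with columns `group`, `sex`, `mosaic`, `n`, `cohort`
#'   (the stats column each cell draws from).
#' @export
default_composition <- function(task = c("rest", "chirp")) {
  task <- match.arg(task)
  n <- if (task == "rest") .rest_n else .chirp_n
  n_mosaic <- n[["fxs_male"]] - n[["fxs_nonmosaic_male"]]
  tibble::tibble(
    group  = c("FXS", "FXS", "FXS", "CON", "CON"),
    sex    = c("M", "M", "F", "M", "F"),
    mosaic = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    n      = c(n[["fxs_nonmosaic_male"]], n_mosaic, n[["fxs_female"]],
               n[["con_male"]], n[["con_female"]]),
    cohort = c("fxs_nonmosaic_male", "fxs_male", "fxs_female",
               "con_male", "con_female")
  )
}
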