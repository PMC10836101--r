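# Montage geometry: channel sets, scalp quadrants and the dense-array to
# clinical 10-20 reduction. The quadrant sensor lists are editable package
# defaults (dense-array quadrant membership is lab convention, not a
# standard), and every function accepts user-supplied sets.

.hydrocel_frontal <- c("E2", "E3", "E4", "E5", "E9", "E10", "E11", "E15",
                       "E16", "E18", "E19", "E22", "E23", "E24", "E26",
                       "E27", "E33", "E122", "E123", "E124")

.hydrocel_posterior <- c("E52", "E58", "E59", "E60", "E61", "E62", "E65",
                         "E66", "E67", "E70", "E71", "E72", "E75", "E76",
                         "E77", "E83", "E84", "E85", "E92", "E96")

# Standard equivalences between HydroCel-128 sensors and 10-20 positions.
.hydrocel_to_1020 <- c(
  Fp1 = "E22", Fp2 = "E9",  F7 = "E33",  F3 = "E24",  Fz = "E11",
  F4  = "E124", F8 = "E122", T7 = "E45", C3 = "E36",  Cz = "E129",
  C4  = "E104", T8 = "E108", P7 = "E58", P3 = "E52",  Pz = "E62",
  P4  = "E92",  P8 = "E96",  O1 = "E70", Oz = "E75",  O2 = "E83"
)

.std1020_frontal   <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
.std1020_posterior <- c("P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")

#' Channel labels of the simulated dense-array working set
#'
#' The union of the frontal quadrant, posterior quadrant and the 20
#' HydroCel sensors mapped to 10-20 positions: the minimal dense-array
#' subset on which every downstream operation (quadrant spectra, whole-head
#' averages, montage reduction) is defined. Simulating this subset rather
#' than all 128 sensors keeps signal-level cohorts desk-sized.
#'
#' @return character vector of channel labels.
#' @export
hydrocel_working_set <- function() {
  unique(c(.hydrocel_frontal, .hydrocel_posterior, unname(.hydrocel_to_1020)))
}

#' Scalp region map for a montage
#'
#' Maps region names (`frontal`, `posterior`, `whole_head`) to channel-label
#' sets. The whole-head region is the full channel set of the recording and
#' always contains both quadrants.
#'
#' @param montage `"hydrocel128"` (also used for its simulated working
#'   subset) or `"standard1020-20"`.
#' @param channels channel labels actually present; quadrant sets are
#'   intersected with these and `whole_head` is set to them.
#' @param frontal,posterior optional explicit quadrant label sets overriding
#'   the defaults.
#' @return named list of character vectors.
#' @export
region_map <- function(montage = c("hydrocel128", "standard1020-20"),
                       channels = NULL, frontal = NULL, posterior = NULL) {
  montage <- match.arg(montage)
  if (is.null(frontal))
    frontal <- if (montage == "hydrocel128") .hydrocel_frontal else .std1020_frontal
  if (is.null(posterior))
    posterior <- if (montage == "hydrocel128") .hydrocel_posterior else .std1020_posterior
  whole <- channels %||% unique(c(frontal, posterior))
  if (!is.null(channels)) {
    frontal <- intersect(frontal, channels)
    posterior <- intersect(posterior, channels)
  }
  if (length(frontal) == 0 || length(posterior) == 0)
    stop_fx("empty scalp region after intersecting with available channels")
  list(frontal = frontal, posterior = posterior, whole_head = whole)
}

#' Dense-array to 20-channel clinical montage map
#'
#' @return named character vector: names are the 20 target 10-20 labels,
#'   values the HydroCel source sensor selected for each (nearest-sensor
#'   lookup, no interpolation).
#' @export
montage_map_1020 <- function() .hydrocel_to_1020

#' Reduce a recording to a clinical montage by nearest-sensor selection
#'
#' Each target channel takes the signal of its mapped source sensor
#' unchanged — down-sampling of the sensor array, not interpolation, which
#' mimics what a sparse clinical net would actually record.
#'
#' @param rec an [epoched_recording()].
#' @param map named character vector target-label -> source-label
#'   (default [montage_map_1020()]).
#' @param montage montage id for the reduced recording.
#' @return an `epoched_recording` with `length(map)` channels.
#' @export
reduce_montage <- function(rec, map = montage_map_1020(),
                           montage = "standard1020-20") {
  missing <- setdiff(unname(map), rec$labels)
  if (length(missing) > 0)
    stop_fx("source channel(s) missing from recording: %s",
            paste(missing, collapse = ", "))
  idx <- match(unname(map), rec$labels)
  epoched_recording(rec$samples[idx, , , drop = FALSE], fs = rec$fs,
                    labels = names(map), montage = montage,
                    task = rec$task, time0 = rec$time0)
}

#' Default fronto-central sensor cluster for the chirp response
#'
#' A 23-sensor fronto-central set over which chirp trials are averaged
#' before time-frequency analysis, consistent with scalp projection of
#' auditory cortex activity. Membership is an editable default; any label
#' set present in the recording is accepted by [cluster_average()].
#'
#' @return character vector of 23 channel labels.
#' @export
chirp_cluster <- function() {
  c("E4", "E5", "E6", "E7", "E10", "E11", "E12", "E13", "E16", "E19",
    "E20", "E28", "E29", "E30", "E31", "E36", "E37", "E42", "E54", "E55",
    "E79", "E80", "E87")
}
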