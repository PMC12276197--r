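# Closed-form phenotype statistics: qPCR fold change, body condition,
# respirometry summaries.

#' qPCR measurement record
#'
#' @param ct_target Ct value(s) for the gene of interest (cycles).
#' @param ct_housekeeping Ct value(s) for the housekeeping gene.
#' @return A `QpcrMeasurement` list; vectors of replicate Ct values are kept
#'   as supplied.
#' @export
qpcr_measurement <- function(ct_target, ct_housekeeping) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_housekeeping))) {
    stop("Ct values must be finite")
  }
  if (any(ct_target <= 0) || any(ct_housekeeping <= 0)) {
    stop("Ct values must be positive")
  }
  structure(list(ct_target = ct_target, ct_housekeeping = ct_housekeeping),
            class = "QpcrMeasurement")
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_housekeeping` per group (replicates are averaged),
#' `ddCt = dCt_treated - dCt_control`, fold change `= 2^-ddCt`.
#'
#' @param treated,control `QpcrMeasurement` records.
#' @return Fold change (unitless).
#' @export
delta_delta_ct <- function(treated, control) {
  stopifnot(inherits(treated, "QpcrMeasurement"),
            inherits(control, "QpcrMeasurement"))
  d_treated <- mean(treated$ct_target) - mean(treated$ct_housekeeping)
  d_control <- mean(control$ct_target) - mean(control$ct_housekeeping)
  2^(-(d_treated - d_control))
}

#' Unpaired t-test on per-replicate delta-Ct values
#'
#' Convenience wrapper: computes per-replicate `dCt` for both groups and
#' applies a standard unpaired t-test.
#'
#' @param treated,control `QpcrMeasurement` records with equal-length
#'   replicate vectors within each group.
#' @return The `htest` result of [stats::t.test()].
#' @export
delta_ct_test <- function(treated, control) {
  stopifnot(inherits(treated, "QpcrMeasurement"),
            inherits(control, "QpcrMeasurement"))
  stats::t.test(treated$ct_target - treated$ct_housekeeping,
                control$ct_target - control$ct_housekeeping)
}

#' Fulton's condition factor
#'
#' `K = 100 * M / L^3` with mass in grams and length in centimetres; a body
#' condition index (lower K at a given length means a leaner fish).
#' Vectorized; a group mean K is the mean of per-fish K values.
#'
#' @param mass Mass in grams (> 0).
#' @param length Length in centimetres (> 0).
#' @return K (unitless).
#' @export
fulton_condition_factor <- function(mass, length) {
  if (any(mass <= 0) || any(length <= 0)) {
    stop("mass and length must be positive")
  }
  100 * mass / length^3
}

#' Respirometry summary: basal and maximum metabolic rate, aerobic scope
#'
#' Basal metabolic rate (BMR) is the mean of the lowest 10% of trials
#' (`max(1, floor(0.1 * n))` trials, so the set is never empty), maximum
#' metabolic rate (MMR) the single greatest rate, and aerobic scope their
#' difference — the capacity for activity above maintenance.
#'
#' @param rates Non-negative oxygen-uptake rates (mgO2 kg^-1 h^-1), >= 1
#'   value; >= 10 trials recommended for the 10% rule.
#' @return List with `bmr`, `mmr`, `aerobic_scope` (same units as input).
#' @export
respirometry_summary <- function(rates) {
  if (!length(rates)) stop("`rates` must be non-empty")
  if (any(rates < 0)) stop("rates must be non-negative")
  n <- length(rates)
  k <- max(1L, floor(0.1 * n))
  bmr <- mean(sort(rates)[seq_len(k)])
  mmr <- max(rates)
  list(bmr = bmr, mmr = mmr, aerobic_scope = mmr - bmr)
}
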