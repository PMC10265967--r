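## Shock-efficacy metrics: defibrillation threshold via the critical-mass
## criterion, capacitive shock energy, impedance, mean E-field.

#' Critical-mass defibrillation criterion
#'
#' Defibrillation is predicted successful when `mass_fraction` of the
#' ventricular myocardium (LV + RV wall, volume-weighted, scar excluded)
#' experiences an E-field magnitude of at least `threshold` V/cm.
#'
#' @param threshold E-field threshold in V/cm (default 5).
#' @param mass_fraction Required myocardial volume fraction (default 0.95).
#' @param v_applied Test shock voltage in V (default 10) at which fields
#'   are simulated before linear rescaling.
#' @return An object of class `dft_criterion`.
#' @export
dft_criterion <- function(threshold = 5, mass_fraction = 0.95,
                          v_applied = 10) {
  stopifnot(threshold > 0, mass_fraction > 0, mass_fraction < 1,
            v_applied > 0)
  structure(list(threshold = threshold, mass_fraction = mass_fraction,
                 v_applied = v_applied), class = "dft_criterion")
}

## Elements counted as excitable ventricular myocardium.
ventricular_elements <- function(mesh) {
  which(mesh$region %in% c("lv_wall", "rv_wall"))
}

## Volume-weighted lower-tail value: smallest E such that the cumulative
## volume fraction of elements with field <= E reaches `frac` (explicit
## sort-and-accumulate; this is the g_(1-mass_fraction) quantile of the
## critical-mass criterion).
weighted_lower_value <- function(e, w, frac) {
  o <- order(e)
  cw <- cumsum(w[o])
  k <- which(cw >= frac * cw[length(cw)])[1]
  e[o][k]
}

#' Defibrillation threshold voltage
#'
#' Linearly rescales the applied test voltage so that the criterion's mass
#' fraction of ventricular myocardium reaches the field threshold: with
#' g05 the field magnitude (V/cm) exceeded by `mass_fraction` of the
#' myocardial volume at `v_applied`, `DFT = v_applied * threshold / g05`.
#'
#' @param solution A `field_solution` computed at the criterion's test
#'   voltage.
#' @param mesh The mesh it was computed on.
#' @param criterion A [dft_criterion()].
#' @return DFT voltage in V.
#' @export
compute_dft <- function(solution, mesh, criterion = dft_criterion()) {
  idx <- ventricular_elements(mesh)
  if (!length(idx)) stop("mesh has no ventricular myocardium elements")
  e_vcm <- solution$e_mag[idx] * 10 # V/mm -> V/cm
  g <- weighted_lower_value(e_vcm, mesh$volumes[idx],
                            1 - criterion$mass_fraction)
  solution$v_applied * criterion$threshold / g
}

#' Capacitive shock energy
#'
#' `E = C V^2 / 2` for a capacitive discharge at the DFT voltage.
#'
#' @param dft_voltage DFT voltage in V.
#' @param capacitance Device capacitance in F (default 100 uF).
#' @return Energy in J.
#' @export
dft_energy <- function(dft_voltage, capacitance = 1e-4) {
  stopifnot(dft_voltage >= 0)
  capacitance * dft_voltage^2 / 2
}

#' Shock impedance
#'
#' Ohm's law over the electrode system: applied voltage divided by the
#' total current leaving the shocking electrode.
#'
#' @inheritParams electrode_currents
#' @param currents Optional precomputed currents from
#'   [electrode_currents()].
#' @return Impedance in Ohm.
#' @export
compute_impedance <- function(solution, mesh, sigma = conductivity_map(),
                              method = c("reaction", "surface"),
                              system = NULL, currents = NULL) {
  if (is.null(currents))
    currents <- electrode_currents(solution, mesh, sigma,
                                   method = match.arg(method),
                                   system = system)
  ish <- sum(currents[solution$shock_electrodes])
  if (abs(ish) < 1e-300) stop("zero shock-electrode current")
  solution$v_applied / abs(ish)
}

#' Mean myocardial E-field
#'
#' Volume-weighted mean of the per-element field magnitude over the
#' ventricular myocardium at the applied voltage.
#'
#' @param solution A `field_solution`.
#' @param mesh The mesh it was computed on.
#' @return Mean field in V/mm.
#' @export
mean_e_field <- function(solution, mesh) {
  idx <- ventricular_elements(mesh)
  if (!length(idx)) stop("mesh has no ventricular myocardium elements")
  sum(solution$e_mag[idx] * mesh$volumes[idx]) / sum(mesh$volumes[idx])
}

#' All shock metrics for one solve
#'
#' @inheritParams compute_dft
#' @param sigma A [conductivity_map()].
#' @param system Optional pre-assembled system (for the current
#'   computation's reaction cross-check).
#' @param current_method Method for [electrode_currents()].
#' @return A one-row data.frame: DFT voltage (V) and energy (J), impedance
#'   (Ohm), mean E-field (V/mm), coverage fraction at the applied voltage,
#'   and the relative charge imbalance of the electrode currents.
#' @export
shock_metrics <- function(solution, mesh, sigma = conductivity_map(),
                          criterion = dft_criterion(), system = NULL,
                          current_method = "reaction") {
  dftv <- compute_dft(solution, mesh, criterion)
  currents <- electrode_currents(solution, mesh, sigma,
                                 method = current_method, system = system)
  ish <- sum(currents[solution$shock_electrodes])
  imbalance <- abs(sum(currents)) / abs(ish)
  idx <- ventricular_elements(mesh)
  e_vcm <- solution$e_mag[idx] * 10
  cov <- sum(mesh$volumes[idx][e_vcm >= criterion$threshold]) /
    sum(mesh$volumes[idx])
  data.frame(dft_voltage_V = dftv,
             dft_energy_J = dft_energy(dftv),
             impedance_ohm = solution$v_applied / abs(ish),
             mean_e_field_V_per_mm = mean_e_field(solution, mesh),
             coverage = cov,
             charge_imbalance = imbalance)
}

#' Write a metrics table as CSV
#'
#' @param results Data.frame of cohort metrics from [run_cohort()].
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
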