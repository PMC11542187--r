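## Transport and sensing layer: band-gap conductivity, Richardson-Dushman
## current density, sensor responses, selectivity coefficients, and
## transition-state-theory recovery times.

#' Operating conditions of the model sensor
#'
#' Bundles the physical constants of the transport/sensing model.
#'
#' @param temperature Operating temperature in K (default 298.15, room
#'   temperature).
#' @param k_B Boltzmann constant in eV/K (default 8.62e-5).
#' @param nu0 Desorption attempt frequency in 1/s (default 5.2e14, the
#'   value associated with yellow-light illumination).
#' @param A_sigma Conductivity prefactor in electron m^-3 K^-3/2.  It
#'   cancels in every reported response and selectivity; absolute
#'   conductivities are therefore prefactor-dependent and default to a
#'   unit prefactor.
#' @param A_rd Richardson-Dushman constant in A m^-2 K^-2 (default 120.1,
#'   as tabulated in the reference dataset; the conventional value is
#'   1.20e6 A m^-2 K^-2).  It cancels in every reported metric; absolute
#'   current densities are prefactor-dependent.
#' @return An object of class `sensor_conditions`.
#' @examples
#' sensor_conditions()
#' @export
sensor_conditions <- function(temperature = 298.15, k_B = 8.62e-5,
                              nu0 = 5.2e14, A_sigma = 1, A_rd = 120.1) {
  if (temperature <= 0) abort_domain("temperature must be > 0")
  if (k_B <= 0) abort_domain("k_B must be > 0")
  if (nu0 <= 0) abort_domain("nu0 must be > 0")
  structure(
    list(temperature = temperature, k_B = k_B, nu0 = nu0,
         A_sigma = A_sigma, A_rd = A_rd),
    class = "sensor_conditions"
  )
}

#' @export
print.sensor_conditions <- function(x, ...) {
  cat("<sensor_conditions>\n")
  cat(sprintf("  temperature: %g K\n", x$temperature))
  cat(sprintf("  k_B:         %g eV/K  (k_B*T = %g eV)\n",
              x$k_B, x$k_B * x$temperature))
  cat(sprintf("  nu0:         %g 1/s\n", x$nu0))
  cat(sprintf("  A_sigma:     %g electron m^-3 K^-3/2 (prefactor-dependent)\n",
              x$A_sigma))
  cat(sprintf("  A_rd:        %g A m^-2 K^-2 (prefactor-dependent)\n", x$A_rd))
  invisible(x)
}

as_conditions <- function(conditions) {
  if (inherits(conditions, "sensor_conditions")) return(conditions)
  do.call(sensor_conditions, as.list(conditions))
}

#' Intrinsic band-gap conductivity
#'
#' Activated-transport estimate
#' `sigma = A_sigma * T^(3/2) * exp(-E_gap / (2 k_B T))`.  The prefactor
#' does not cancel here, so absolute values are prefactor-dependent; only
#' conductivity ratios are physically meaningful in this model.
#'
#' @param e_gap HOMO--LUMO gap(s), eV, `>= 0`.
#' @param conditions A [sensor_conditions()] object.
#' @return Numeric vector of conductivities.
#' @export
conductivity <- function(e_gap, conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (any(e_gap < 0)) abort_domain("e_gap must be >= 0")
  with(conditions,
       A_sigma * temperature^(3 / 2) *
         exp(-e_gap / (2 * k_B * temperature)))
}

#' Richardson-Dushman thermionic current density
#'
#' `j = A_rd * T^2 * exp(-phi / (k_B T))`.  Absolute values are
#' prefactor-dependent (see [sensor_conditions()]); ratios are not.
#'
#' @param phi Work function(s), eV, `>= 0`.
#' @inheritParams conductivity
#' @return Numeric vector of current densities (A/m^2 under the stored
#'   prefactor).
#' @export
current_density <- function(phi, conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (any(phi < 0)) abort_domain("phi must be >= 0")
  with(conditions, A_rd * temperature^2 * exp(-phi / (k_B * temperature)))
}

#' Conductometric sensor response
#'
#' The relative resistance change upon adsorption under the
#' activated-transport conductivity model,
#' `S = |R_after - R_before| / min(R) = exp(|gap_complex - gap_host| /
#' (2 k_B T)) - 1`.
#'
#' The absolute exponent makes gap opening and closing of equal size give
#' the same response; the `- 1` makes an unchanged gap report exactly 0.
#'
#' @param gap_host Gap of the isolated host (eV).
#' @param gap_complex Gap of the host--analyte complex (eV).
#' @inheritParams conductivity
#' @return Numeric vector of dimensionless responses.
#' @examples
#' sensor_response(3.04, 4.25) # ~1.7e10
#' @export
sensor_response <- function(gap_host, gap_complex,
                            conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (any(gap_host < 0) || any(gap_complex < 0)) {
    abort_domain("gaps must be >= 0")
  }
  d <- snap_zero(abs(gap_complex - gap_host))
  with(conditions, exp(d / (2 * k_B * temperature)) - 1)
}

## Energy differences below 1 neV are floating-point cancellation noise of
## tabulated inputs, not signal; treat them as exactly zero so an unchanged
## gap or work function reports a response of exactly 0.
snap_zero <- function(x, tol = 1e-9) ifelse(abs(x) < tol, 0, x)

#' Work-function sensor response
#'
#' The relative change of the Richardson-Dushman current density,
#' `S_j = exp(|phi_after - phi_before| / (k_B T)) - 1`.
#'
#' @param phi_before,phi_after Work functions before/after adsorption
#'   (eV), `> 0`.
#' @inheritParams conductivity
#' @return Numeric vector of dimensionless responses.
#' @examples
#' wf_response(3.25, 2.46) # ~2.2e13
#' @export
wf_response <- function(phi_before, phi_after,
                        conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (any(phi_before <= 0) || any(phi_after <= 0)) {
    abort_domain("work functions must be > 0")
  }
  d <- snap_zero(abs(phi_after - phi_before))
  with(conditions, exp(d / (k_B * temperature)) - 1)
}

#' Selectivity coefficient
#'
#' `kappa = S_target / S_other`: how many times more strongly the sensor
#' responds to the target analyte than to an interferent.  The same ratio
#' applied to work-function responses gives `kappa_j`.  A zero interferent
#' response yields the undefined sentinel `NA` (reported as a dash in the
#' reference tables).
#'
#' @param s_target Response to the target analyte.
#' @param s_other Response to the interferent.
#' @return Numeric vector of selectivity coefficients.
#' @export
selectivity_coefficient <- function(s_target, s_other) {
  if (any(s_target < 0, na.rm = TRUE) || any(s_other < 0, na.rm = TRUE)) {
    abort_domain("responses must be >= 0")
  }
  ifelse(s_other == 0, NA_real_, s_target / s_other)
}

#' Transition-state-theory recovery time
#'
#' `tau = (1/nu0) * exp(-E_ads / (k_B T))`, the expected desorption time of
#' the analyte.  With a bound complex (`E_ads < 0`) the exponent is
#' positive and recovery slows exponentially with binding strength.
#'
#' @param e_ads Adsorption energy (eV); negative means bound.
#' @inheritParams conductivity
#' @return Numeric vector of recovery times in seconds.
#' @examples
#' recovery_time(-1.39) / 3600 # hours; far above 12 h
#' @export
recovery_time <- function(e_ads, conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  with(conditions, exp(-e_ads / (k_B * temperature)) / nu0)
}

#' Recovery-time scan over temperature and attempt frequency
#'
#' Evaluates [recovery_time()] on the Cartesian grid of temperatures and
#' attempt frequencies, for log-scale Arrhenius plotting.
#'
#' @param e_ads Adsorption energy (eV).
#' @param temperatures Numeric vector of temperatures (K), default
#'   350--650 K.
#' @param nu0 Numeric vector of attempt frequencies (1/s); defaults to the
#'   value stored in `conditions`.
#' @inheritParams conductivity
#' @return A tibble of class `recovery_scan` with columns `temperature`,
#'   `nu0`, `tau`.
#' @export
recovery_scan <- function(e_ads, temperatures = seq(350, 650, by = 5),
                          nu0 = NULL, conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (length(temperatures) == 0) abort_domain("empty temperature grid")
  if (any(temperatures <= 0)) abort_domain("temperatures must be > 0")
  if (is.null(nu0)) nu0 <- conditions$nu0
  if (length(nu0) == 0) abort_domain("empty attempt-frequency grid")
  grid <- tidyr::expand_grid(temperature = temperatures, nu0 = nu0)
  out <- grid %>%
    mutate(tau = exp(-e_ads / (conditions$k_B * .data$temperature)) /
             .data$nu0)
  attr(out, "e_ads") <- e_ads
  class(out) <- c("recovery_scan", class(out))
  out
}

#' @rdname recovery_scan
#' @param object A `recovery_scan`.
#' @param ... Unused.
#' @method autoplot recovery_scan
#' @export
autoplot.recovery_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$temperature, y = .data$tau,
                               colour = factor(.data$nu0))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Temperature (K)", y = expression(tau ~ "(s)"),
                  colour = expression(nu[0] ~ (s^-1))) +
    ggplot2::theme_minimal()
}

#' Ranked selectivity table for one host
#'
#' Screens a set of analytes adsorbed on a common host: for every pair the
#' reporting channel, complex gap and work function, gap sensitivity,
#' conductometric response `S`, adsorption energy, work-function
#' modulation, work-function response `S_j`, recovery time `tau`, and the
#' selectivity coefficients `kappa`/`kappa_j` against a stated reference
#' analyte.  Rows are ordered by descending electronic sensitivity.
#'
#' @param species Species table.
#' @param pairs Pairs table whose rows share a single host.
#' @param reference Guest label of the reference (target) analyte; its row
#'   has `kappa = kappa_j = 1`.
#' @inheritParams conductivity
#' @return A tibble with one row per analyte, class `selectivity_table`.
#' @export
selectivity_table <- function(species, pairs, reference,
                              conditions = sensor_conditions()) {
  conditions <- as_conditions(conditions)
  if (!reference %in% pairs$guest) {
    abort_lookup(paste0("reference analyte '", reference,
                        "' not among the pairs"))
  }
  if (length(unique(pairs$host)) > 1) {
    abort_validation("selectivity_table() expects a single host")
  }
  tab <- adsorption_table(species, pairs, gibbs = FALSE)
  tab <- tab %>%
    mutate(
      S = sensor_response(.data$gap_host, .data$gap_complex, conditions),
      S_j = wf_response(.data$phi_host, .data$phi_complex, conditions),
      tau = recovery_time(.data$E_ads, conditions)
    )
  s_ref <- tab$S[tab$guest == reference]
  sj_ref <- tab$S_j[tab$guest == reference]
  out <- tab %>%
    mutate(
      kappa = selectivity_coefficient(s_ref, .data$S),
      kappa_j = selectivity_coefficient(sj_ref, .data$S_j)
    ) %>%
    arrange(desc(.data$dgap_pct)) %>%
    select("host", "guest", "complex", "channel",
           E_gap = "gap_complex", "dgap_pct", "S", "kappa",
           "E_ads", phi = "phi_complex", "dphi_pct", "S_j", "kappa_j",
           "tau", "flag")
  attr(out, "reference") <- reference
  attr(out, "conditions") <- conditions
  class(out) <- c("selectivity_table", class(out))
  out
}

#' Format responses in two-significant-figure scientific notation
#'
#' @param x Numeric vector.
#' @param sig Significant figures (default 2).
#' @return Character vector like `"1.7e+10"`; `NA` becomes `"-"`.
#' @export
format_response <- function(x, sig = 2) {
  ifelse(is.na(x), "-", formatC(signif(x, sig), format = "g", digits = sig))
}
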