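## Pairwise host--guest energetics and response precursors: gap
## sensitivity, BSSE-corrected adsorption energy, Gibbs adsorption energy,
## work-function modulation and charge transfer.

#' Electronic gap sensitivity
#'
#' `d_gap = |gap_after - gap_before|` and
#' `dgap_pct = 100 * d_gap / gap_before`, the percentage gap change used as
#' the electronic sensitivity of a chemiresistive sensor.  The denominator
#' is always the isolated host's gap.  The signed change is retained so the
#' direction (gap opening vs closing) is not lost.
#'
#' @param gap_before,gap_after Numeric vectors of HOMO--LUMO gaps (eV);
#'   `gap_before > 0`.
#' @return A tibble with columns `d_gap`, `d_gap_signed`, `dgap_pct`.
#' @examples
#' gap_sensitivity(3.04, 4.25)
#' @export
gap_sensitivity <- function(gap_before, gap_after) {
  if (any(gap_before <= 0)) {
    abort_domain("gap_before must be > 0")
  }
  tibble(
    d_gap = abs(gap_after - gap_before),
    d_gap_signed = gap_after - gap_before,
    dgap_pct = 100 * abs(gap_after - gap_before) / gap_before
  )
}

species_energy <- function(species, col) {
  one_per_label <- distinct(species, .data$label, .keep_all = TRUE)
  setNames(one_per_label[[col]], one_per_label$label)
}

resolve_energy <- function(energies, labels, what, field) {
  miss <- setdiff(labels, names(energies))
  if (length(miss) > 0) {
    abort_lookup(paste0("unresolved ", what, " label '", miss[1], "'"))
  }
  vals <- energies[labels]
  if (anyNA(vals)) {
    lab <- labels[which(is.na(vals))[1]]
    abort_field(paste0("field '", field, "' missing for species '", lab, "'"))
  }
  unname(vals)
}

#' Counterpoise-corrected adsorption energy
#'
#' `E_ads = E_complex - E_host - E_guest + E_BSSE`, in eV; negative values
#' indicate a bound complex.  The counterpoise (BSSE) term is taken from
#' the pairs table (default 0).
#'
#' @param pairs Pairs table with columns `host`, `guest`, `complex`,
#'   `E_BSSE`.
#' @param species Species table providing `E_total` for every label.
#' @return `pairs` with an `E_ads` column appended.
#' @export
adsorption_energy <- function(pairs, species) {
  en <- species_energy(species, "E_total")
  as_tibble(pairs) %>%
    mutate(E_ads =
      resolve_energy(en, .data$complex, "complex", "E_total") -
      resolve_energy(en, .data$host, "host", "E_total") -
      resolve_energy(en, .data$guest, "guest", "E_total") +
      .data$E_BSSE)
}

#' Gibbs free energy of adsorption
#'
#' `dG_ads = G_complex - G_host - G_guest`, in eV; negative values indicate
#' a spontaneous adsorption.  A missing `G_free` on any of the three
#' species raises a named-field error rather than being imputed.
#'
#' @inheritParams adsorption_energy
#' @return `pairs` with a `dG_ads` column appended.
#' @export
gibbs_adsorption <- function(pairs, species) {
  if (!"G_free" %in% names(species)) {
    abort_field("field 'G_free' missing from the species table")
  }
  gn <- species_energy(species, "G_free")
  as_tibble(pairs) %>%
    mutate(dG_ads =
      resolve_energy(gn, .data$complex, "complex", "G_free") -
      resolve_energy(gn, .data$host, "host", "G_free") -
      resolve_energy(gn, .data$guest, "guest", "G_free"))
}

#' Work-function modulation
#'
#' `100 * |phi_after - phi_before| / phi_before`, the percentage change of
#' the work function upon adsorption.  The absolute value is used: a rise
#' and a fall of equal size report the same modulation.
#'
#' @param phi_before,phi_after Work functions (eV); `phi_before > 0`.
#' @return Numeric vector of percentage changes.
#' @examples
#' workfunction_modulation(4.19, 3.21)
#' @export
workfunction_modulation <- function(phi_before, phi_after) {
  if (any(phi_before <= 0)) {
    abort_domain("phi_before must be > 0")
  }
  100 * abs(phi_after - phi_before) / phi_before
}

#' Charge transfer at a tagged site
#'
#' `dQ = Q_after - Q_before` (e).  Negative values mean the site gained
#' electron density.
#'
#' @param q_before,q_after Partial charges (e).
#' @return Numeric vector of charge differences.
#' @export
charge_transfer <- function(q_before, q_after) {
  q_after - q_before
}

## Pair host and complex channel rows for one adsorption pair.  Channels
## shared by host and complex are paired directly and the reporting channel
## is the one with the larger relative gap change; when the records share
## no channel (e.g. only the beta channel of the complex was recorded) the
## host's first channel is used as the baseline and the row keeps its flag.
pair_channels <- function(host_rows, complex_rows) {
  shared <- intersect(host_rows$channel, complex_rows$channel)
  if (length(shared) > 0) {
    h <- host_rows[host_rows$channel %in% shared, ]
    cx <- complex_rows[complex_rows$channel %in% shared, ]
    cx$label <- h$label[match(cx$channel, h$channel)]
    sel <- select_channel(h, cx)
    hi <- h[h$channel == sel$channel[1], ]
    ci <- cx[cx$channel == sel$channel[1], ]
  } else {
    hi <- host_rows[1, ]
    ci <- complex_rows[1, ]
  }
  list(host = hi, complex = ci, channel = ci$channel[1])
}

#' Adsorption report for host--guest pairs
#'
#' One row per adsorption pair with the selected reporting channel, gap
#' sensitivity, work functions and their modulation, site charges and
#' charge transfer, Gibbs adsorption energy and BSSE-corrected adsorption
#' energy.
#'
#' @param species Species table.
#' @param pairs Pairs table.
#' @param gibbs Compute `dG_ads` (requires `G_free` on all species of every
#'   pair)?  Default `TRUE`.
#' @return A tibble with one row per pair.
#' @export
adsorption_table <- function(species, pairs, gibbs = TRUE) {
  validate_pairs(pairs, species)
  desc <- frontier_descriptors(species)
  pairs <- adsorption_energy(pairs, species)
  if (gibbs) pairs <- gibbs_adsorption(pairs, species)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    hr <- desc[desc$label == p$host, ]
    cr <- desc[desc$label == p$complex, ]
    pc <- pair_channels(hr, cr)
    gs <- gap_sensitivity(pc$host$E_gap, pc$complex$E_gap)
    phi_b <- pc$host$phi
    phi_a <- pc$complex$phi
    q_cu_b <- charge_of(pc$host, "Cu")
    q_cu_a <- charge_of(pc$complex, "Cu")
    tibble(
      host = p$host, guest = p$guest, complex = p$complex,
      channel = pc$channel,
      gap_host = pc$host$E_gap, gap_complex = pc$complex$E_gap,
      d_gap = gs$d_gap, d_gap_signed = gs$d_gap_signed,
      dgap_pct = gs$dgap_pct,
      phi_host = phi_b, phi_complex = phi_a,
      dphi_pct = workfunction_modulation(phi_b, phi_a),
      Q_Cu_host = q_cu_b, Q_Cu_complex = q_cu_a,
      dQ_Cu = charge_transfer(q_cu_b, q_cu_a),
      Q_guest = charge_of(pc$complex, "guest"),
      dG_ads = if (gibbs) p$dG_ads else NA_real_,
      E_ads = p$E_ads,
      flag = p$flag %||% ""
    )
  })
  bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
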