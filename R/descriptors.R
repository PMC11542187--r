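## Per-species conceptual-DFT descriptors from frontier orbitals, cohesion
## energy, and the open-shell channel-selection rule.

#' Frontier-orbital reactivity descriptors
#'
#' Computes, per row of a species table, the Koopmans-style conceptual-DFT
#' descriptors from the HOMO/LUMO energies `E_H` and `E_L` (eV):
#'
#' * `E_gap = E_L - E_H`, the HOMO--LUMO gap;
#' * `mu = (E_H + E_L)/2`, the chemical potential;
#' * `eta = (E_L - E_H)/2`, the global hardness;
#' * `omega = mu^2 / (2*eta)`, the electrophilicity index;
#' * `phi = -mu`, the frontier-orbital work function.
#'
#' For a degenerate frontier (`eta = 0`) the electrophilicity is reported
#' as `NA` (an explicit "undefined" sentinel) rather than infinity, so bulk
#' screening never aborts on a metallic record.
#'
#' @param data A data frame with numeric columns `E_H` and `E_L` (eV), e.g.
#'   a species table.
#' @return `data` as a tibble with columns `E_gap`, `mu`, `eta`, `omega`
#'   and `phi` appended.
#' @examples
#' frontier_descriptors(tibble::tibble(E_H = -7.63, E_L = -0.76))
#' @export
frontier_descriptors <- function(data) {
  if (!all(c("E_H", "E_L") %in% names(data))) {
    abort_schema("frontier_descriptors() needs columns 'E_H' and 'E_L'")
  }
  bad <- which(data$E_L < data$E_H)
  if (length(bad) > 0) {
    lab <- if ("label" %in% names(data)) data$label[bad[1]] else bad[1]
    abort_validation(paste0("E_L < E_H for row '", lab, "'"))
  }
  as_tibble(data) %>%
    mutate(
      E_gap = .data$E_L - .data$E_H,
      mu = (.data$E_H + .data$E_L) / 2,
      eta = (.data$E_L - .data$E_H) / 2,
      omega = ifelse(.data$eta > 0, .data$mu^2 / (2 * .data$eta), NA_real_),
      phi = -.data$mu
    )
}

#' Cohesion energy per atom
#'
#' `E_coh = [E_total - sum_e n_e * E_atom(e)] / N`, where the sum runs over
#' the elemental composition and `N` is the total atom count.  More
#' negative values indicate a more cohesive (more strongly bound) cluster.
#'
#' @param data A data frame with columns `label`, `formula` and `E_total`
#'   (eV).
#' @param atomic_ref Named numeric vector of ground-state atomic energies
#'   (eV per atom), e.g. `c(B = -670, N = -1485)`.
#' @return A tibble with columns `label`, `n_atoms`, `E_coh` (eV/atom).
#' @export
cohesion_energy <- function(data, atomic_ref) {
  comp <- parse_formula(data$formula)
  missing_el <- setdiff(unique(unlist(lapply(comp, names))), names(atomic_ref))
  if (length(missing_el) > 0) {
    abort_lookup(paste0(
      "no atomic reference energy for element '", missing_el[1], "'"
    ))
  }
  atoms_sum <- vapply(comp, function(cc) {
    sum(cc * atomic_ref[names(cc)])
  }, numeric(1))
  n_atoms <- vapply(comp, sum, integer(1))
  tibble(
    label = data$label,
    n_atoms = n_atoms,
    E_coh = (data$E_total - atoms_sum) / n_atoms
  )
}

#' Select the reporting spin channel
#'
#' For open-shell species the reported channel is the one with the greater
#' electronic sensitivity, i.e. the channel maximising the relative gap
#' change `|gap_after - gap_before| / gap_before` between the isolated and
#' adsorbed system.  Restricted species report `"restricted"`.
#'
#' @param before,after Data frames with columns `label`, `channel` and
#'   either `E_gap` or (`E_H`, `E_L`); `before` holds the isolated system,
#'   `after` the adsorbed one.  Labels in `after` must match `before`
#'   (complex records should be relabelled to their host before calling,
#'   as [adsorption_table()] does).
#' @return A tibble with columns `label`, `channel` (the selected channel)
#'   and `rel_gap_change`.
#' @export
select_channel <- function(before, after) {
  need_gap <- function(df) {
    if (!"E_gap" %in% names(df)) df <- frontier_descriptors(df)
    df
  }
  b <- need_gap(as_tibble(before)) %>%
    select("label", "channel", gap_before = "E_gap")
  a <- need_gap(as_tibble(after)) %>%
    select("label", "channel", gap_after = "E_gap")
  paired <- inner_join(b, a, by = c("label", "channel"))
  unpaired <- setdiff(unique(b$label), unique(paired$label))
  if (length(unpaired) > 0) {
    abort_validation(paste0(
      "no shared channel between isolated and adsorbed records of '",
      unpaired[1], "'"
    ))
  }
  paired %>%
    mutate(rel_gap_change = abs(.data$gap_after - .data$gap_before) /
             .data$gap_before) %>%
    group_by(.data$label) %>%
    slice_max(.data$rel_gap_change, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("label", "channel", "rel_gap_change")
}

#' Descriptor report for a species table
#'
#' One row per (species, channel) with gap, hardness, chemical potential,
#' electrophilicity, work function, dipole moment and the tagged Cu charge,
#' mirroring the column order of the published descriptor table.
#'
#' @param data Species table.
#' @param digits Number of decimals for reported eV values (default 2, the
#'   precision of the published tables); `NULL` keeps full precision.
#' @return A tibble with columns `label`, `channel`, `E_gap`, `eta`, `mu`,
#'   `omega`, `phi`, `dipole`, `Q_Cu`.
#' @export
descriptor_table <- function(data, digits = 2) {
  out <- frontier_descriptors(data) %>%
    mutate(Q_Cu = charge_of(data, "Cu")) %>%
    select("label", "channel", "E_gap", "eta", "mu", "omega", "phi",
           "dipole", "Q_Cu")
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(
      c("E_gap", "eta", "mu", "omega", "phi"), ~ round(.x, digits)
    ))
  }
  out
}
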