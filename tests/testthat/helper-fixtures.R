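# Shared fixtures and small builders used across the suite.

fx <- paper_fixtures()

# a minimal valid species table built in code
toy_species <- function() {
  tibble::tibble(
    label = c("hostA", "hostA", "guestX", "cplxAX", "cplxAX"),
    role = c("host", "host", "guest", "complex", "complex"),
    formula = c("B12N12", "B12N12", "H2O", "B12N12H2O", "B12N12H2O"),
    E_total = c(-100, -100, -10, -110.5, -110.5),
    G_free = c(-99, -99, -9.5, -109.6, -109.6),
    dipole = c(0.5, 0.5, 1.8, NA, NA),
    multiplicity = c(2L, 2L, 1L, 2L, 2L),
    channel = c("alpha", "beta", "restricted", "alpha", "beta"),
    E_H = c(-5.0, -5.2, -7.0, -4.8, -5.1),
    E_L = c(-2.0, -1.8, 1.0, -1.2, -2.0),
    charges = c("Cu=0.10", "Cu=0.10", NA, "Cu=0.25;guest=0.15",
                "Cu=0.25;guest=0.15")
  )
}

toy_pairs <- function() {
  tibble::tibble(host = "hostA", guest = "guestX", complex = "cplxAX",
                 E_BSSE = 0.1, flag = "")
}

kBT <- function(cond = sensor_conditions()) cond$k_B * cond$temperature

recover_errors <- function(camp, conditions = sensor_conditions()) {
  # relative error of every pipeline metric against the stored ground truth
  purrr::map_dfr(unique(camp$pairs$host), function(h) {
    pr <- camp$pairs[camp$pairs$host == h, ]
    tr <- camp$truth[camp$truth$host == h, ]
    st <- selectivity_table(camp$species, pr, reference = tr$guest[1],
                            conditions = conditions)
    m <- dplyr::inner_join(st, tr, by = "guest", suffix = c("", ".t"))
    tibble::tibble(
      host = h,
      dgap = abs(m$dgap_pct - m$dgap_pct.t),
      dgap_rel = abs(m$dgap_pct - m$dgap_pct.t) / pmax(m$dgap_pct.t, 1e-300),
      dphi_rel = abs(m$dphi_pct - m$dphi_pct.t) / pmax(m$dphi_pct.t, 1e-300),
      S_rel = abs(m$S - m$S.t) / pmax(m$S.t, 1e-300),
      Sj_rel = abs(m$S_j - m$S_j.t) / pmax(m$S_j.t, 1e-300),
      eads_rel = abs(m$E_ads - m$E_ads.t) / abs(m$E_ads.t),
      tau_rel = abs(m$tau - m$tau.t) / m$tau.t,
      kappa_rel = abs(m$kappa - m$kappa.t) / m$kappa.t
    )
  })
}
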