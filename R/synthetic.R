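## Synthetic screening campaigns with analytic ground truth, used to
## validate every pipeline stage end to end.

#' Specification of a synthetic screening campaign
#'
#' Describes the statistical structure of a simulated host/analyte screen:
#' host gaps drawn uniformly from `gap_range`, symmetric adsorption-induced
#' gap and work-function shifts (so both gap opening and closing are
#' exercised), and uniformly drawn negative adsorption energies.  Defaults
#' mirror the value ranges of the packaged nanocage dataset: twelve hosts,
#' nine analytes, host gaps 1.9--6.9 eV, gap shifts up to 1.2 eV,
#' work-function shifts up to 0.8 eV and adsorption energies between
#' -1.9 and -0.05 eV.
#'
#' @param n_hosts,n_guests Number of hosts and analytes.
#' @param gap_range Interval (eV) for host HOMO--LUMO gaps.
#' @param gap_shift_scale Maximum magnitude (eV) of adsorption-induced gap
#'   changes.
#' @param phi_shift_scale Maximum magnitude (eV) of work-function changes.
#' @param eads_range Interval (eV, negative) for adsorption energies.
#' @param noise_sd Standard deviation (eV) of Gaussian noise added to the
#'   orbital energies of the emitted records (0 = noise-free).
#' @param seed Integer seed; identical seeds give identical campaigns.
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(n_hosts = 12, n_guests = 9,
                          gap_range = c(1.9, 6.9),
                          gap_shift_scale = 1.2,
                          phi_shift_scale = 0.8,
                          eads_range = c(-1.9, -0.05),
                          noise_sd = 0, seed = 1L) {
  if (n_hosts < 1 || n_guests < 1) {
    abort_validation("n_hosts and n_guests must be >= 1")
  }
  if (diff(gap_range) <= 0 || diff(eads_range) <= 0) {
    abort_validation("degenerate range in campaign specification")
  }
  if (any(eads_range > 0)) {
    abort_validation("eads_range must be negative (bound complexes)")
  }
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  structure(
    list(n_hosts = as.integer(n_hosts), n_guests = as.integer(n_guests),
         gap_range = gap_range, gap_shift_scale = gap_shift_scale,
         phi_shift_scale = phi_shift_scale, eads_range = eads_range,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "campaign_spec"
  )
}

#' Generate a synthetic screening campaign
#'
#' Builds species and pairs tables in the [load_species_table()] schema
#' together with a ground-truth metric table computed analytically from
#' the sampled parameters.  At `noise_sd = 0` the pipeline
#' ([selectivity_table()] with `digits = NULL`) recovers every stored
#' metric exactly; with noise, recovery degrades gracefully.
#'
#' Hosts alternate between restricted (singlet) and open-shell records;
#' open-shell hosts carry alpha and beta channels with independently
#' shifted gaps, so the channel-selection rule is exercised.  The
#' reference analyte of the stored `kappa`/`kappa_j` columns is the first
#' guest.
#'
#' @param spec A [campaign_spec()].
#' @param conditions [sensor_conditions()] under which the ground-truth
#'   responses are evaluated.
#' @return A list of class `cage_campaign` with elements `species`,
#'   `pairs`, `truth` and `spec`.
#' @export
generate_campaign <- function(spec = campaign_spec(),
                              conditions = sensor_conditions()) {
  stopifnot(inherits(spec, "campaign_spec"))
  conditions <- as_conditions(conditions)
  withr::with_seed(spec$seed, {
    hosts <- generate_hosts(spec)
    guests <- generate_guests(spec)
    cx <- generate_complexes(spec, hosts, guests, conditions)
  })
  species <- bind_rows(hosts$species, guests$species, cx$species)
  validate_species(species)
  if (spec$noise_sd > 0) {
    species <- perturb_species(species, spec$noise_sd,
                               seed = spec$seed + 1L)
  }
  structure(
    list(species = species, pairs = cx$pairs, truth = cx$truth, spec = spec),
    class = "cage_campaign"
  )
}

generate_hosts <- function(spec) {
  n <- spec$n_hosts
  labels <- sprintf("H%03d", seq_len(n))
  open_shell <- seq_len(n) %% 2 == 0
  gap_a <- runif(n, spec$gap_range[1], spec$gap_range[2])
  mu_a <- runif(n, -5, -3)
  gap_b <- pmax(0.3, gap_a + runif(n, -0.4, 0.4))
  mu_b <- mu_a + runif(n, -0.2, 0.2)
  e_tot <- -500 - 10 * seq_len(n)
  rows <- lapply(seq_len(n), function(i) {
    chans <- if (open_shell[i]) {
      tibble(channel = c("alpha", "beta"),
             mu = c(mu_a[i], mu_b[i]), gap = c(gap_a[i], gap_b[i]))
    } else {
      tibble(channel = "restricted", mu = mu_a[i], gap = gap_a[i])
    }
    tibble(
      label = labels[i], role = "host", formula = "B12N12",
      E_total = e_tot[i], G_free = e_tot[i] + 1.5, dipole = NA_real_,
      multiplicity = if (open_shell[i]) 2L else 1L,
      channel = chans$channel,
      E_H = chans$mu - chans$gap / 2, E_L = chans$mu + chans$gap / 2,
      charges = NA_character_
    )
  })
  list(species = bind_rows(rows),
       params = tibble(label = labels, open_shell = open_shell,
                       gap_alpha = gap_a, mu_alpha = mu_a,
                       gap_beta = gap_b, mu_beta = mu_b,
                       E_total = e_tot))
}

generate_guests <- function(spec) {
  n <- spec$n_guests
  labels <- sprintf("G%03d", seq_len(n))
  gap <- runif(n, 6, 10)
  mu <- runif(n, -4, -2)
  e_tot <- -100 - 10 * seq_len(n)
  species <- tibble(
    label = labels, role = "guest", formula = "C5H14N2",
    E_total = e_tot, G_free = e_tot + 2, dipole = NA_real_,
    multiplicity = 1L, channel = "restricted",
    E_H = mu - gap / 2, E_L = mu + gap / 2, charges = NA_character_
  )
  list(species = species,
       params = tibble(label = labels, E_total = e_tot))
}

generate_complexes <- function(spec, hosts, guests, conditions) {
  hp <- hosts$params
  gp <- guests$params
  kT <- conditions$k_B * conditions$temperature
  species <- list()
  pairs <- list()
  truth <- list()
  k <- 0
  for (i in seq_len(nrow(hp))) {
    for (j in seq_len(nrow(gp))) {
      k <- k + 1
      lab <- paste0(hp$label[i], "-", gp$label[j])
      two <- hp$open_shell[i]
      chans <- if (two) c("alpha", "beta") else "restricted"
      gap_h <- if (two) c(hp$gap_alpha[i], hp$gap_beta[i]) else hp$gap_alpha[i]
      mu_h <- if (two) c(hp$mu_alpha[i], hp$mu_beta[i]) else hp$mu_alpha[i]
      gap_c <- pmax(0.05, gap_h +
                      runif(length(chans), -1, 1) * spec$gap_shift_scale)
      phi_h <- -mu_h
      phi_c <- pmax(0.5, phi_h +
                      runif(length(chans), -1, 1) * spec$phi_shift_scale)
      mu_c <- -phi_c
      e_ads <- runif(1, spec$eads_range[1], spec$eads_range[2])
      e_bsse <- runif(1, 0, 0.05)
      dg_ads <- e_ads + runif(1, 0, 0.3)
      e_cx <- hp$E_total[i] + gp$E_total[j] + e_ads - e_bsse
      g_cx <- (hp$E_total[i] + 1.5) + (gp$E_total[j] + 2) + dg_ads
      species[[k]] <- tibble(
        label = lab, role = "complex",
        formula = "B12N12C5H14N2",
        E_total = e_cx, G_free = g_cx, dipole = NA_real_,
        multiplicity = if (two) 2L else 1L,
        channel = chans,
        E_H = mu_c - gap_c / 2, E_L = mu_c + gap_c / 2,
        charges = NA_character_
      )
      pairs[[k]] <- tibble(host = hp$label[i], guest = gp$label[j],
                           complex = lab, E_BSSE = e_bsse, flag = "")
      rel <- abs(gap_c - gap_h) / gap_h
      sel <- which.max(rel)
      truth[[k]] <- tibble(
        host = hp$label[i], guest = gp$label[j], complex = lab,
        channel = chans[sel],
        gap_host = gap_h[sel], gap_complex = gap_c[sel],
        dgap_pct = 100 * rel[sel],
        phi_host = phi_h[sel], phi_complex = phi_c[sel],
        dphi_pct = 100 * abs(phi_c[sel] - phi_h[sel]) / phi_h[sel],
        E_ads = e_ads, dG_ads = dg_ads,
        S = exp(abs(gap_c[sel] - gap_h[sel]) / (2 * kT)) - 1,
        S_j = exp(abs(phi_c[sel] - phi_h[sel]) / kT) - 1,
        tau = exp(-e_ads / kT) / conditions$nu0
      )
    }
  }
  truth <- bind_rows(truth) %>%
    group_by(.data$host) %>%
    mutate(
      kappa = .data$S[.data$guest == gp$label[1]] / .data$S,
      kappa_j = ifelse(.data$S_j == 0, NA_real_,
                       .data$S_j[.data$guest == gp$label[1]] / .data$S_j)
    ) %>%
    ungroup()
  list(species = bind_rows(species), pairs = bind_rows(pairs), truth = truth)
}

#' Perturb orbital energies with Gaussian noise
#'
#' Adds independent `N(0, noise_sd)` noise to every `E_H` and `E_L` entry,
#' emulating numerical scatter in the electronic-structure inputs; used to
#' study the stability of the derived metrics.  After perturbation `E_L`
#' is clamped to stay at or above `E_H` so the records remain valid.
#'
#' @param species Species table.
#' @param noise_sd Noise standard deviation (eV); 0 returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @return The perturbed species table.
#' @export
perturb_species <- function(species, noise_sd, seed = 1L) {
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (noise_sd == 0) return(species)
  withr::with_seed(seed, {
    n <- nrow(species)
    species$E_H <- species$E_H + rnorm(n, 0, noise_sd)
    species$E_L <- species$E_L + rnorm(n, 0, noise_sd)
  })
  species$E_L <- pmax(species$E_L, species$E_H)
  species
}
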