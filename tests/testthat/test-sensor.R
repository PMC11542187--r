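cond <- sensor_conditions()

test_that("conductivity follows the activated-transport form", {
  expect_equal(conductivity(0, cond), cond$A_sigma * cond$temperature^1.5,
               tolerance = 1e-12)
  gaps <- seq(0.5, 6, by = 0.5)
  expect_true(all(diff(conductivity(gaps, cond)) < 0))
  # ratio evaluates the Boltzmann factor of half the gap difference
  r <- conductivity(3.04, cond) / conductivity(4.25, cond)
  expect_equal(r, exp((4.25 - 3.04) / (2 * kBT(cond))), tolerance = 1e-12)
  expect_equal(r, 1.67e10, tolerance = 0.01)
  expect_error(conductivity(1, sensor_conditions(temperature = -1)),
               class = "cagesense_domain_error")
})

test_that("current density follows the Richardson-Dushman form", {
  expect_equal(current_density(0, cond), cond$A_rd * cond$temperature^2,
               tolerance = 1e-12)
  phis <- seq(2, 6, by = 0.5)
  expect_true(all(diff(current_density(phis, cond)) < 0))
  r <- current_density(2.46, cond) / current_density(3.25, cond)
  expect_equal(r, exp((3.25 - 2.46) / kBT(cond)), tolerance = 1e-12)
})

test_that("sensor response equals the brute-force resistance-change oracle", {
  # oracle: R = 1/sigma with the explicit conductivity law
  oracle <- function(gap_host, gap_complex) {
    r_before <- 1 / conductivity(gap_host, cond)
    r_after <- 1 / conductivity(gap_complex, cond)
    abs(r_after - r_before) / min(r_before, r_after)
  }
  withr::with_seed(11, {
    gh <- runif(50, 1, 6)
    gc <- pmax(0.05, gh + runif(50, -1.5, 1.5))
  })
  s_closed <- sensor_response(gh, gc, cond)
  s_brute <- mapply(oracle, gh, gc)
  expect_equal(s_closed, s_brute, tolerance = 1e-12)
})

test_that("sensor response is symmetric and zero for an unchanged gap", {
  expect_identical(sensor_response(3.0, 3.0, cond), 0)
  expect_equal(sensor_response(3.04, 4.25, cond),
               sensor_response(4.25, 3.04, cond), tolerance = 1e-12)
  # gap opening and closing of equal size respond identically
  expect_equal(sensor_response(3.04, 3.04 + 1.10, cond),
               sensor_response(3.04, 3.04 - 1.10, cond), tolerance = 1e-12)
})

test_that("work-function response matches its closed form", {
  expect_equal(wf_response(3.25, 2.46, cond),
               exp(0.79 / kBT(cond)) - 1, tolerance = 1e-9)
  expect_equal(wf_response(3.25, 2.46, cond), 2.2e13, tolerance = 0.03)
  expect_identical(wf_response(3.25, 3.25, cond), 0)
  expect_equal(wf_response(3.25, 2.75, cond),
               exp(0.50 / kBT(cond)) - 1, tolerance = 1e-9)
})

test_that("selectivity coefficients are self-consistent", {
  expect_identical(selectivity_coefficient(5, 5), 1)
  s <- c(1.7e10, 2e9, 7.4e8)
  expect_equal(selectivity_coefficient(s[1], s[2]) *
                 selectivity_coefficient(s[2], s[1]), 1, tolerance = 1e-12)
  expect_true(is.na(selectivity_coefficient(5, 0)))
  expect_error(selectivity_coefficient(-1, 2),
               class = "cagesense_domain_error")
})

test_that("responses and selectivities are prefactor invariant", {
  for (scale in 10^c(-3, 0, 3)) {
    ca <- sensor_conditions(A_sigma = scale, A_rd = 120.1 * scale)
    expect_equal(sensor_response(3.04, 4.25, ca),
                 sensor_response(3.04, 4.25, cond), tolerance = 1e-12)
    expect_equal(wf_response(3.25, 2.46, ca),
                 wf_response(3.25, 2.46, cond), tolerance = 1e-12)
  }
})

test_that("recovery time follows transition-state theory", {
  expect_equal(recovery_time(0, cond), 1 / cond$nu0, tolerance = 1e-12)
  tau <- recovery_time(-1.39, cond)
  expect_equal(tau, exp(1.39 / kBT(cond)) / 5.2e14, tolerance = 1e-12)
  expect_equal(tau, 5.9e8, tolerance = 0.01)
  expect_gt(tau, 12 * 3600) # far above 12 h at room temperature
  # colder sensors recover more slowly for a bound analyte
  expect_gt(recovery_time(-1.39, sensor_conditions(temperature = 280)),
            recovery_time(-1.39, sensor_conditions(temperature = 320)))
})

test_that("recovery scan is an Arrhenius family over (T, nu0)", {
  one <- recovery_scan(-1.39, temperatures = 500, nu0 = 5.2e14)
  expect_identical(nrow(one), 1L)
  expect_equal(one$tau, recovery_time(-1.39, sensor_conditions(temperature = 500)),
               tolerance = 1e-12)

  scan <- recovery_scan(-1.39, temperatures = seq(350, 650, by = 25),
                        nu0 = c(5.2e14, 1.04e15))
  # log tau vs 1/T is affine with slope -E_ads/kB for each nu0
  for (nu in unique(scan$nu0)) {
    s <- scan[scan$nu0 == nu, ]
    fit <- stats::lm(log(tau) ~ I(1 / temperature), data = s)
    expect_equal(unname(stats::coef(fit)[2]), 1.39 / cond$k_B,
                 tolerance = 1e-9)
  }
  # doubling the attempt frequency halves tau at every temperature
  wide <- tidyr::pivot_wider(scan, names_from = "nu0", values_from = "tau")
  expect_equal(wide[[2]] / wide[[3]], rep(2, nrow(wide)), tolerance = 1e-12)
})

test_that("the interferent screen ranks the diamine first on the cage", {
  intf <- fx$pairs[fx$pairs$host == "Cu(b64)B12N12", ]
  sel <- selectivity_table(fx$species, intf, reference = "Cad")
  unflagged <- sel[sel$flag == "", ]
  expect_identical(unflagged$guest[1], "Cad")
  expect_identical(unflagged$guest[nrow(unflagged)], "N2")
  expect_true(all(diff(unflagged$dgap_pct) <= 0))
  # the reference analyte scores unit selectivity against itself
  expect_identical(unflagged$kappa[1], 1)
  expect_identical(unflagged$kappa_j[1], 1)
  # CO leaves the work function unchanged: zero response, undefined kappa_j
  co <- sel[sel$guest == "CO", ]
  expect_identical(co$S_j, 0)
  expect_true(is.na(co$kappa_j))
})

test_that("a single-analyte screen reports unit selectivity", {
  pr <- fx$pairs[fx$pairs$complex == "Cu(b64)B12N12-Cad", ]
  sel <- selectivity_table(fx$species, pr, reference = "Cad")
  expect_identical(sel$kappa, 1)
  expect_identical(sel$kappa_j, 1)
})

test_that("selectivity screen rejects bad configurations", {
  intf <- fx$pairs[fx$pairs$host == "Cu(b64)B12N12", ]
  expect_error(selectivity_table(fx$species, intf, reference = "Xe"),
               "Xe", class = "cagesense_lookup_error")
  expect_error(selectivity_table(fx$species, fx$pairs, reference = "Cad"),
               "single host", class = "cagesense_validation_error")
})
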