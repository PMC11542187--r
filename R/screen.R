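## End-to-end screening: descriptor, adsorption and selectivity reports,
## recovery scan and spectra in one bundle, with broom-style accessors.

#' Run the full screening pipeline
#'
#' Ties the stages together: per-species descriptor report, adsorption
#' report for every pair, ranked selectivity table against a reference
#' analyte, recovery-time scan for the most strongly bound pair, and
#' broadened UV-vis spectra with peak annotations when transitions are
#' supplied.  With an empty pairs table a descriptor-only report is
#' produced with a warning.
#'
#' @param species Species table (see [load_species_table()]).
#' @param pairs Pairs table; may be empty.
#' @param reference Guest label of the reference analyte for the
#'   selectivity stage; `NULL` skips that stage.
#' @param transitions Optional transitions table for the spectra stage.
#' @param conditions [sensor_conditions()].
#' @param atomic_ref Optional named vector of atomic energies; when given,
#'   cohesion energies are reported for the hosts.
#' @param gibbs Compute Gibbs adsorption energies in the adsorption stage?
#' @param digits Reporting precision (decimals) of the descriptor table's
#'   eV columns (default 2); `NULL` for full precision.  Percentages and
#'   responses are always computed at full precision.
#' @param scan_temperatures Temperature grid (K) of the recovery scan.
#' @param fwhm Broadening width (eV) for the spectra stage.
#' @return An object of class `cage_screen`: a list with elements
#'   `descriptors`, `cohesion`, `adsorption`, `selectivity`, `recovery`,
#'   `spectra`, `peaks` and `conditions`.
#' @examples
#' fx <- paper_fixtures()
#' scr <- run_screen(fx$species, fx$pairs, reference = "Cad",
#'                   transitions = fx$transitions)
#' glance(scr)
#' @export
run_screen <- function(species, pairs, reference = NULL,
                       transitions = NULL,
                       conditions = sensor_conditions(),
                       atomic_ref = NULL, gibbs = FALSE, digits = 2,
                       scan_temperatures = seq(350, 650, by = 5),
                       fwhm = 0.33) {
  conditions <- as_conditions(conditions)
  validate_species(species)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cs_abort(paste0("stage '", name, "': ", conditionMessage(e)),
               "cagesense_stage_error")
    })
  }
  descriptors <- stage("descriptors", descriptor_table(species, digits = digits))
  cohesion <- if (!is.null(atomic_ref)) {
    stage("cohesion",
          cohesion_energy(filter(species, .data$role == "host"), atomic_ref))
  }
  adsorption <- selectivity <- recovery <- NULL
  if (is.null(pairs) || nrow(pairs) == 0) {
    warn("empty pairs table: descriptor-only report")
  } else {
    adsorption <- stage("adsorption",
                        adsorption_table(species, pairs, gibbs = gibbs))
    if (!is.null(reference)) {
      selectivity <- stage("selectivity",
                           selectivity_table(species, pairs, reference,
                                             conditions = conditions))
    }
    strongest <- adsorption$E_ads[which.min(adsorption$E_ads)]
    recovery <- stage("recovery",
                      recovery_scan(strongest,
                                    temperatures = scan_temperatures,
                                    conditions = conditions))
  }
  spectra <- peaks <- NULL
  if (!is.null(transitions) && nrow(transitions) > 0) {
    spectra <- stage("spectra", {
      split(as_tibble(transitions), transitions$label) |>
        lapply(broaden_spectrum, fwhm = fwhm)
    })
    peaks <- tibble(
      label = names(spectra),
      lambda_max = vapply(spectra, lambda_max, numeric(1))
    )
  }
  structure(
    list(descriptors = descriptors, cohesion = cohesion,
         adsorption = adsorption, selectivity = selectivity,
         recovery = recovery, spectra = spectra, peaks = peaks,
         conditions = conditions),
    class = "cage_screen"
  )
}

#' @export
print.cage_screen <- function(x, ...) {
  cat("<cage_screen>\n")
  print(x$conditions)
  cat(sprintf("  descriptors: %d species rows\n", nrow(x$descriptors)))
  if (!is.null(x$adsorption)) {
    cat(sprintf("  adsorption:  %d pairs\n", nrow(x$adsorption)))
  }
  if (!is.null(x$selectivity)) {
    ref <- attr(x$selectivity, "reference")
    cat(sprintf("  selectivity: %d analytes (reference: %s)\n",
                nrow(x$selectivity), ref))
    sel <- x$selectivity
    if (any(sel$flag == "")) sel <- sel[sel$flag == "", ]
    top <- sel[1, ]
    cat(sprintf("    top analyte %s: dgap %.2f%%, S = %s, S_j = %s\n",
                top$guest, top$dgap_pct, format_response(top$S),
                format_response(top$S_j)))
  }
  if (!is.null(x$peaks)) {
    cat(sprintf("  spectra:     %d systems (lambda_max %s nm)\n",
                nrow(x$peaks),
                paste(format(x$peaks$lambda_max, trim = TRUE),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `cage_screen`.
#' @param table Which component to return: `"selectivity"` (default),
#'   `"descriptors"`, `"adsorption"`, `"cohesion"`, `"recovery"` or
#'   `"peaks"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cage_screen
#' @export
tidy.cage_screen <- function(x, table = c("selectivity", "descriptors",
                                          "adsorption", "cohesion",
                                          "recovery", "peaks"), ...) {
  table <- match.arg(table)
  out <- x[[table]]
  if (is.null(out)) {
    abort_lookup(paste0("screen has no '", table, "' component"))
  }
  as_tibble(out)
}

#' One-row summary of a screening result
#'
#' @param x A `cage_screen`.
#' @param ... Unused.
#' @return A tibble with one row: species/pair counts, the most sensitive
#'   analyte and its responses, the strongest binding energy and its
#'   room-temperature recovery time.
#' @method glance cage_screen
#' @export
glance.cage_screen <- function(x, ...) {
  sel <- x$selectivity
  ads <- x$adsorption
  # flagged rows carry values known to be inconsistent; rank without them
  if (!is.null(sel) && any(sel$flag == "")) sel <- sel[sel$flag == "", ]
  tibble(
    n_species = nrow(x$descriptors),
    n_pairs = if (is.null(ads)) 0L else nrow(ads),
    top_analyte = if (is.null(sel)) NA_character_ else sel$guest[1],
    max_dgap_pct = if (is.null(sel)) NA_real_ else max(sel$dgap_pct),
    max_S = if (is.null(sel)) NA_real_ else max(sel$S),
    max_S_j = if (is.null(sel)) NA_real_ else max(sel$S_j),
    min_E_ads = if (is.null(ads)) NA_real_ else min(ads$E_ads),
    tau_s = if (is.null(ads)) NA_real_ else
      recovery_time(min(ads$E_ads), x$conditions)
  )
}

#' Write a screening report bundle to disk
#'
#' Emits the tabular components as deterministic delimited files and/or a
#' single JSON document (full precision).  Two runs on identical inputs
#' produce byte-identical delimited outputs.
#'
#' @param x A `cage_screen`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
write_screen <- function(x, dir, formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(descriptors = x$descriptors, cohesion = x$cohesion,
                 adsorption = x$adsorption, selectivity = x$selectivity,
                 recovery = x$recovery, peaks = x$peaks)
  tables <- tables[!vapply(tables, is.null, logical(1))]
  paths <- character(0)
  if ("csv" %in% formats) {
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(as_tibble(tables[[nm]]), p, progress = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "screen.json")
    payload <- c(lapply(tables, as.data.frame),
                 list(conditions = unclass(x$conditions)))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
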