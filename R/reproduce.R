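# Orchestration of the full study matrix: {open, brass, cerrobend} x
# {10x10, 20x20} phantom runs, the TPR two-geometry pairs, and the in-air
# attenuation pair, plus the side-by-side comparison against the published
# values.

#' Published reference values for the study comparison
#'
#' The printed dosimetric characteristics (TPR20/10, d_max, output factor,
#' spatial fraction, average energies, in-air fluences) used by
#' [reproduce_study()] for its side-by-side table.
#'
#' @return Tibble with columns `quantity`, `field`, `modality`, `paper`.
#' @export
reference_values <- function() {
  tibble::tribble(
    ~quantity, ~field, ~modality, ~paper,
    "tpr_20_10", "10x10", "open", 0.678,
    "tpr_20_10", "10x10", "brass", 0.648,
    "tpr_20_10", "10x10", "cerrobend", 0.645,
    "d_max_mm", "10x10", "open", 15.5,
    "d_max_mm", "20x20", "open", 14.5,
    "d_max_mm", "10x10", "brass", 13.5,
    "d_max_mm", "10x10", "cerrobend", 13.5,
    "output_factor", "10x10", "open", 1.000,
    "output_factor", "20x20", "open", 1.045,
    "output_factor", "10x10", "brass", 0.782,
    "output_factor", "10x10", "cerrobend", 0.772,
    "output_factor", "20x20", "brass", 0.813,
    "output_factor", "20x20", "cerrobend", 0.790,
    "spatial_fraction", "10x10", "brass", 0.23,
    "spatial_fraction", "10x10", "cerrobend", 0.17,
    "spatial_fraction", "20x20", "brass", 0.26,
    "spatial_fraction", "20x20", "cerrobend", 0.20,
    "avg_energy_1.5cm_mev", "10x10", "open", 1.47,
    "avg_energy_1.5cm_mev", "10x10", "brass", 1.77,
    "inair_fluence_1e7_per_cm2_mu", "10x10", "open", 6.95,
    "inair_fluence_1e7_per_cm2_mu", "10x10", "brass", 3.15
  )
}

modality_grid <- function(modality) {
  switch(modality, open = NULL, grid_spec(material = modality))
}

#' Reproduce the study's experiment matrix
#'
#' Runs the six phantom experiments ({open, brass, cerrobend} x {10x10,
#' 20x20} at SSD 100), the six TPR20/10 two-geometry run pairs, and the
#' in-air attenuation pair, then assembles the dosimetric quantities and a
#' comparison table against the published values.
#'
#' @param scale Histories multiplier; `scale = 1` uses 2e6 histories per
#'   run (the package's desk-scale default).
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV/JSON exports.
#' @param modalities,fields Subsets of the matrix to run.
#' @return A list of class `gridrt_report`: `runs` (named list),
#'   `comparison` (tibble with simulated value, sigma and paper value),
#'   `calibration`.
#' @export
reproduce_study <- function(scale = 1, seed = 1, out_dir = NULL,
                            modalities = c("open", "brass", "cerrobend"),
                            fields = c(10, 20)) {
  n <- max(10, round(2e6 * scale))
  runs <- list()
  for (f in fields) for (mo in modalities) {
    key <- sprintf("%s_%d", mo, f)
    runs[[key]] <- run_simulation(
      beam_spec(field_cm = c(f, f)), modality_grid(mo),
      transport_config(n_histories = n, seed = seed, ssd = 100))
    for (ssd in c(80, 90)) {
      runs[[sprintf("%s_%d_ssd%d", mo, f, ssd)]] <- run_simulation(
        beam_spec(field_cm = c(f, f)), modality_grid(mo),
        transport_config(n_histories = n, seed = seed, ssd = ssd))
    }
  }
  for (mo in intersect(modalities, c("open", "brass"))) {
    runs[[sprintf("inair_%s", mo)]] <- run_simulation(
      beam_spec(field_cm = c(10, 10)), modality_grid(mo),
      transport_config(n_histories = n, seed = seed), phantom = FALSE)
  }

  cal <- if ("open_10" %in% names(runs)) mu_calibration(runs$open_10)

  rows <- list()
  add <- function(quantity, field, modality, value, sigma = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble(quantity = quantity, field = field,
                                        modality = modality,
                                        simulated = value, sigma = sigma)
  }
  ref_dmax <- NULL
  for (f in fields) for (mo in modalities) {
    key <- sprintf("%s_%d", mo, f)
    if (is.null(runs[[key]])) next
    fld <- sprintf("%dx%d", f, f)
    fit <- pdd_and_dmax(pdd_curve(runs[[key]]))
    add("d_max_mm", fld, mo, fit$d_max_mm, 1.0)
    if (!is.null(cal)) {
      of <- output_factor(fit$max_value, cal$dose_max)
      add("output_factor", fld, mo, of$value, of$sigma)
    }
    p80 <- runs[[sprintf("%s_%d_ssd80", mo, f)]]
    p90 <- runs[[sprintf("%s_%d_ssd90", mo, f)]]
    if (!is.null(p80) && !is.null(p90)) {
      tpr <- tpr_20_10(p80, p90)
      add("tpr_20_10", fld, mo, tpr$value, tpr$sigma)
    }
    if (mo != "open") {
      sf <- spatial_fraction(lateral_profile(runs[[key]]), pitch = 2.2)
      add("spatial_fraction", fld, mo, sf$value)
    }
    ae <- average_energy(spectrum_table(runs[[key]], "photon", 1.5))
    add("avg_energy_1.5cm_mev", fld, mo, ae)
  }
  for (mo in intersect(modalities, c("open", "brass"))) {
    key <- sprintf("inair_%s", mo)
    if (is.null(runs[[key]]) || is.null(cal)) next
    fl <- in_air_fluence(runs[[key]])
    tot <- fl$value[fl$tag == "total"] * cal$histories_per_mu / 1e7
    add("inair_fluence_1e7_per_cm2_mu", "10x10", mo, tot,
        fl$sigma[fl$tag == "total"] * cal$histories_per_mu / 1e7)
  }
  comparison <- left_join(bind_rows(rows), reference_values(),
                          by = c("quantity", "field", "modality"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    for (key in names(runs)) {
      if (isTRUE(runs[[key]]$phantom))
        write_curve(pdd_curve(runs[[key]]),
                    file.path(out_dir, sprintf("pdd_%s.csv", key)),
                    units = c(depth = "cm", value = "MeV/g/history"))
    }
  }
  structure(list(runs = runs, comparison = comparison, calibration = cal),
            class = "gridrt_report")
}

#' @export
print.gridrt_report <- function(x, ...) {
  cat("<gridrt_report>\n")
  print(as.data.frame(x$comparison), digits = 3)
  invisible(x)
}

#' @export
tidy.gridrt_report <- function(x, ...) x$comparison
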