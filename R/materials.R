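# Cross sections, stopping powers and material mixtures.
#
# Per-element photon partial mass cross sections (photoelectric, incoherent,
# coherent, pair) and electron collision stopping powers are shipped as
# plain-text fixtures under extdata/ (regenerated by
# tools/make-physics-tables.R).  Materials are weight-fraction mixtures of
# those elements; every lookup applies the mixture rule exactly, so a blend
# of two materials is the convex combination of its components at every
# energy.

PHOTON_EMIN <- 0.01
PHOTON_EMAX <- 6.02
ELECTRON_EMIN <- 0.5
ELECTRON_EMAX <- 6.02
PAIR_THRESHOLD <- 2 * 0.51099895

element_data <- function() {
  if (is.null(the$elements)) {
    path <- function(f) system.file("extdata", f, package = "gridrt",
                                    mustWork = TRUE)
    the$elements <- list(
      photon   = read.delim(path("photon_xs.tsv")),
      electron = read.delim(path("electron_sp.tsv")),
      transfer = read.delim(path("compton_transfer.tsv"))
    )
  }
  the$elements
}

list_elements <- function() unique(element_data()$photon$element)

#' Define a material from element weight fractions
#'
#' A material is a density plus a weight-fraction composition over the
#' elements in the embedded physics tables.  Attenuation and stopping-power
#' lookups for the material obey the mixture (Bragg additivity) rule: the
#' mass coefficient is the weight-fraction sum of elemental coefficients.
#'
#' @param composition Named numeric vector of element weight fractions
#'   (e.g. `c(Zn = 0.37, Cu = 0.63)`).  Must be positive and sum to 1
#'   within `1e-9`; no silent renormalization is performed.
#' @param density Mass density in g/cm^3.
#' @param name Optional identifier.
#' @return An object of class `gridrt_material`.
#' @examples
#' brass <- material(c(Zn = 0.37, Cu = 0.63), density = 8.49, name = "brass")
#' mu_total(brass, 2.0)
#' @export
material <- function(composition, density, name = NULL) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    abort("`composition` must be a named vector of element weight fractions")
  unknown <- setdiff(names(composition), list_elements())
  if (length(unknown))
    abort(paste0("unknown element(s) in composition: ",
                 paste(unknown, collapse = ", ")))
  if (any(composition <= 0)) abort("weight fractions must be positive")
  if (abs(sum(composition) - 1) > 1e-9)
    abort(sprintf("weight fractions must sum to 1 (got %.12g)",
                  sum(composition)))
  if (!is.numeric(density) || length(density) != 1 || density <= 0)
    abort("`density` must be a single positive number")
  structure(list(name = name %||% "custom",
                 density = density,
                 composition = composition),
            class = "gridrt_material")
}

#' @export
print.gridrt_material <- function(x, ...) {
  cat(sprintf("<gridrt_material> %s, density %.4g g/cm^3\n", x$name, x$density))
  comp <- paste(sprintf("%s %.4g", names(x$composition), x$composition),
                collapse = ", ")
  cat(" composition:", comp, "\n")
  invisible(x)
}

# handbook densities; all overridable through material()
MATERIAL_REGISTRY <- list(
  water     = list(composition = c(H = 0.111894, O = 0.888106), density = 1.000),
  brass     = list(composition = c(Zn = 0.37, Cu = 0.63), density = 8.49),
  cerrobend = list(composition = c(Cd = 0.10, Sn = 0.133, Pb = 0.267,
                                   Bi = 0.50), density = 9.38),
  pmma      = list(composition = c(H = 0.080538, C = 0.599848, O = 0.319614),
                   density = 1.19),
  air       = list(composition = c(C = 0.000124, N = 0.755267, O = 0.231781,
                                   Ar = 0.012827), density = 0.0012)
)

#' Look up a predefined material by name
#'
#' @param name One of `"water"`, `"brass"`, `"cerrobend"`, `"pmma"`, `"air"`.
#' @param density Optional density override (g/cm^3).
#' @return A `gridrt_material`.
#' @export
gr_material <- function(name, density = NULL) {
  name <- match.arg(name, names(MATERIAL_REGISTRY))
  entry <- MATERIAL_REGISTRY[[name]]
  material(entry$composition, density %||% entry$density, name = name)
}

# log-log interpolation of one element/process column; pair is interpolated
# linearly in value (it is exactly zero below threshold)
interp_process <- function(egrid, values, energy, loglog = TRUE) {
  if (loglog && all(values > 0)) {
    exp(approx(log(egrid), log(values), log(energy), rule = 2)$y)
  } else {
    pmax(0, approx(log(egrid), values, log(energy), rule = 2)$y)
  }
}

check_photon_energy <- function(energy) {
  if (any(energy < PHOTON_EMIN - 1e-12 | energy > PHOTON_EMAX + 1e-12))
    abort(sprintf(
      "photon energy outside the tabulated span [%.3g, %.3g] MeV",
      PHOTON_EMIN, PHOTON_EMAX))
}

# mass attenuation partials for a material, cm^2/g, tibble column per process
mass_mu_partials <- function(material, energy) {
  check_photon_energy(energy)
  tab <- element_data()$photon
  out <- matrix(0, length(energy), 4,
                dimnames = list(NULL, c("photoelectric", "incoherent",
                                        "coherent", "pair")))
  for (el in names(material$composition)) {
    w <- material$composition[[el]]
    sub <- tab[tab$element == el, ]
    out[, "photoelectric"] <- out[, "photoelectric"] +
      w * interp_process(sub$energy_mev, sub$pe, energy)
    out[, "incoherent"] <- out[, "incoherent"] +
      w * interp_process(sub$energy_mev, sub$incoherent, energy)
    out[, "coherent"] <- out[, "coherent"] +
      w * interp_process(sub$energy_mev, sub$coherent, energy)
    out[, "pair"] <- out[, "pair"] +
      w * interp_process(sub$energy_mev, sub$pair, energy, loglog = FALSE)
  }
  out[, "pair"][energy <= PAIR_THRESHOLD] <- 0
  out
}

#' Linear attenuation coefficient with per-process partials
#'
#' Log-log interpolates the embedded elemental cross sections, applies the
#' weight-fraction mixture rule and scales by the material density.
#'
#' @param material A `gridrt_material`.
#' @param energy Photon energies in MeV, within `[0.01, 6.02]`.
#' @return A tibble with columns `energy`, `photoelectric`, `incoherent`,
#'   `coherent`, `pair` and `total`, all in 1/cm; `total` is the exact sum
#'   of the partials.
#' @export
mu_total <- function(material, energy) {
  stopifnot(inherits(material, "gridrt_material"))
  p <- mass_mu_partials(material, energy) * material$density
  tibble(energy = energy,
         photoelectric = p[, 1], incoherent = p[, 2],
         coherent = p[, 3], pair = p[, 4],
         total = rowSums(p))
}

#' Sample the interaction process at a given energy
#'
#' Draws interaction process labels with probabilities proportional to the
#' per-process attenuation partials of the material at that energy.
#'
#' @param material A `gridrt_material`.
#' @param energy A single photon energy in MeV.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Character vector of process labels among `"photoelectric"`,
#'   `"incoherent"`, `"coherent"`, `"pair"`.
#' @export
sample_interaction <- function(material, energy, n = 1, seed = 1) {
  stopifnot(length(energy) == 1)
  p <- mass_mu_partials(material, energy)[1, ]
  if (!is.null(seed)) set.seed(seed)
  sample(names(p), n, replace = TRUE, prob = p / sum(p))
}

#' Sample Compton scattering kinematics (Klein-Nishina)
#'
#' Samples scattered-photon energies and polar angles from the free-electron
#' Klein-Nishina differential cross section, with the scattered energy tied
#' to the angle by Compton kinematics
#' \eqn{E' = E / (1 + (E/m_ec^2)(1 - \cos\theta))}.
#'
#' @param energy Incident photon energy in MeV (single value, > 0).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A tibble with columns `energy` (scattered photon, MeV) and
#'   `theta` (polar scattering angle, rad).
#' @export
sample_klein_nishina <- function(energy, n = 1, seed = 1) {
  stopifnot(length(energy) == 1, energy > 0)
  as_tibble(cpp_kn_sample(energy, as.integer(n), as.integer(seed)))
}

check_electron_energy <- function(energy) {
  if (any(energy < ELECTRON_EMIN - 1e-12 | energy > ELECTRON_EMAX + 1e-12))
    abort(sprintf(
      "electron energy outside the transport window [%.3g, %.3g] MeV",
      ELECTRON_EMIN, ELECTRON_EMAX))
}

# mass collision stopping power, MeV cm^2/g
mass_stopping_power <- function(material, energy) {
  check_electron_energy(energy)
  tab <- element_data()$electron
  s <- numeric(length(energy))
  for (el in names(material$composition)) {
    sub <- tab[tab$element == el, ]
    s <- s + material$composition[[el]] *
      interp_process(sub$energy_mev, sub$scol, energy)
  }
  s
}

#' Electron stopping power and residual CSDA range
#'
#' Total (collision) stopping power of the material and the residual
#' continuous-slowing-down range down to the 0.5 MeV transport cutoff,
#' obtained by trapezoid integration of `1/S` over the embedded grid.
#'
#' @param material A `gridrt_material`.
#' @param energy Electron energies in MeV within `[0.5, 6.02]`.
#' @return A tibble with columns `energy` (MeV), `stopping_power` (MeV/cm)
#'   and `csda_range` (cm, residual range to the transport cutoff).
#' @export
electron_stopping_and_range <- function(material, energy) {
  stopifnot(inherits(material, "gridrt_material"))
  check_electron_energy(energy)
  egrid <- exp(seq(log(ELECTRON_EMIN), log(ELECTRON_EMAX), length.out = 400))
  s_mass <- mass_stopping_power(material, egrid)      # MeV cm^2/g
  inv <- 1 / s_mass
  cum <- c(0, cumsum(diff(egrid) * (head(inv, -1) + tail(inv, -1)) / 2))
  range_mass <- approx(egrid, cum, energy)$y           # g/cm^2
  tibble(energy = energy,
         stopping_power = mass_stopping_power(material, energy) *
           material$density,
         csda_range = range_mass / material$density)
}

# Klein-Nishina mean energy-transfer fraction (embedded quadrature table)
compton_transfer_fraction <- function(energy) {
  tab <- element_data()$transfer
  approx(log(tab$energy_mev), tab$f_compton, log(pmin(pmax(energy,
         PHOTON_EMIN), PHOTON_EMAX)), rule = 2)$y
}

# energy-transfer coefficient (1/cm) used by the track-length kerma estimator
mu_transfer <- function(material, energy) {
  p <- mass_mu_partials(material, energy) * material$density
  f_pair <- ifelse(energy > PAIR_THRESHOLD,
                   (energy - PAIR_THRESHOLD) / energy, 0)
  p[, "photoelectric"] + p[, "incoherent"] * compton_transfer_fraction(energy) +
    p[, "pair"] * f_pair
}

# fine uniform-log-grid table handed to the C++ core
fine_mu_table <- function(material, n = 600) {
  egrid <- exp(seq(log(PHOTON_EMIN), log(PHOTON_EMAX), length.out = n))
  p <- mass_mu_partials(material, egrid) * material$density
  zeff <- {
    tabz <- element_data()$photon
    zs <- vapply(names(material$composition), function(el)
      tabz$Z[match(el, tabz$element)], 0)
    as_ <- vapply(names(material$composition), function(el)
      tabz$A[match(el, tabz$element)], 0)
    w <- material$composition
    sum(w / as_ * zs^2) / sum(w / as_ * zs)
  }
  list(logE0 = log(PHOTON_EMIN),
       dlogE = (log(PHOTON_EMAX) - log(PHOTON_EMIN)) / (n - 1),
       pe = p[, 1], inc = p[, 2], coh = p[, 3], pair = p[, 4],
       tot = rowSums(p),
       mutr = mu_transfer(material, egrid),
       zeff = zeff)
}

# fine electron stopping-power table (MeV/cm) for the C++ core
fine_e_table <- function(material, n = 200) {
  egrid <- exp(seq(log(ELECTRON_EMIN), log(ELECTRON_EMAX), length.out = n))
  list(logE0 = log(ELECTRON_EMIN),
       dlogE = (log(ELECTRON_EMAX) - log(ELECTRON_EMIN)) / (n - 1),
       S = mass_stopping_power(material, egrid) * material$density)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
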