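## Synthetic track generator: spatial distributions of radiolytic species at
## 1 ps, standing in for the physical/physicochemical stage. Spur ensembles
## for low LET, cylindrical segments for high LET; calibrated against the
## accepted escape yields of acidic water.

#' Spur/track generator parameters
#'
#' Calibration parameters of the synthetic 1-ps stage: per-species initial
#' yields (molecules/100 eV), two Gaussian width classes for initial
#' positions (thermalised electrons spread further than radicals born at
#' ionisation sites), and the mean energy of a low-LET spur.
#'
#' @param initial_yields Named vector, molecules/100 eV at 1 ps.
#' @param sigma Named vector (nm) with elements `electron` and `radical`.
#' @param mean_spur_energy Mean energy per spur (eV).
#' @return A `spur_params` object.
#' @examples
#' spur_parameters()            # packaged literature-guided defaults
#' @export
spur_parameters <- function(initial_yields = NULL, sigma = NULL,
                            mean_spur_energy = NULL) {
  defaults <- .spur_defaults()
  p <- list(
    initial_yields = if (is.null(initial_yields)) defaults$initial_yields else initial_yields,
    sigma = if (is.null(sigma)) defaults$sigma else sigma,
    mean_spur_energy = if (is.null(mean_spur_energy)) defaults$mean_spur_energy else mean_spur_energy
  )
  stopifnot(all(p$initial_yields >= 0), all(p$sigma > 0),
            p$mean_spur_energy > 0,
            all(c("electron", "radical") %in% names(p$sigma)))
  structure(p, class = "spur_params")
}

.spur_defaults <- function() {
  path <- system.file("extdata", "spur_defaults.yaml", package = "frickesim")
  raw <- yaml::read_yaml(path)
  list(initial_yields = unlist(raw$initial_yields),
       sigma = unlist(raw$sigma),
       mean_spur_energy = raw$mean_spur_energy,
       yield_bounds = unlist(raw$yield_bounds),
       sigma_bounds = raw$sigma_bounds)
}

#' @export
print.spur_params <- function(x, ...) {
  cat("<spur_params> mean spur energy", x$mean_spur_energy, "eV\n")
  cat("  sigma (nm):", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                             collapse = ", "), "\n")
  cat("  1-ps yields:", paste(sprintf("%s=%.3g", names(x$initial_yields),
                                      x$initial_yields), collapse = ", "), "\n")
  invisible(x)
}

#' LET of the tabulated proton energies
#'
#' Returns the linear energy transfer pairing used throughout: 300 MeV
#' protons ~0.3 keV/um, 1 MeV ~25 keV/um, 0.15 MeV (150 keV, Bragg-peak
#' region) ~72 keV/um. Scenarios are LET-parametrised; other energies must be
#' specified as LET directly.
#'
#' @param proton_energy_MeV One of 300, 1 or 0.15.
#' @return LET in keV/um.
#' @examples
#' let_lookup(300)
#' @export
let_lookup <- function(proton_energy_MeV) {
  tab <- c(`300` = 0.3, `1` = 25, `0.15` = 72)
  key <- as.character(proton_energy_MeV)
  if (!key %in% names(tab)) {
    stop("proton energy not tabulated (300, 1 or 0.15 MeV); ",
         "specify the LET directly instead")
  }
  unname(tab[key])
}

## sample particle identities and offsets for an expected species inventory
## expected_counts: named vector; returns data.frame(species, dx, dy, dz) nm
.sample_species_cloud <- function(expected_counts, sigma_of) {
  counts <- rpois(length(expected_counts), expected_counts)
  species <- rep(names(expected_counts), counts)
  n <- length(species)
  sig <- sigma_of[species]
  list(species = species,
       offsets = cbind(dx = rnorm(n, 0, sig), dy = rnorm(n, 0, sig),
                       dz = rnorm(n, 0, sig)))
}

## per-species sigma lookup (nm) from the class assignment in the registry
.sigma_by_species <- function(params, species_table) {
  cls <- setNames(species_table$sigma_class, species_table$name)
  vapply(names(params$initial_yields),
         function(s) params$sigma[[cls[[s]]]], numeric(1))
}

#' Sample a low-LET spur ensemble at 1 ps
#'
#' Draws `n_spurs` spurs, each with Poisson species counts of expectation
#' `initial_yield * mean_spur_energy / 100` and isotropic Gaussian positions
#' about the spur centre with the class width. With `spacing = Inf`
#' (default) spurs are mutually independent (infinitely separated; the
#' returned coordinates place them on a widely spaced lattice). With finite
#' `spacing` (nm) the spur centres sit on the track axis at that interval and
#' the axial coordinate is treated as periodic downstream, emulating a
#' constant-LET track segment of well-separated spurs.
#'
#' @param params A `spur_params` object.
#' @param n_spurs Number of spurs (>= 0).
#' @param spacing Centre-to-centre spacing along the track axis (nm), or
#'   `Inf` for independent spurs.
#' @param species_table Species registry (for the sigma class of each
#'   species); defaults to the packaged registry.
#' @return An `initial_distribution` object.
#' @export
sample_spur_ensemble <- function(params, n_spurs, spacing = Inf,
                                 species_table = fricke_chemistry_config()$species) {
  stopifnot(inherits(params, "spur_params"), n_spurs >= 0)
  e_spur <- params$mean_spur_energy
  expected <- params$initial_yields * e_spur / 100
  sigma_of <- .sigma_by_species(params, species_table)

  ## independent spurs are laid out at 1 mm intervals: far beyond any
  ## reaction cutoff, so they cannot interact
  gap <- if (is.finite(spacing)) spacing else 1e6
  parts <- vector("list", n_spurs)
  for (i in seq_len(n_spurs)) {
    cl <- .sample_species_cloud(expected, sigma_of)
    parts[[i]] <- data.frame(species = cl$species,
                             x = cl$offsets[, 1] + (i - 1) * gap,
                             y = cl$offsets[, 2], z = cl$offsets[, 3],
                             stringsAsFactors = FALSE)
  }
  particles <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(particles)) {
    particles <- data.frame(species = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0))
  }
  structure(list(
    particles = particles,
    deposited_energy = n_spurs * e_spur,
    geometry = "spur-ensemble",
    length_um = if (is.finite(spacing)) n_spurs * spacing * 1e-3 else NA_real_,
    periodic = is.finite(spacing),
    LET = if (is.finite(spacing) && n_spurs > 0) {
      e_spur / spacing  # eV/nm == keV/um
    } else NA_real_
  ), class = "initial_distribution")
}

#' Sample a high-LET cylindrical track segment at 1 ps
#'
#' Expected species counts are `initial_yield * LET * length / 100`; axial
#' positions are uniform over the segment (periodic axial wrap downstream),
#' radial positions Gaussian with the class width.
#'
#' @param params A `spur_params` object.
#' @param LET Linear energy transfer (keV/um, > 0).
#' @param length_um Segment length (um, > 0).
#' @param species_table Species registry, as in [sample_spur_ensemble()].
#' @return An `initial_distribution` object.
#' @export
sample_cylindrical_track <- function(params, LET, length_um,
                                     species_table = fricke_chemistry_config()$species) {
  stopifnot(inherits(params, "spur_params"), LET > 0, length_um > 0)
  energy <- LET * length_um * 1000          # eV
  expected <- params$initial_yields * energy / 100
  sigma_of <- .sigma_by_species(params, species_table)
  counts <- rpois(length(expected), expected)
  species <- rep(names(expected), counts)
  n <- length(species)
  sig <- sigma_of[species]
  particles <- data.frame(
    species = species,
    x = runif(n, 0, length_um * 1000),     # nm
    y = rnorm(n, 0, sig), z = rnorm(n, 0, sig),
    stringsAsFactors = FALSE
  )
  structure(list(
    particles = particles,
    deposited_energy = energy,
    geometry = "cylinder",
    length_um = length_um,
    periodic = TRUE,
    LET = LET
  ), class = "initial_distribution")
}

#' @export
print.initial_distribution <- function(x, ...) {
  cat("<initial_distribution>", x$geometry, "-", nrow(x$particles),
      "particles,", x$deposited_energy, "eV\n")
  invisible(x)
}

#' 1-ps G-values of a distribution
#'
#' Counts normalised by deposited energy, molecules/100 eV.
#' @param dist An `initial_distribution`.
#' @return Named numeric vector.
#' @export
initial_yields_of <- function(dist) {
  if (nrow(dist$particles) == 0) return(setNames(numeric(0), character(0)))
  tab <- table(dist$particles$species)
  100 * setNames(as.numeric(tab), names(tab)) / dist$deposited_energy
}
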