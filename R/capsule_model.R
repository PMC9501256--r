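#' Physical constants for the capture model
#'
#' Bundles the constants used to convert a capsule description into the
#' quantities entering the force balance.  All values are SI.
#'
#' @param eta_water Dynamic viscosity of the carrier fluid (Pa s).
#' @param rho_water Density of the carrier fluid (kg/m^3).
#' @param chi_mnp Mass magnetic susceptibility of the magnetite
#'   nanoparticle payload (m^3/kg).  Multiplied by payload mass fraction
#'   and capsule density it yields the dimensionless volume
#'   susceptibility of the composite capsule.  The default is a mid-range
#'   literature value for citrate-stabilised magnetite; only relative
#'   payloads are constrained experimentally, so this scale factor is
#'   deliberately configurable.
#' @param rho_mnp Density of magnetite (kg/m^3).
#'
#' @return An object of class `physical_constants`: a list with the four
#'   arguments plus `mu0`, the vacuum magnetic permeability (T m/A),
#'   which is fixed at its SI value.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(eta_water = 1.0e-3, rho_water = 998,
                               chi_mnp = 5e-4, rho_mnp = 5180) {
  stopifnot(eta_water > 0, rho_water > 0, chi_mnp > 0, rho_mnp > 0)
  structure(list(mu0 = 4e-7 * pi, eta_water = eta_water,
                 rho_water = rho_water, chi_mnp = chi_mnp,
                 rho_mnp = rho_mnp),
            class = "physical_constants")
}

#' Magnetite mass fraction after freezing-induced loading
#'
#' Printed payload fractions for vaterite templates subjected to one, two
#' or three freezing/thawing cycles.
#'
#' @param n_cycles Integer number of freezing/thawing cycles, in 1:3.
#' @return Mass fraction of magnetite in the capsule (dimensionless).
#' @export
fil_mass_fraction <- function(n_cycles) {
  if (!all(n_cycles %in% 1:3))
    stop("n_cycles must be 1, 2 or 3", call. = FALSE)
  c(0.016, 0.046, 0.064)[n_cycles]
}

#' Volume magnetic susceptibility from payload mass fraction
#'
#' Linear mixing rule: the capsule volume susceptibility is the payload
#' mass per unit capsule volume times the magnetite mass susceptibility,
#' `chi_cap = fraction * rho * chi_mnp`.  It is linear in the mass
#' fraction and zero for an unloaded capsule.
#'
#' @param mnp_mass_fraction Payload mass fraction in `[0, 1)`.
#' @param constants A [physical_constants()] object.
#' @param rho Effective capsule density (kg/m^3).
#' @return Dimensionless (SI) volume susceptibility.
#' @export
derive_susceptibility <- function(mnp_mass_fraction,
                                  constants = physical_constants(),
                                  rho = capsule_density(mnp_mass_fraction,
                                                        constants)) {
  if (any(mnp_mass_fraction < 0 | mnp_mass_fraction >= 1))
    stop("mnp_mass_fraction must lie in [0, 1)", call. = FALSE)
  mnp_mass_fraction * rho * constants$chi_mnp
}

#' Effective density of a payload-bearing capsule
#'
#' The hollow shell is treated as carrier fluid carrying a magnetite mass
#' fraction `f`; volumes are additive, so the density is the harmonic
#' mixture `1 / ((1 - f)/rho_water + f/rho_mnp)`.
#'
#' @inheritParams derive_susceptibility
#' @return Density in kg/m^3.
#' @export
capsule_density <- function(mnp_mass_fraction,
                            constants = physical_constants()) {
  f <- mnp_mass_fraction
  if (any(f < 0 | f >= 1))
    stop("mnp_mass_fraction must lie in [0, 1)", call. = FALSE)
  1 / ((1 - f) / constants$rho_water + f / constants$rho_mnp)
}

#' Describe one capsule population
#'
#' Converts the printed descriptors of a capsule batch (diameter,
#' dispersion, number of freezing/thawing loading cycles) into the
#' physical quantities the force equations need: volume, mass, effective
#' density and volume magnetic susceptibility.
#'
#' @param mean_diameter_um Mean capsule diameter (micrometres).
#' @param diameter_sd_um Standard deviation of the diameter
#'   (micrometres); the printed "mean +/- x" dispersion.
#' @param n_freeze_cycles Number of freezing/thawing loading cycles
#'   (1--3); sets the payload mass fraction unless `mnp_mass_fraction`
#'   is given explicitly.
#' @param mnp_mass_fraction Optional explicit payload mass fraction.
#'   Zero gives a nonmagnetic capsule.
#' @param shell_label Free-text shell composition label.
#' @param rho Optional density override (kg/m^3); default from
#'   [capsule_density()].
#' @param M0 Remanent magnetisation vector (A/m), length 2.  Defaults to
#'   zero: ~10 nm citrate-stabilised magnetite is superparamagnetic with
#'   negligible remanence.  The remanence term of the force equation is
#'   retained in code and activates when this is nonzero.
#' @param constants A [physical_constants()] object.
#'
#' @return An object of class `capsule_spec`: a list with the inputs plus
#'   derived `volume_m3` (`pi/6 d^3`), `mass_kg` (`rho * volume`),
#'   `chi_cap` and `radius_m`.
#' @export
#' @examples
#' capsule_spec(2.7, 0.4, n_freeze_cycles = 3)
capsule_spec <- function(mean_diameter_um, diameter_sd_um = 0,
                         n_freeze_cycles = NULL, mnp_mass_fraction = NULL,
                         shell_label = "PAH/PSS", rho = NULL,
                         M0 = c(0, 0),
                         constants = physical_constants()) {
  stopifnot(mean_diameter_um > 0, diameter_sd_um >= 0, length(M0) == 2)
  if (is.null(mnp_mass_fraction)) {
    if (is.null(n_freeze_cycles))
      stop("give either n_freeze_cycles or mnp_mass_fraction",
           call. = FALSE)
    mnp_mass_fraction <- fil_mass_fraction(n_freeze_cycles)
  }
  if (mnp_mass_fraction < 0 || mnp_mass_fraction >= 1)
    stop("mnp_mass_fraction must lie in [0, 1)", call. = FALSE)
  if (is.null(rho)) rho <- capsule_density(mnp_mass_fraction, constants)
  d <- mean_diameter_um * 1e-6
  vol <- pi / 6 * d^3
  spec <- list(mean_diameter_um = mean_diameter_um,
               diameter_sd_um = diameter_sd_um,
               n_freeze_cycles = n_freeze_cycles,
               mnp_mass_fraction = mnp_mass_fraction,
               shell_label = shell_label,
               rho = rho,
               M0 = as.numeric(M0),
               radius_m = d / 2,
               volume_m3 = vol,
               chi_cap = if (mnp_mass_fraction > 0)
                 derive_susceptibility(mnp_mass_fraction, constants, rho)
               else 0,
               mass_kg = rho * vol,
               constants = constants)
  class(spec) <- "capsule_spec"
  spec
}

#' @export
print.capsule_spec <- function(x, ...) {
  cat(sprintf(
    "<capsule_spec> %s, d = %g +/- %g um, payload %.1f%% (chi_cap %.3g)\n",
    x$shell_label, x$mean_diameter_um, x$diameter_sd_um,
    100 * x$mnp_mass_fraction, x$chi_cap))
  cat(sprintf("  rho %.0f kg/m3, V %.3g m3, mass %.3g kg\n",
              x$rho, x$volume_m3, x$mass_kg))
  invisible(x)
}

#' Replace the diameter of a capsule spec, rederiving volume and mass
#'
#' Used when propagating a sampled per-capsule diameter through the
#' force model.  Susceptibility and density are intensive and unchanged.
#'
#' @param spec A [capsule_spec()].
#' @param diameter_um New diameter (micrometres).
#' @return A `capsule_spec` with updated radius, volume and mass.
#' @export
set_diameter <- function(spec, diameter_um) {
  stopifnot(inherits(spec, "capsule_spec"), diameter_um > 0)
  d <- diameter_um * 1e-6
  spec$mean_diameter_um <- diameter_um
  spec$diameter_sd_um <- 0
  spec$radius_m <- d / 2
  spec$volume_m3 <- pi / 6 * d^3
  spec$mass_kg <- spec$rho * spec$volume_m3
  spec
}

#' Capsule mass
#'
#' `mass = rho * (pi/6) d^3`, the inertial mass entering the equation of
#' motion.
#'
#' @param spec A [capsule_spec()].
#' @return Mass in kg.
#' @export
capsule_mass <- function(spec) {
  stopifnot(inherits(spec, "capsule_spec"))
  spec$rho * spec$volume_m3
}

#' Sample a capsule population
#'
#' Draws per-capsule diameters from a truncated normal distribution
#' (truncation at 0.1 x mean, so diameters stay strictly positive) and
#' derives per-capsule volume and mass.
#'
#' @param spec A [capsule_spec()]; its mean and sd set the distribution.
#' @param n Number of capsules to draw (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return A data.frame with columns `diameter_um`, `volume_m3`,
#'   `mass_kg`.
#' @export
sample_population <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "capsule_spec"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  d <- withr::with_seed(seed,
    rtruncnorm_pos(n, spec$mean_diameter_um, spec$diameter_sd_um,
                   lower = 0.1 * spec$mean_diameter_um))
  vol <- pi / 6 * (d * 1e-6)^3
  data.frame(diameter_um = d, volume_m3 = vol, mass_kg = spec$rho * vol)
}

# truncated-normal draw by rejection; degenerate sd returns the mean
rtruncnorm_pos <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Describe a capsule-laden cell
#'
#' A cell is modelled as a sphere whose magnetic moment is the sum of the
#' moments of its internalised capsules: `k` identical capsules give
#' exactly `k` times the single-capsule moment in the same field.
#'
#' @param internalized_capsules Integer count of internalised capsules
#'   (>= 0).
#' @param capsule The [capsule_spec()] describing the internalised
#'   capsule population.
#' @param diameter_um Cell diameter (micrometres); default 13, a
#'   macrophage-sized cell.
#' @return An object of class `cell_spec`.
#' @export
#' @examples
#' cell_spec(5, capsule_spec(2.7, 0.4, n_freeze_cycles = 3))
cell_spec <- function(internalized_capsules, capsule, diameter_um = 13) {
  stopifnot(inherits(capsule, "capsule_spec"), diameter_um > 0,
            internalized_capsules >= 0,
            internalized_capsules == round(internalized_capsules))
  structure(list(diameter_um = diameter_um,
                 internalized_capsules = as.integer(internalized_capsules),
                 capsule = capsule),
            class = "cell_spec")
}

#' Equivalent capsule spec for a capsule-laden cell
#'
#' Builds a sphere of the cell's diameter whose volume susceptibility
#' (and remanent moment) reproduce `k` times the single-capsule magnetic
#' moment, so the cell can be passed through the same trajectory
#' integrator as a capsule.  The cell's inertial mass uses the carrier
#' fluid density plus the payload excess of the internalised capsules.
#'
#' @param cell A [cell_spec()].
#' @param constants A [physical_constants()] object.
#' @return A `capsule_spec` describing the equivalent magnetic sphere.
#' @export
cell_as_capsule <- function(cell, constants = physical_constants()) {
  stopifnot(inherits(cell, "cell_spec"))
  k <- cell$internalized_capsules
  cap <- cell$capsule
  d <- cell$diameter_um * 1e-6
  v_cell <- pi / 6 * d^3
  chi_eff <- k * cap$volume_m3 * cap$chi_cap / v_cell
  m0_eff <- k * cap$rho * cap$volume_m3 * cap$M0 / v_cell
  rho_eff <- constants$rho_water +
    k * cap$volume_m3 * (cap$rho - constants$rho_water) / v_cell
  out <- capsule_spec(cell$diameter_um, 0,
                      mnp_mass_fraction = 0,
                      shell_label = sprintf("cell+%d capsules", k),
                      rho = rho_eff, constants = constants)
  out$chi_cap <- chi_eff
  out$M0 <- m0_eff
  out
}

#' Magnetic moment of a capsule in a given field
#'
#' `m = rho V M0 + (V chi_cap / mu0) B`: a remanence term plus an induced
#' term linear in the local field.  With zero remanence the moment is
#' parallel to `B`.
#'
#' @param spec A [capsule_spec()] (or the cell-equivalent sphere from
#'   [cell_as_capsule()]).
#' @param B Local magnetic field vector (T), length 2.
#' @param constants A [physical_constants()] object.
#' @return Magnetic moment vector (A m^2), length 2.
#' @export
magnetic_moment <- function(spec, B, constants = physical_constants()) {
  stopifnot(inherits(spec, "capsule_spec"), length(B) == 2)
  spec$rho * spec$volume_m3 * spec$M0 +
    spec$volume_m3 * spec$chi_cap / constants$mu0 * as.numeric(B)
}

#' Built-in capsule population presets
#'
#' The three studied capsule sizes (1 +/- 0.2, 2.7 +/- 0.4 and
#' 5.5 +/- 0.8 micrometres) at a given number of loading cycles.
#'
#' @param n_freeze_cycles Number of freezing/thawing cycles (1--3).
#' @param constants A [physical_constants()] object.
#' @return Named list of three [capsule_spec()] objects.
#' @export
capsule_presets <- function(n_freeze_cycles = 3,
                            constants = physical_constants()) {
  sizes <- list(`1um`   = c(1, 0.2),
                `2.7um` = c(2.7, 0.4),
                `5.5um` = c(5.5, 0.8))
  lapply(sizes, function(s)
    capsule_spec(s[1], s[2], n_freeze_cycles = n_freeze_cycles,
                 constants = constants))
}

#' Read a capsule description from a YAML config file
#'
#' Recognised keys: `diameter_um`, `diameter_sd_um`, `cycles`,
#' `mnp_mass_fraction`, `rho_override`, `shell_label`.  Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @param constants A [physical_constants()] object.
#' @return A [capsule_spec()].
#' @export
read_capsule_config <- function(path, constants = physical_constants()) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("diameter_um", "diameter_sd_um", "cycles",
               "mnp_mass_fraction", "rho_override", "shell_label")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  capsule_spec(mean_diameter_um = cfg$diameter_um,
               diameter_sd_um = cfg$diameter_sd_um %||% 0,
               n_freeze_cycles = cfg$cycles,
               mnp_mass_fraction = cfg$mnp_mass_fraction,
               shell_label = cfg$shell_label %||% "PAH/PSS",
               rho = cfg$rho_override,
               constants = constants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
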