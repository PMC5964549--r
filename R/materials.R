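# Electron rest energy in keV.
MEC2_KEV <- 510.99895

# Classical electron radius squared, cm^2.
RE2_CM2 <- (2.8179403262e-13)^2

# Avogadro constant, 1/mol.
N_AVOGADRO <- 6.02214076e23

# Gy per (keV/g): 1 keV = 1.602176634e-16 J, 1 g = 1e-3 kg.
GY_PER_KEV_PER_G <- 1.602176634e-13

# Range-model exponent fitted to measured electron stopping powers;
# material independent over 10 keV - a few 100 keV.
ALPHA_STOPPING <- 0.415

# Energy grid for embedded cross-section tables, keV.
TABLE_ENERGIES <- exp(seq(log(10), log(500), length.out = 25))

# Elemental data used to mix tissue cross sections.  Photoelectric and
# Rayleigh mass attenuation (cm^2/g) are compact power-law
# parameterisations calibrated against a standard compilation at 50 and
# 100 keV (water/bone mixtures reproduce compilation values to a few
# percent over 10-500 keV); Compton comes from the closed-form
# Klein-Nishina total cross section (free electron, no binding/Doppler).
ELEMENTS <- list(
  H  = list(Z = 1,  A = 1.008),
  C  = list(Z = 6,  A = 12.011),
  N  = list(Z = 7,  A = 14.007),
  O  = list(Z = 8,  A = 15.999),
  P  = list(Z = 15, A = 30.974),
  Ca = list(Z = 20, A = 40.078)
)

# photoelectric mass attenuation for one element, cm^2/g
element_photoelectric <- function(symbol, E) {
  el <- ELEMENTS[[symbol]]
  tau50 <- 3.981e-5 * el$Z^4.5 / el$A
  p <- ifelse(E < 50, 3.15 + 0.12 * log(50 / E) / log(5), 3.15)
  tau50 * (50 / E)^p
}

# Rayleigh (coherent) mass attenuation for one element, cm^2/g
element_rayleigh <- function(symbol, E) {
  el <- ELEMENTS[[symbol]]
  r50 <- 3.25e-3 * el$Z^2.3 / el$A
  r50 * (50 / E)^1.7
}

#' Klein-Nishina total cross section per electron
#'
#' Closed-form total Compton cross section for scattering off a free
#' electron at photon energy `E`, in cm^2 per electron.
#'
#' @param E photon energy in keV (vectorised).
#' @return cross section in cm^2 per electron.
#' @export
klein_nishina_total <- function(E) {
  k <- E / MEC2_KEV
  2 * pi * RE2_CM2 *
    ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
       log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# Compton (incoherent) mass attenuation for one element, cm^2/g
element_compton <- function(symbol, E) {
  el <- ELEMENTS[[symbol]]
  el$Z / el$A * N_AVOGADRO * klein_nishina_total(E)
}

#' Construct a material
#'
#' A material bundles a mass density, an elemental composition and
#' embedded photon interaction coefficient tables (photoelectric, Compton,
#' Rayleigh mass attenuation on a 10-500 keV log grid).  Coefficients for
#' mixtures follow mass-weighted additivity.
#'
#' @param name label.
#' @param density nominal mass density in g/cm^3 (> 0).
#' @param composition named numeric vector of element mass fractions
#'   (names from H, C, N, O, P, Ca); must sum to 1.
#' @return an object of class `material`.
#' @export
material <- function(name, density, composition) {
  stopifnot(density > 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  }
  if (!all(names(composition) %in% names(ELEMENTS))) {
    stop("unknown element(s): ",
         paste(setdiff(names(composition), names(ELEMENTS)), collapse = ", "))
  }
  E <- TABLE_ENERGIES
  tau <- sig_c <- sig_r <- numeric(length(E))
  for (el in names(composition)) {
    w <- composition[[el]]
    tau   <- tau   + w * element_photoelectric(el, E)
    sig_c <- sig_c + w * element_compton(el, E)
    sig_r <- sig_r + w * element_rayleigh(el, E)
  }
  structure(
    list(name = name, density = density, composition = composition,
         energies = E, tau = tau, sigma_compton = sig_c,
         sigma_rayleigh = sig_r),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " rho =", x$density, "g/cm^3\n")
  cat("  composition:",
      paste(sprintf("%s=%.4f", names(x$composition), x$composition),
            collapse = " "), "\n")
  invisible(x)
}

#' Mass attenuation coefficients of a material
#'
#' Log-log interpolation of the embedded tables.
#'
#' @param mat a [material()].
#' @param E photon energy in keV, 10-500 (vectorised).
#' @return a list with components `photoelectric`, `compton`, `rayleigh`
#'   and `total`, each in cm^2/g.
#' @export
mass_attenuation <- function(mat, E) {
  tau <- loglog_interp(mat$energies, mat$tau, E)
  sc  <- loglog_interp(mat$energies, mat$sigma_compton, E)
  sr  <- loglog_interp(mat$energies, mat$sigma_rayleigh, E)
  list(photoelectric = tau, compton = sc, rayleigh = sr,
       total = tau + sc + sr)
}

#' Linear attenuation coefficient, 1/cm
#'
#' @inheritParams mass_attenuation
#' @param density override of the material's nominal density (g/cm^3).
#' @export
linear_attenuation <- function(mat, E, density = mat$density) {
  ma <- mass_attenuation(mat, E)
  lapply(ma, function(v) v * density)
}

#' Build the default material library
#'
#' Water, ICRU-style cortical bone, air and soft tissue, each with
#' embedded coefficient tables.  Compositions are restricted to the
#' elements H, C, N, O, P, Ca (trace elements folded into the nearest
#' neighbour and renormalised).
#'
#' @return named list of [material()] objects.
#' @export
build_material_library <- function() {
  norm <- function(x) x / sum(x)
  list(
    water = material("water", 1.0,
                     c(H = 0.1119, O = 0.8881)),
    bone = material("bone", 1.85,
                    norm(c(H = 0.034, C = 0.155, N = 0.042, O = 0.435,
                           P = 0.103, Ca = 0.225))),
    air = material("air", 1.205e-3,
                   c(C = 0.013, N = 0.755, O = 0.232)),
    soft_tissue = material("soft_tissue", 1.06,
                           norm(c(H = 0.102, C = 0.143, N = 0.034,
                                  O = 0.708)))
  )
}

#' Interaction type fractions at a photon energy
#'
#' Probabilities that an interaction in `mat` at energy `E` is
#' photoelectric, Compton or Rayleigh, proportional to the respective
#' attenuation coefficients.
#'
#' @inheritParams mass_attenuation
#' @return list with `photoelectric`, `compton`, `rayleigh` (sum to 1).
#' @export
interaction_fractions <- function(mat, E) {
  ma <- mass_attenuation(mat, E)
  tot <- ma$total
  list(photoelectric = ma$photoelectric / tot,
       compton = ma$compton / tot,
       rayleigh = ma$rayleigh / tot)
}

#' Mean Compton energy-transfer fraction
#'
#' Mean fraction p of the photon energy transferred to the recoil
#' electron in Compton scattering, from the free-electron Klein-Nishina
#' differential cross section (ratio of the energy-transfer to the total
#' Compton cross section).  Monotone increasing in E; p -> 0 in the
#' Thomson limit.
#'
#' @param E photon energy in keV (vectorised).
#' @return mean transfer fraction in (0, 1).
#' @export
compton_mean_transfer_fraction <- function(E) {
  stopifnot(all(E > 0))
  vapply(E, function(e) {
    k <- e / MEC2_KEV
    f <- function(mu) {
      eps <- 1 / (1 + k * (1 - mu))
      eps^2 * (eps + 1 / eps - (1 - mu^2))
    }
    num <- stats::integrate(function(mu) (1 - 1 / (1 + k * (1 - mu))) * f(mu),
                            -1, 1, rel.tol = 1e-11)$value
    den <- stats::integrate(f, -1, 1, rel.tol = 1e-11)$value
    num / den
  }, numeric(1))
}

#' Electron stopping/range model
#'
#' Power-law continuous-slowing-down-approximation (CSDA) range model:
#' the stopping power S proportional to E^(-alpha/(1-alpha)) implies
#' range(E) = anchor_range * (E/anchor_energy)^(1/(1-alpha)), scaled with
#' the inverse density ratio across materials.  The default anchor is
#' 43 um at 50 keV in water.
#'
#' @param alpha dimensionless exponent in (0,1).
#' @param anchor_energy keV.
#' @param anchor_range cm (in water at density 1).
#' @return object of class `stopping_model`.
#' @export
stopping_model <- function(alpha = ALPHA_STOPPING, anchor_energy = 50,
                           anchor_range = 43e-4) {
  stopifnot(alpha > 0, alpha < 1, anchor_energy > 0, anchor_range > 0)
  structure(list(alpha = alpha, anchor_energy = anchor_energy,
                 anchor_range = anchor_range),
            class = "stopping_model")
}

#' Electron CSDA range
#'
#' @param model a [stopping_model()].
#' @param mat a [material()] (only the density enters).
#' @param E electron kinetic energy in keV (vectorised, >= 0).
#' @param density density override, g/cm^3.
#' @return range sigma in cm.
#' @export
csda_range <- function(model, mat, E, density = mat$density) {
  if (any(E < 0)) stop("negative electron energy")
  model$anchor_range * (E / model$anchor_energy)^(1 / (1 - model$alpha)) *
    (1.0 / density)
}

#' Hounsfield-unit to material conversion
#'
#' Simplified piecewise Schneider-style mapping with four pieces:
#' HU <= -900 air; -900 < HU <= -100 lung-like (water composition with a
#' linearly ramped density); -100 < HU <= 100 water/soft tissue;
#' HU > 100 bone with a linear density ramp.  Density is continuous
#' within each piece.  HU outside [-1024, 3000] is clamped with a
#' warning.
#'
#' @param HU numeric vector of Hounsfield units.
#' @param library material library from [build_material_library()].
#' @return list with `piece` (air/lung/water/bone), `material` (library
#'   label holding the composition; lung-like voxels use the water
#'   composition) and `density` (g/cm^3).
#' @export
hu_to_material <- function(HU, library = build_material_library()) {
  if (any(HU < -1024 | HU > 3000)) {
    warning("HU outside [-1024, 3000] clamped")
    HU <- pmin(pmax(HU, -1024), 3000)
  }
  piece <- character(length(HU))
  mat <- character(length(HU))
  density <- numeric(length(HU))
  i <- HU <= -900
  piece[i] <- "air"; mat[i] <- "air"; density[i] <- library$air$density
  i <- HU > -900 & HU <= -100
  piece[i] <- "lung"; mat[i] <- "water"; density[i] <- 1 + HU[i] / 1000
  i <- HU > -100 & HU <= 100
  piece[i] <- "water"; mat[i] <- "water"; density[i] <- 1 + HU[i] / 1000
  i <- HU > 100
  piece[i] <- "bone"; mat[i] <- "bone"
  density[i] <- 1.1 + (HU[i] - 100) * (1.85 - 1.1) / 1400
  list(piece = piece, material = mat, density = density)
}

#' Serialise a material library to JSON
#'
#' @param library named list of [material()] objects.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
material_library_to_json <- function(library, path = NULL) {
  doc <- lapply(library, function(m) {
    list(name = m$name, density = m$density,
         composition = as.list(m$composition),
         energies_keV = m$energies,
         photoelectric_cm2_g = m$tau,
         compton_cm2_g = m$sigma_compton,
         rayleigh_cm2_g = m$sigma_rayleigh)
  })
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a material library from JSON
#'
#' @param path file written by [material_library_to_json()].
#' @return named list of [material()] objects (tables taken verbatim).
#' @export
material_library_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(doc, function(m) {
    structure(
      list(name = m$name, density = m$density,
           composition = unlist(m$composition),
           energies = m$energies_keV, tau = m$photoelectric_cm2_g,
           sigma_compton = m$compton_cm2_g,
           sigma_rayleigh = m$rayleigh_cm2_g),
      class = "material")
  })
  names(out) <- names(doc)
  out
}
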