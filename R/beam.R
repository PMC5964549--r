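#' Photon spectrum
#'
#' A polychromatic source is described by energy lines `E_i` (keV) and the
#' fractional beam *power* carried by each line, `f(E_i)`.  Because f is a
#' power (energy-flux) fraction, the photon *count* emitted at line i is
#' proportional to f(E_i)/E_i.
#'
#' @param energies strictly increasing energies in keV.
#' @param power_fractions nonnegative relative power per line; normalised
#'   to sum to 1 on construction.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(energies, power_fractions) {
  stopifnot(length(energies) == length(power_fractions),
            all(power_fractions >= 0), sum(power_fractions) > 0)
  if (length(energies) > 1 && any(diff(energies) <= 0)) {
    stop("energies must be strictly increasing")
  }
  structure(list(energies = as.numeric(energies),
                 power_fractions = power_fractions / sum(power_fractions)),
            class = "spectrum")
}

#' Monoenergetic line spectrum
#' @param E energy in keV.
#' @export
mono_spectrum <- function(E) spectrum(E, 1)

#' Read a spectrum from a two-column CSV (energy_keV, relative_power)
#' @param path CSV file with a header line.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectrum(df[[1]], df[[2]])
}

#' Collimator description
#'
#' @param type "planar" (slits), "pencil" (square grid) or "open".
#' @param slit_width_um slit (or square side) width w in micrometres.
#' @param pitch_um centre-to-centre spacing in micrometres (w < pitch).
#' @export
collimator <- function(type = c("planar", "pencil", "open"),
                       slit_width_um = 50, pitch_um = 400) {
  type <- match.arg(type)
  if (type != "open") {
    stopifnot(slit_width_um > 0)
    if (slit_width_um >= pitch_um) stop("slit width must be < pitch")
  }
  structure(list(type = type, slit_width_um = slit_width_um,
                 pitch_um = pitch_um), class = "collimator")
}

default_collimator <- function() collimator("planar")

#' Parallel-beam configuration
#'
#' The source is a plane emitting photons perpendicular to its surface with
#' homogeneous intensity over a polygonal field outline; beam divergence is
#' ignored (parallel beams).  Directions are restricted to the grid axes.
#' Source-plane coordinates (u, v) map to phantom axes; collimator slits
#' vary along u.
#'
#' @param direction one of "+x","-x","+y","-y","+z","-z".
#' @param field_polygon n x 2 matrix of (u, v) vertices in mm, centred on
#'   the beam axis.
#' @param collimator a [collimator()].
#' @param spectrum a [spectrum()].
#' @param emission_pixel_mm source-plane rasterisation pitch in mm.
#' @return object of class `beam_config`.
#' @export
beam_config <- function(direction = "+z",
                        field_polygon = square_field(20),
                        collimator = default_collimator(),
                        spectrum = mono_spectrum(100),
                        emission_pixel_mm = 0.1) {
  stopifnot(direction %in% c("+x", "-x", "+y", "-y", "+z", "-z"))
  field_polygon <- as.matrix(field_polygon)
  if (nrow(field_polygon) < 3) stop("field polygon needs >= 3 vertices")
  structure(list(direction = direction, field_polygon = field_polygon,
                 collimator = collimator, spectrum = spectrum,
                 emission_pixel_mm = emission_pixel_mm),
            class = "beam_config")
}

#' Axis-aligned square field polygon
#' @param side_mm side length in mm, centred on the origin.
#' @export
square_field <- function(side_mm) {
  h <- side_mm / 2
  matrix(c(-h, -h, h, -h, h, h, -h, h), ncol = 2, byrow = TRUE)
}

# signed area of a polygon (shoelace)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# even-odd point-in-polygon, boundary points included.
# px, py vectors; poly n x 2 matrix.
points_in_polygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # edge crossing test (even-odd rule)
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    # boundary: distance from point to segment
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(pmax(((px - xi) * dx + (py - yi) * dy) / L2, 0), 1) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    onedge <- onedge | d2 <= tol^2
  }
  inside | onedge
}

#' Rasterise a field polygon onto the source-plane pixel grid
#'
#' Photons are emitted from all pixels whose centre lies inside the field
#' outline (even-odd rule); centres exactly on an edge are included.
#'
#' @param polygon n x 2 matrix of vertices in mm.
#' @param pixel_mm pixel pitch in mm.
#' @return list with `mask` (logical matrix), `u`, `v` (pixel centre
#'   coordinates in mm) and `pixel_mm`.
#' @export
rasterize_field <- function(polygon, pixel_mm) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || abs(polygon_area(polygon)) < 1e-12) {
    stop("degenerate field polygon")
  }
  ulo <- min(polygon[, 1]); uhi <- max(polygon[, 1])
  vlo <- min(polygon[, 2]); vhi <- max(polygon[, 2])
  nu <- max(1L, ceiling((uhi - ulo) / pixel_mm - 1e-9))
  nv <- max(1L, ceiling((vhi - vlo) / pixel_mm - 1e-9))
  u <- ulo + (seq_len(nu) - 0.5) * pixel_mm
  v <- vlo + (seq_len(nv) - 0.5) * pixel_mm
  g <- expand.grid(u = u, v = v)
  mask <- matrix(points_in_polygon(g$u, g$v, polygon), nrow = nu)
  list(mask = mask, u = u, v = v, pixel_mm = pixel_mm)
}

#' Sample photons from the source plane
#'
#' Emission pixels are drawn uniformly from the rasterised field mask with
#' a uniform sub-pixel offset; every photon travels along the beam
#' direction (no divergence).  Energies are drawn proportional to
#' f(E_i)/E_i (power-to-count conversion).
#'
#' @param beam a [beam_config()].
#' @param n number of photons.
#' @return list with `u`, `v` (source-plane positions, mm) and `energy`
#'   (keV); the direction is `beam$direction` for every photon.
#' @export
sample_photon <- function(beam, n) {
  ras <- rasterize_field(beam$field_polygon, beam$emission_pixel_mm)
  idx <- which(ras$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty emission mask")
  pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
  u <- ras$u[pick[, 1]] + (stats::runif(n) - 0.5) * ras$pixel_mm
  v <- ras$v[pick[, 2]] + (stats::runif(n) - 0.5) * ras$pixel_mm
  sp <- beam$spectrum
  if (length(sp$energies) == 1) {
    energy <- rep(sp$energies, n)
  } else {
    w <- sp$power_fractions / sp$energies
    energy <- sp$energies[sample.int(length(w), n, replace = TRUE,
                                     prob = w / sum(w))]
  }
  list(u = u, v = v, energy = energy)
}

#' Within-voxel fluence pattern of the collimator
#'
#' The lateral distribution nu of primary energy-transfer events: an ideal
#' binary comb (no septal transmission, no source blur) normalised to unit
#' mean over one period.  Planar collimators give a 1D rectangular comb of
#' in-slit value pitch/w; pencil grids give the 2D product comb with
#' in-square value (pitch/w)^2; open fields give nu = 1.
#'
#' Bins are area-weighted so the unit mean is exact for any bin size; the
#' slit is centred at u = 0 (a slit centre coincides with the field
#' centre).
#'
#' @param beam a [beam_config()] (or a [collimator()]).
#' @param bin_um fine-grid bin size in micrometres.
#' @return object of class `fluence_pattern` with fields `dimensionality`
#'   (0 for open), `period_um`, `bin_um` and `profile` (vector for 1D,
#'   matrix for 2D).
#' @export
fluence_pattern <- function(beam, bin_um = 5) {
  col <- if (inherits(beam, "collimator")) beam else beam$collimator
  if (col$type == "open") {
    return(structure(list(dimensionality = 0L, period_um = NA_real_,
                          bin_um = bin_um, profile = 1),
                     class = "fluence_pattern"))
  }
  pitch <- col$pitch_um; w <- col$slit_width_um
  if (w >= pitch) stop("slit width must be < pitch")
  nb <- round(pitch / bin_um)
  if (abs(nb * bin_um - pitch) > 1e-9) {
    stop("bin size must divide the collimator pitch")
  }
  # bin i covers [(i-1-nb/2)*bin, (i-nb/2)*bin); slit is [-w/2, w/2]
  lo <- (seq_len(nb) - 1 - nb / 2) * bin_um
  hi <- lo + bin_um
  occ <- pmax(0, pmin(hi, w / 2) - pmax(lo, -w / 2)) / bin_um
  prof1 <- occ * (pitch / w)        # unit mean by construction
  prof1 <- prof1 / mean(prof1)
  if (col$type == "planar") {
    structure(list(dimensionality = 1L, period_um = pitch, bin_um = bin_um,
                   profile = prof1), class = "fluence_pattern")
  } else {
    prof2 <- outer(prof1, prof1)
    prof2 <- prof2 / mean(prof2)
    structure(list(dimensionality = 2L, period_um = pitch, bin_um = bin_um,
                   profile = prof2), class = "fluence_pattern")
  }
}

#' Finite fluence profile across a field
#'
#' The 1D comb over the full lateral field extent (for edge handling and
#' direct-sampling oracles): slit centres at multiples of the pitch from
#' the field centre, clipped by the field envelope `[-width/2, width/2]`.
#' Values are on the same scale as [fluence_pattern()] (in-slit value
#' pitch/w, envelope mean 1 over an integer number of periods).
#'
#' @param col a [collimator()] of type "planar".
#' @param width_mm lateral field width in mm.
#' @param bin_um bin size in micrometres.
#' @param margin_um extra zero margin on both sides, micrometres.
#' @return list with `u_um` (bin centres relative to the field centre) and
#'   `profile`.
#' @export
fluence_field_1d <- function(col, width_mm, bin_um = 5, margin_um = 0) {
  stopifnot(col$type == "planar")
  pitch <- col$pitch_um; w <- col$slit_width_um
  half <- width_mm * 1e3 / 2 + margin_um
  nb <- ceiling(half / bin_um)
  lo <- (seq(-nb, nb - 1)) * bin_um
  hi <- lo + bin_um
  ctr <- (lo + hi) / 2
  kmax <- ceiling((half + w) / pitch)
  occ <- numeric(length(lo))
  for (k in seq(-kmax, kmax)) {
    c_k <- k * pitch
    slo <- max(c_k - w / 2, -width_mm * 1e3 / 2)
    shi <- min(c_k + w / 2, width_mm * 1e3 / 2)
    if (shi > slo) occ <- occ + pmax(0, pmin(hi, shi) - pmax(lo, slo))
  }
  list(u_um = ctr, profile = occ / bin_um * (pitch / w))
}
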