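#' Voxelised phantom
#'
#' @param material_index integer 3D array indexing `materials`.
#' @param density numeric 3D array, g/cm^3 per voxel.
#' @param spacing_mm length-3 voxel spacing in mm.
#' @param materials character vector of material labels (library keys).
#' @return object of class `voxel_phantom`.  The phantom occupies
#'   `[0, n*spacing]` mm along each axis.
#' @export
voxel_phantom <- function(material_index, density, spacing_mm, materials) {
  stopifnot(all(dim(material_index) == dim(density)),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            all(material_index >= 1),
            all(material_index <= length(materials)))
  structure(list(material_index = material_index, density = density,
                 spacing = as.numeric(spacing_mm), materials = materials,
                 dims = dim(material_index)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>", paste(x$dims, collapse = " x "),
      "voxels,", paste(x$spacing, collapse = " x "), "mm\n")
  cat("  materials:", paste(x$materials, collapse = ", "), "\n")
  invisible(x)
}

#' Physical extent of a phantom in mm
#' @param phantom a [voxel_phantom()].
#' @export
phantom_extent <- function(phantom) phantom$dims * phantom$spacing

#' Homogeneous cubic water phantom
#'
#' @param side_mm side length in mm (default 160).
#' @param voxel_mm isotropic voxel size in mm.
#' @export
water_cube <- function(side_mm = 160, voxel_mm = 2) {
  stopifnot(side_mm > 0, voxel_mm > 0)
  n <- round(side_mm / voxel_mm)
  idx <- array(1L, dim = c(n, n, n))
  dens <- array(1.0, dim = c(n, n, n))
  voxel_phantom(idx, dens, rep(voxel_mm, 3), "water")
}

#' Simplified head phantom
#'
#' A 160 mm cube of water with a 4 mm water "skin" shell at the surface,
#' a 6 mm bone shell underneath (4-10 mm depth from every face), and a
#' 10 mm bone cube whose corner sits at the phantom centre, extending into
#' the +x/+y/+z octant.
#'
#' @param voxel_mm voxel size in mm; must divide 2 mm so the layer
#'   boundaries fall on voxel faces.
#' @export
simplified_head <- function(voxel_mm = 2) {
  if (abs(2 / voxel_mm - round(2 / voxel_mm)) > 1e-9) {
    stop("voxel size must divide the 2 mm layer structure")
  }
  side <- 160
  n <- round(side / voxel_mm)
  ctr <- (seq_len(n) - 0.5) * voxel_mm   # voxel centre coordinates, mm
  idx <- array(1L, dim = c(n, n, n))     # 1 = water, 2 = bone
  # depth below the nearest surface for each voxel centre
  d1 <- pmin(ctr, side - ctr)
  A <- array(rep(d1, times = n * n), dim = c(n, n, n))
  depth <- pmin(A, aperm(A, c(2, 1, 3)), aperm(A, c(3, 2, 1)))
  idx[depth > 4 & depth <= 10] <- 2L
  # bone insert: corner at the centre (80,80,80), extends to +x,+y,+z
  ins <- ctr > 80 & ctr < 90
  idx[ins, ins, ins] <- 2L
  dens <- array(1.0, dim = c(n, n, n))
  dens[idx == 2L] <- 1.85
  voxel_phantom(idx, dens, rep(voxel_mm, 3), c("water", "bone"))
}

#' Synthetic anthropomorphic head CT (stand-in)
#'
#' A synthetic Hounsfield-unit volume imitating a human head: an ellipsoid
#' of soft tissue (HU around 0-50 with smooth noise) wrapped in a bone
#' shell (HU around 1200), surrounded by air (HU -1000).  This is a
#' synthetic stand-in for a real head CT; it reproduces the air/bone/soft
#' tissue topology, not real anatomy.
#'
#' @param voxel_mm voxel size in mm.
#' @param seed RNG seed for the interior noise.
#' @param side_mm volume side length in mm.
#' @return integer (16-bit range) 3D HU array with attributes
#'   `spacing_mm`.
#' @export
synthetic_head_ct <- function(voxel_mm = 2, seed = 1, side_mm = 180) {
  n <- round(side_mm / voxel_mm)
  ctr <- (seq_len(n) - 0.5) * voxel_mm - side_mm / 2
  ax <- c(70, 85, 75)   # ellipsoid semi-axes, mm
  X <- array(rep(ctr, times = n * n), dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  r2 <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2
  hu <- array(-1000, dim = c(n, n, n))
  shell <- r2 <= 1 & r2 > 0.85
  inner <- r2 <= 0.85
  hu[shell] <- 1200
  # smooth interior noise: coarse white noise, separably upsampled
  set.seed(seed)
  nc <- max(3L, ceiling(n / 8))
  coarse <- array(stats::rnorm(nc^3, mean = 25, sd = 15), dim = rep(nc, 3))
  upsample1 <- function(v) {
    stats::approx(seq_along(v), v,
                  xout = (seq_len(n) - 0.5) / n * (length(v) - 1) + 1,
                  rule = 2)$y
  }
  up <- apply(coarse, c(2, 3), upsample1)                 # n x nc x nc
  up <- aperm(apply(up, c(1, 3), upsample1), c(2, 1, 3))  # n x n x nc
  up <- aperm(apply(up, c(1, 2), upsample1), c(2, 3, 1))  # n x n x n
  hu[inner] <- round(pmax(-100, pmin(100, up[inner])))
  hu <- round(hu)
  storage.mode(hu) <- "integer"
  attr(hu, "spacing_mm") <- rep(voxel_mm, 3)
  hu
}

#' Build a phantom from a Hounsfield-unit volume
#'
#' Applies [hu_to_material()] voxel-wise.
#'
#' @param hu integer/numeric 3D HU array.
#' @param spacing_mm voxel spacing (defaults to the `spacing_mm`
#'   attribute).
#' @param library material library.
#' @export
phantom_from_hu <- function(hu, spacing_mm = attr(hu, "spacing_mm"),
                            library = build_material_library()) {
  conv <- hu_to_material(as.numeric(hu), library)
  labels <- unique(conv$material)
  idx <- array(match(conv$material, labels), dim = dim(hu))
  dens <- array(conv$density, dim = dim(hu))
  voxel_phantom(idx, dens, spacing_mm, labels)
}
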