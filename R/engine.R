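# Fine-scale dose reconstruction: per coarse voxel the primary dose is
# modulated by the collimator fluence convolved with the electron
# kernel, and the scatter dose is added as a homogeneous bath:
#   D(fine) = D_scatter + D_primary * (K_el (*) nu)

# circular convolution of a periodic profile with a discrete kernel
# (offsets in bins); wraps kernels wider than the period
circular_convolve <- function(profile, kvals, koffs) {
  if (is.matrix(profile)) {
    n1 <- nrow(profile); n2 <- ncol(profile)
    kw <- matrix(0, n1, n2)
    i1 <- (koffs %% n1) + 1
    i2 <- (koffs %% n2) + 1
    for (a in seq_along(koffs)) {
      for (b in seq_along(koffs)) {
        kw[i1[a], i2[b]] <- kw[i1[a], i2[b]] + kvals[a, b]
      }
    }
    out <- Re(stats::fft(stats::fft(profile) * stats::fft(kw),
                         inverse = TRUE)) / (n1 * n2)
  } else {
    n <- length(profile)
    kw <- numeric(n)
    ii <- (koffs %% n) + 1
    for (a in seq_along(koffs)) kw[ii[a]] <- kw[ii[a]] + kvals[a]
    out <- Re(stats::fft(stats::fft(profile) * stats::fft(kw),
                         inverse = TRUE)) / n
  }
  out
}

#' Periodic modulation function
#'
#' Convolves the unit-mass discretised electron kernel with the
#' collimator fluence pattern over one period (circular convolution)
#' and rescales so the period mean is exactly 1.  This is the factor
#' that multiplies the voxel's primary dose on the fine grid.
#'
#' @param kernel an [electron_kernel()] whose dimensionality matches
#'   the fluence pattern (1D for planar, 2D for pencil).
#' @param nu a [fluence_pattern()].
#' @return numeric vector (1D) or matrix (2D) with unit mean; for an
#'   open field the scalar 1.
#' @export
modulation_function <- function(kernel, nu) {
  if (nu$dimensionality == 0) return(1)
  if (kernel$dimensionality != nu$dimensionality) {
    stop("kernel dimensionality (", kernel$dimensionality,
         ") does not match fluence pattern (", nu$dimensionality, ")")
  }
  ck <- cell_integrated_kernel(kernel, nu$bin_um)
  kv <- ck$values / sum(ck$values)   # unit mass
  M <- circular_convolve(nu$profile, kv, ck$offsets)
  M <- pmax(M, 0)
  M / mean(M)
}

#' Reconstruct the fine dose within one voxel
#'
#' @param d_primary,d_scatter coarse primary and scatter dose (Gy).
#' @param M modulation from [modulation_function()].
#' @return fine dose, `d_scatter + d_primary * M`; its mean over one
#'   period equals `d_scatter + d_primary`.
#' @export
reconstruct_voxel <- function(d_primary, d_scatter, M) {
  stopifnot(d_primary >= 0, d_scatter >= 0)
  d_scatter + d_primary * M
}

#' Fine-resolution dose grid
#'
#' @param dose 3D array, dims ordered (modulated lateral u, second
#'   lateral v, longitudinal w).
#' @param axes integer vector: phantom axis (1=x, 2=y, 3=z) of each
#'   array dimension.
#' @param spacing_mm grid spacing per dimension, mm.
#' @param origin_mm phantom-frame coordinate of the lower corner per
#'   dimension, mm.
#' @param meta provenance list.
#' @export
micro_dose_grid <- function(dose, axes, spacing_mm, origin_mm,
                            meta = list()) {
  stopifnot(length(dim(dose)) == 3, length(axes) == 3,
            all(sort(axes) == 1:3))
  structure(list(dose = dose, axes = axes,
                 spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm), meta = meta),
            class = "micro_dose_grid")
}

#' @export
print.micro_dose_grid <- function(x, ...) {
  cat("<micro_dose_grid>", paste(dim(x$dose), collapse = " x "),
      "bins, spacing", paste(signif(x$spacing * 1e3, 4), collapse = "/"),
      "um\n")
  invisible(x)
}

# finite (field-edge aware) modulation on the global comb raster:
# linear convolution of the clipped comb with the unit-mass kernel
finite_modulation <- function(kernel, col, width_mm, bin_um) {
  ck <- cell_integrated_kernel(kernel, bin_um)
  kv <- ck$values / sum(ck$values)
  support_um <- (length(kv) %/% 2 + 1) * bin_um
  ff <- fluence_field_1d(col, width_mm, bin_um,
                         margin_um = support_um + col$pitch_um)
  prof <- ff$profile
  n <- length(prof)
  J <- length(kv) %/% 2
  ext <- c(numeric(J), prof, numeric(J))
  out <- numeric(n)
  for (a in seq_along(kv)) {
    out <- out + kv[a] * ext[seq_len(n) + (a - 1)]
  }
  # bins are [m*bin, (m+1)*bin) relative to the field centre
  list(m = round(ff$u_um / bin_um - 0.5), M = out)
}

#' Reconstruct the fine-scale dose over a region of interest
#'
#' Applies the per-voxel convolution reconstruction to every coarse
#' voxel in the ROI.  Each voxel uses the electron kernel of its own
#' material (and density); within-field voxels use the periodic
#' modulation, voxels touching the lateral field edge use the finite
#' fluence support so the penumbra falls off over the kernel range.
#' The fine grid is fixed in the beam frame: `bin_um` along the
#' modulated lateral axis (5 um default), the coarse spacing along the
#' unmodulated lateral axis, and `long_um` along the beam axis.
#'
#' @param cubes a `dose_cube_pair` from [run_transport()].
#' @param beam the [beam_config()] used for the transport.
#' @param phantom the [voxel_phantom()].
#' @param roi_mm list with `lo` and `hi`, phantom-frame corners in mm
#'   (snapped outward to coarse voxel boundaries).
#' @param model a [stopping_model()].
#' @param library material library.
#' @param bin_um fine lateral bin, micrometres (must divide the pitch
#'   and the coarse spacing).
#' @param long_um fine longitudinal bin, micrometres.
#' @return a [micro_dose_grid()].
#' @export
reconstruct_field <- function(cubes, beam, phantom, roi_mm,
                              model = stopping_model(),
                              library = build_material_library(),
                              bin_um = 5, long_um = 500) {
  if (beam$collimator$type == "pencil") {
    return(reconstruct_field_pencil(cubes, beam, phantom, roi_mm, model,
                                    library, bin_um, long_um))
  }
  ba <- beam_axes(beam$direction)
  dims <- phantom$dims; sp <- phantom$spacing; ext <- dims * sp
  au <- ba$lat1; av <- ba$lat2; aw <- ba$axis
  # snap ROI to coarse voxels
  lo <- pmax(floor(roi_mm$lo / sp), 0)
  hi <- pmin(ceiling(roi_mm$hi / sp), dims)
  if (any(hi <= lo)) stop("ROI outside the dose cubes")
  vox_u <- (lo[au] + 1):hi[au]
  vox_v <- (lo[av] + 1):hi[av]
  vox_w <- (lo[aw] + 1):hi[aw]
  bin_mm <- bin_um / 1e3; long_mm <- long_um / 1e3
  npu <- round(sp[au] / bin_mm)     # fine bins per voxel, lateral
  npw <- round(sp[aw] / long_mm)    # fine bins per voxel, longitudinal
  if (abs(npu * bin_mm - sp[au]) > 1e-9 || abs(npw * long_mm - sp[aw]) > 1e-9) {
    stop("fine grid must nest integrally inside the coarse grid")
  }
  n_u <- length(vox_u) * npu
  n_v <- length(vox_v)
  n_w <- length(vox_w) * npw
  out <- array(0, dim = c(n_u, n_v, n_w))

  open_field <- beam$collimator$type == "open"
  col <- beam$collimator
  c_u <- ext[au] / 2                      # comb centred on the phantom axis
  poly_u <- beam$field_polygon[, 1]
  W_mm <- max(poly_u) - min(poly_u)       # lateral field width
  origin_u <- lo[au] * sp[au]
  # global comb bin index of the first fine bin
  m0 <- round((origin_u - c_u) / bin_mm)
  if (abs((origin_u - c_u) / bin_mm - m0) > 1e-6) {
    stop("ROI must be aligned with the fine-grid raster")
  }

  nu <- if (open_field) NULL else
    fluence_pattern(collimator("planar", col$slit_width_um, col$pitch_um),
                    bin_um)
  nb <- if (open_field) 1L else length(nu$profile)

  # kernels and modulations per (material, density) pair present in ROI
  key_of <- function(mi, de) paste0(mi, "@", signif(de, 6))
  cacheM <- new.env(parent = emptyenv())
  get_mod <- function(mi, de) {
    key <- key_of(mi, de)
    got <- cacheM[[key]]
    if (!is.null(got)) return(got)
    mat <- library[[phantom$materials[mi]]]
    kern <- polychromatic_kernel(beam$spectrum, mat, model, 1, density = de)
    ans <- list(
      periodic = if (open_field) 1 else modulation_function(kern, nu),
      finite = if (open_field) NULL else
        finite_modulation(kern, col, W_mm, bin_um),
      support_um = kern$max_sigma * 1e4)
    cacheM[[key]] <- ans
    ans
  }

  idx3 <- function(iu, iv, iw) {        # phantom voxel index per beam axes
    ii <- integer(3)
    ii[au] <- iu; ii[av] <- iv; ii[aw] <- iw
    ii
  }
  for (ku in seq_along(vox_u)) {
    iu <- vox_u[ku]
    # global comb indices of this voxel's fine bins
    mg <- m0 + (ku - 1) * npu + seq_len(npu) - 1
    ulo <- (iu - 1) * sp[au] - c_u; uhi <- iu * sp[au] - c_u
    for (kv_ in seq_along(vox_v)) {
      iv <- vox_v[kv_]
      for (kw in seq_along(vox_w)) {
        iw <- vox_w[kw]
        ii <- idx3(iu, iv, iw)
        dp <- cubes$primary[ii[1], ii[2], ii[3]]
        ds <- cubes$scatter[ii[1], ii[2], ii[3]]
        if (open_field || dp == 0) {
          seg <- rep(ds + dp, npu)
        } else {
          mi <- phantom$material_index[ii[1], ii[2], ii[3]]
          de <- phantom$density[ii[1], ii[2], ii[3]]
          md <- get_mod(mi, de)
          s_mm <- (md$support_um + bin_um) / 1e3
          edge <- ulo < -W_mm / 2 + s_mm || uhi > W_mm / 2 - s_mm
          if (!edge) {
            seg <- ds + dp * md$periodic[(mg %% nb) + 1]
          } else {
            # envelope coverage of the voxel (uniform-fluence fraction)
            cov <- max(0, min(uhi, W_mm / 2) - max(ulo, -W_mm / 2)) /
              (uhi - ulo)
            Mv <- md$finite$M[match(mg, md$finite$m)]
            Mv[is.na(Mv)] <- 0
            if (cov > 0) Mv <- Mv / cov
            seg <- ds + dp * Mv
          }
        }
        u_id <- (ku - 1) * npu + seq_len(npu)
        w_id <- (kw - 1) * npw + seq_len(npw)
        out[u_id, kv_, w_id] <- seg      # recycled along w block
      }
    }
  }
  orig <- numeric(3)
  orig[1] <- origin_u
  orig[2] <- lo[av] * sp[av]
  orig[3] <- lo[aw] * sp[aw]
  micro_dose_grid(out, axes = c(au, av, aw),
                  spacing_mm = c(bin_mm, sp[av], long_mm),
                  origin_mm = orig,
                  meta = list(direction = beam$direction,
                              collimator = col, comb_centre_mm = c_u,
                              histories = cubes$histories))
}

# pencil-beam variant: both lateral axes modulated by the 2D pattern
reconstruct_field_pencil <- function(cubes, beam, phantom, roi_mm, model,
                                     library, bin_um, long_um) {
  ba <- beam_axes(beam$direction)
  dims <- phantom$dims; sp <- phantom$spacing; ext <- dims * sp
  au <- ba$lat1; av <- ba$lat2; aw <- ba$axis
  lo <- pmax(floor(roi_mm$lo / sp), 0)
  hi <- pmin(ceiling(roi_mm$hi / sp), dims)
  if (any(hi <= lo)) stop("ROI outside the dose cubes")
  vox_u <- (lo[au] + 1):hi[au]; vox_v <- (lo[av] + 1):hi[av]
  vox_w <- (lo[aw] + 1):hi[aw]
  bin_mm <- bin_um / 1e3; long_mm <- long_um / 1e3
  npu <- round(sp[au] / bin_mm); npv <- round(sp[av] / bin_mm)
  npw <- round(sp[aw] / long_mm)
  nu <- fluence_pattern(beam$collimator, bin_um)
  nb <- nrow(nu$profile)
  c_u <- ext[au] / 2; c_v <- ext[av] / 2
  m0u <- round((lo[au] * sp[au] - c_u) / bin_mm)
  m0v <- round((lo[av] * sp[av] - c_v) / bin_mm)
  out <- array(0, dim = c(length(vox_u) * npu, length(vox_v) * npv,
                          length(vox_w) * npw))
  cacheM <- new.env(parent = emptyenv())
  get_mod <- function(mi, de) {
    key <- paste0(mi, "@", signif(de, 6))
    got <- cacheM[[key]]
    if (!is.null(got)) return(got)
    mat <- library[[phantom$materials[mi]]]
    kern <- polychromatic_kernel(beam$spectrum, mat, model, 2, density = de)
    ans <- modulation_function(kern, nu)
    cacheM[[key]] <- ans
    ans
  }
  for (ku in seq_along(vox_u)) {
    mgu <- (m0u + (ku - 1) * npu + seq_len(npu) - 1) %% nb + 1
    for (kv_ in seq_along(vox_v)) {
      mgv <- (m0v + (kv_ - 1) * npv + seq_len(npv) - 1) %% nb + 1
      for (kw in seq_along(vox_w)) {
        ii <- integer(3)
        ii[au] <- vox_u[ku]; ii[av] <- vox_v[kv_]; ii[aw] <- vox_w[kw]
        dp <- cubes$primary[ii[1], ii[2], ii[3]]
        ds <- cubes$scatter[ii[1], ii[2], ii[3]]
        if (dp == 0) {
          blk <- matrix(ds, npu, npv)
        } else {
          M <- get_mod(phantom$material_index[ii[1], ii[2], ii[3]],
                       phantom$density[ii[1], ii[2], ii[3]])
          blk <- ds + dp * M[mgu, mgv]
        }
        u_id <- (ku - 1) * npu + seq_len(npu)
        v_id <- (kv_ - 1) * npv + seq_len(npv)
        w_id <- (kw - 1) * npw + seq_len(npw)
        out[u_id, v_id, w_id] <- array(blk, c(npu, npv, npw))
      }
    }
  }
  micro_dose_grid(out, axes = c(au, av, aw),
                  spacing_mm = c(bin_mm, bin_mm, long_mm),
                  origin_mm = c(lo[au] * sp[au], lo[av] * sp[av],
                                lo[aw] * sp[aw]),
                  meta = list(direction = beam$direction,
                              collimator = beam$collimator,
                              comb_centre_mm = c(c_u, c_v),
                              histories = cubes$histories))
}

#' Sample a micro dose grid at phantom-frame points (trilinear)
#'
#' @param grid a [micro_dose_grid()].
#' @param pts N x 3 matrix of phantom-frame coordinates, mm.
#' @param outside value returned outside the grid (default NA).
#' @export
sample_micro_grid <- function(grid, pts, outside = NA_real_) {
  d <- dim(grid$dose)
  # fractional index along each grid dimension
  f <- sapply(1:3, function(k) {
    (pts[, grid$axes[k]] - grid$origin[k]) / grid$spacing[k] + 0.5
  })
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  out <- rep(outside, nrow(pts))
  ok <- f[, 1] >= 0.5 & f[, 1] <= d[1] + 0.5 &
    f[, 2] >= 0.5 & f[, 2] <= d[2] + 0.5 &
    f[, 3] >= 0.5 & f[, 3] <= d[3] + 0.5
  if (!any(ok)) return(out)
  g <- pmin(pmax(f[ok, , drop = FALSE], 1), rep(d, each = sum(ok)))
  i0 <- pmin(pmax(floor(g), 1), rep(pmax(d - 1, 1), each = sum(ok)))
  t <- g - i0
  acc <- numeric(sum(ok))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ii <- pmin(i0[, 1] + cx, d[1])
    jj <- pmin(i0[, 2] + cy, d[2])
    kk <- pmin(i0[, 3] + cz, d[3])
    w <- (ifelse(cx == 1, t[, 1], 1 - t[, 1])) *
      (ifelse(cy == 1, t[, 2], 1 - t[, 2])) *
      (ifelse(cz == 1, t[, 3], 1 - t[, 3]))
    acc <- acc + w * grid$dose[cbind(ii, jj, kk)]
  }
  out[ok] <- acc
  out
}

#' Superpose cross-fired fields on a common grid
#'
#' Resamples each field's fine grid onto a common phantom-frame grid by
#' trilinear interpolation and sums the doses (dose linearity).
#'
#' @param fields list of [micro_dose_grid()] objects.
#' @param spacing_mm length-3 spacing of the common grid (x, y, z).
#' @param roi_mm list with `lo`, `hi` corners in mm; default is the
#'   intersection of the fields' extents.
#' @return a [micro_dose_grid()] in phantom axis order.
#' @export
assemble_cross_fire <- function(fields, spacing_mm, roi_mm = NULL) {
  stopifnot(length(fields) >= 1)
  exts <- lapply(fields, function(g) {
    lo <- hi <- numeric(3)
    lo[g$axes] <- g$origin
    hi[g$axes] <- g$origin + dim(g$dose) * g$spacing
    list(lo = lo, hi = hi)
  })
  if (is.null(roi_mm)) {
    lo <- do.call(pmax, lapply(exts, `[[`, "lo"))
    hi <- do.call(pmin, lapply(exts, `[[`, "hi"))
  } else {
    lo <- roi_mm$lo; hi <- roi_mm$hi
  }
  if (any(hi <= lo)) stop("fields do not overlap")
  n <- pmax(1, round((hi - lo) / spacing_mm))
  xs <- lapply(1:3, function(k) lo[k] + (seq_len(n[k]) - 0.5) * spacing_mm[k])
  pts <- as.matrix(expand.grid(xs[[1]], xs[[2]], xs[[3]]))
  acc <- numeric(nrow(pts))
  for (g in fields) acc <- acc + sample_micro_grid(g, pts, outside = 0)
  micro_dose_grid(array(acc, n), axes = 1:3, spacing_mm = spacing_mm,
                  origin_mm = lo,
                  meta = list(n_fields = length(fields)))
}
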