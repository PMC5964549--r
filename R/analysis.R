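# PVDR, profile and DVH analysis of reconstructed fine-dose grids.

#' Extract a lateral dose profile at a given depth
#'
#' Dose versus position along the modulated lateral axis, averaged over
#' the longitudinal bin containing `depth_mm` (and optionally over the
#' second lateral axis).
#'
#' @param grid a [micro_dose_grid()] (beam-frame dims u, v, w).
#' @param depth_mm depth along the beam axis, phantom-frame mm.
#' @param v_mm position along the unmodulated lateral axis (phantom-frame
#'   mm); `NULL` averages over v.
#' @return data.frame with `position_um` (relative to the collimator
#'   comb centre) and `dose`.
#' @export
extract_profile <- function(grid, depth_mm, v_mm = NULL) {
  d <- dim(grid$dose)
  kw <- floor((depth_mm - grid$origin[3]) / grid$spacing[3]) + 1
  if (kw < 1 || kw > d[3]) stop("requested depth outside the grid")
  sl <- grid$dose[, , kw, drop = FALSE]
  if (is.null(v_mm)) {
    prof <- rowMeans(sl[, , 1, drop = FALSE])
  } else {
    kv <- floor((v_mm - grid$origin[2]) / grid$spacing[2]) + 1
    if (kv < 1 || kv > d[2]) stop("requested line outside the grid")
    prof <- sl[, kv, 1]
  }
  ctr <- grid$meta$comb_centre_mm
  if (is.null(ctr)) ctr <- grid$origin[1] + d[1] * grid$spacing[1] / 2
  u <- (grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1] -
          ctr[1]) * 1e3
  data.frame(position_um = u, dose = prof)
}

#' Peak and valley dose and PVDR of a microbeam profile
#'
#' Peak dose: mean over the central 10 um of each slit, averaged over
#' interior slits (first and last slit excluded).  Valley dose: mean
#' over the central 100 um of each gap, averaged over interior gaps.
#' These region widths are a declared convention of this package.
#'
#' @param profile data.frame from [extract_profile()] (positions
#'   relative to the comb centre; slit centres at multiples of the
#'   pitch).
#' @param col the planar [collimator()].
#' @param peak_window_um,valley_window_um averaging window widths.
#' @return list with `peak`, `valley`, `pvdr`, `n_slits`.
#' @export
pvdr <- function(profile, col, peak_window_um = 10,
                 valley_window_um = 100) {
  pitch <- col$pitch_um
  u <- profile$position_um
  span <- max(u) - min(u)
  if (span < 3 * pitch) stop("profile must span at least 3 periods")
  kmax <- floor(max(u) / pitch)
  kmin <- ceiling(min(u) / pitch)
  ks <- seq(kmin, kmax)
  if (length(ks) < 3) stop("profile must span at least 3 slit positions")
  # drop comb positions outside the irradiated field (the profile may
  # extend beyond the field edge): a genuine slit carries at least 10%
  # of the strongest slit's dose
  wm <- vapply(ks, function(k) {
    mean(profile$dose[abs(u - k * pitch) <= peak_window_um / 2])
  }, numeric(1))
  ks <- ks[wm > 0.1 * max(wm)]
  if (length(ks) < 3) stop("profile must span at least 3 slit positions")
  # interior slits only
  ks <- ks[-c(1, length(ks))]
  peak <- mean(vapply(ks, function(k) {
    mean(profile$dose[abs(u - k * pitch) <= peak_window_um / 2])
  }, numeric(1)))
  valley <- mean(vapply(ks[-length(ks)], function(k) {
    mean(profile$dose[abs(u - (k + 0.5) * pitch) <= valley_window_um / 2])
  }, numeric(1)))
  list(peak = peak, valley = valley, pvdr = peak / valley,
       n_slits = length(ks))
}

#' PVDR as a function of depth
#'
#' Applies [pvdr()] to the profile at every longitudinal bin of the
#' grid.  Approximate 95% confidence intervals are propagated from the
#' coarse dose cubes when provided.
#'
#' @param grid a [micro_dose_grid()].
#' @param col planar [collimator()].
#' @param cubes optional `dose_cube_pair` used for the uncertainty of
#'   peak and valley (relative CI of the underlying primary and
#'   scatter voxel doses on the central axis).
#' @return data.frame with `depth_mm`, `peak`, `valley`, `pvdr` and,
#'   if `cubes` is given, `peak_ci95`, `valley_ci95`, `pvdr_ci95`.
#' @export
pvdr_vs_depth <- function(grid, col, cubes = NULL) {
  d <- dim(grid$dose)
  depths <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing[3]
  rows <- lapply(seq_len(d[3]), function(kw) {
    g2 <- grid
    pr <- extract_profile(grid, depths[kw])
    pv <- pvdr(pr, col)
    data.frame(depth_mm = depths[kw], peak = pv$peak,
               valley = pv$valley, pvdr = pv$pvdr)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cubes)) {
    # relative uncertainty of the central-axis coarse doses at depth
    dims <- dim(cubes$primary)
    ax <- beam_axes(cubes$beam_direction)
    ic <- pmax(1, round(dims / 2))
    relci <- vapply(out$depth_mm, function(z) {
      ii <- ic
      ii[ax$axis] <- pmin(pmax(floor(z / cubes$spacing[ax$axis]) + 1, 1),
                          dims[ax$axis])
      p <- cubes$primary[ii[1], ii[2], ii[3]]
      s <- cubes$scatter[ii[1], ii[2], ii[3]]
      cp <- cubes$primary_ci95[ii[1], ii[2], ii[3]]
      cs <- cubes$scatter_ci95[ii[1], ii[2], ii[3]]
      c(if (p > 0) cp / p else 0, if (s > 0) cs / s else 0)
    }, numeric(2))
    out$peak_ci95 <- out$peak * relci[1, ]
    out$valley_ci95 <- out$valley * relci[2, ]
    out$pvdr_ci95 <- out$pvdr * sqrt(relci[1, ]^2 + relci[2, ]^2)
  }
  out
}

#' Cumulative dose-volume histogram
#'
#' Exact empirical complementary CDF: the volume fraction receiving at
#' least each dose level.
#'
#' @param grid a [micro_dose_grid()] or a numeric array/vector of dose.
#' @param mask optional logical mask selecting the scored volume.
#' @param dose_grid optional dose levels; defaults to the sorted unique
#'   doses (prepended with 0).
#' @return data.frame with `dose` and `volume_fraction`
#'   (monotone non-increasing, starting at 1).
#' @export
dvh <- function(grid, mask = NULL, dose_grid = NULL) {
  v <- if (inherits(grid, "micro_dose_grid")) as.numeric(grid$dose)
       else as.numeric(grid)
  if (!is.null(mask)) v <- v[as.logical(mask)]
  if (length(v) == 0) stop("empty mask")
  sv <- sort(v)
  if (is.null(dose_grid)) dose_grid <- unique(c(0, sv))
  n <- length(sv)
  frac <- 1 - (findInterval(dose_grid, sv, left.open = TRUE)) / n
  data.frame(dose = dose_grid, volume_fraction = frac)
}

#' Mean dose from a DVH (integral identity check)
#'
#' The area under the cumulative DVH equals the mean dose over the
#' mask.
#'
#' @param curve data.frame from [dvh()] (evaluated on the full set of
#'   unique doses).
#' @export
dvh_mean_dose <- function(curve) {
  # integrate the step function: V(d) is constant on (d_i, d_(i+1)]
  d <- curve$dose; v <- curve$volume_fraction
  sum(diff(d) * v[-1]) + d[1]
}

#' Relative-difference report between two dose grids
#'
#' @param a,b numeric arrays (same geometry) or `micro_dose_grid`s.
#' @param mask optional logical mask.
#' @return list with `rel` (array of (a-b)/b, NA where b == 0), `max`,
#'   `mean`, `mean_abs`.
#' @export
compare_grids <- function(a, b, mask = NULL) {
  va <- if (inherits(a, "micro_dose_grid")) a$dose else a
  vb <- if (inherits(b, "micro_dose_grid")) b$dose else b
  if (!all(dim(va) == dim(vb))) stop("grids have different geometry")
  rel <- (va - vb) / ifelse(vb == 0, NA, vb)
  sel <- if (is.null(mask)) !is.na(rel) else as.logical(mask) & !is.na(rel)
  list(rel = rel, max = max(abs(rel[sel])), mean = mean(rel[sel]),
       mean_abs = mean(abs(rel[sel])))
}
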