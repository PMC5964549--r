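# MetaImage (.mha, local uncompressed data) volume I/O and CSV/JSON
# exports.  The single-file MetaImage layout is a plain-text header
# followed by raw little-endian voxel data.

MHA_TYPES <- list(MET_DOUBLE = list(what = "double", size = 8),
                  MET_FLOAT  = list(what = "double", size = 4),
                  MET_SHORT  = list(what = "integer", size = 2),
                  MET_UCHAR  = list(what = "integer", size = 1))

#' Write a 3D volume as MetaImage (.mha)
#'
#' @param x 3D numeric/integer array.
#' @param path output file (.mha).
#' @param spacing_mm length-3 voxel spacing (default from the
#'   `spacing_mm` attribute, else 1).
#' @param type element type: MET_DOUBLE, MET_FLOAT, MET_SHORT or
#'   MET_UCHAR.
#' @export
write_mha <- function(x, path, spacing_mm = NULL, type = "MET_DOUBLE") {
  stopifnot(length(dim(x)) == 3, type %in% names(MHA_TYPES))
  if (is.null(spacing_mm)) {
    spacing_mm <- attr(x, "spacing_mm")
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  }
  tp <- MHA_TYPES[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1", "Offset = 0 0 0",
           paste("ElementSpacing =", paste(spacing_mm, collapse = " ")),
           paste("DimSize =", paste(dim(x), collapse = " ")),
           paste("ElementType =", type), "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  vals <- as.vector(x)
  if (tp$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = tp$size,
             endian = "little")
  } else {
    writeBin(as.double(vals), con, size = tp$size, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mha) volume
#'
#' Supports 3D local uncompressed little-endian data of type
#' MET_DOUBLE, MET_FLOAT, MET_SHORT or MET_UCHAR.
#'
#' @param path .mha file.
#' @return 3D array with attribute `spacing_mm`.
#' @export
read_mha <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw_all == as.raw(10))
  hdr <- character(); data_at <- NA
  start <- 1
  for (pos in nl) {
    line <- rawToChar(raw_all[start:(pos - 1)])
    hdr <- c(hdr, line)
    start <- pos + 1
    if (grepl("^ElementDataFile", line)) { data_at <- start; break }
  }
  if (is.na(data_at)) stop("no ElementDataFile key in header")
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*= *", "", ln[1]))
  }
  if (!identical(get("CompressedData"), "False")) {
    stop("compressed MetaImage not supported")
  }
  if (!identical(get("ElementDataFile"), "LOCAL")) {
    stop("only local (single-file) MetaImage supported")
  }
  dims <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  type <- get("ElementType")
  tp <- MHA_TYPES[[type]]
  if (is.null(tp)) stop("unsupported element type ", type)
  n <- prod(dims)
  vals <- readBin(raw_all[data_at:length(raw_all)], tp$what, n = n,
                  size = tp$size, endian = "little",
                  signed = !(type == "MET_UCHAR"))
  x <- array(vals, dims)
  attr(x, "spacing_mm") <- spacing
  x
}

#' Write a dose cube pair (two .mha volumes plus a JSON sidecar)
#'
#' @param cubes a `dose_cube_pair`.
#' @param prefix path prefix; writes `<prefix>_primary.mha`,
#'   `<prefix>_scatter.mha`, `<prefix>.json`.
#' @export
write_dose_cubes <- function(cubes, prefix) {
  write_mha(cubes$primary, paste0(prefix, "_primary.mha"), cubes$spacing)
  write_mha(cubes$scatter, paste0(prefix, "_scatter.mha"), cubes$spacing)
  meta <- list(histories = cubes$histories, batches = cubes$batches,
               seed = cubes$seed, beam_direction = cubes$beam_direction,
               energy = cubes$energy)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Write a micro dose grid as MetaImage
#' @param grid a [micro_dose_grid()].
#' @param path output .mha.
#' @export
write_micro_grid <- function(grid, path) {
  write_mha(grid$dose, path, grid$spacing)
}

#' Write a lateral profile as CSV (position_um, dose)
#' @param profile data.frame from [extract_profile()].
#' @param path output CSV.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Export an electron kernel (CSV values + JSON metadata)
#'
#' Writes `<prefix>.csv` with cell-integrated (distance_um, value)
#' pairs and `<prefix>.json` with the kernel parameters.
#'
#' @param kernel an [electron_kernel()].
#' @param prefix path prefix.
#' @param bin_um discretisation pitch, micrometres.
#' @export
export_kernel <- function(kernel, prefix, bin_um = 1) {
  ck <- cell_integrated_kernel(kernel, bin_um)
  if (kernel$dimensionality == 2) {
    ctr <- which(ck$offsets == 0)
    vals <- ck$values[, ctr]
  } else {
    vals <- ck$values
  }
  utils::write.csv(data.frame(distance_um = ck$offsets * bin_um,
                              value_keV_per_g = vals),
                   paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(dimensionality = kernel$dimensionality, rho = kernel$rho,
               alpha = kernel$alpha, mean_energy_keV = kernel$mean_energy,
               max_sigma_cm = kernel$max_sigma,
               components = kernel$components)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(prefix)
}

#' Write a voxel phantom (material index + density volumes)
#'
#' @param phantom a [voxel_phantom()].
#' @param prefix writes `<prefix>_materials.mha` (MET_SHORT),
#'   `<prefix>_density.mha` (MET_DOUBLE) and `<prefix>.json`.
#' @export
write_phantom <- function(phantom, prefix) {
  write_mha(phantom$material_index, paste0(prefix, "_materials.mha"),
            phantom$spacing, type = "MET_SHORT")
  write_mha(phantom$density, paste0(prefix, "_density.mha"),
            phantom$spacing)
  jsonlite::write_json(list(materials = phantom$materials,
                            spacing_mm = phantom$spacing),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a voxel phantom written by [write_phantom()]
#' @param prefix path prefix.
#' @export
read_phantom <- function(prefix) {
  mi <- read_mha(paste0(prefix, "_materials.mha"))
  de <- read_mha(paste0(prefix, "_density.mha"))
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  attr(mi, "spacing_mm") <- NULL
  attr(de, "spacing_mm") <- NULL
  storage.mode(mi) <- "integer"
  voxel_phantom(mi, de, meta$spacing_mm, meta$materials)
}
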