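#' Write a phantom to a volume container directory
#'
#' The dynamic series is written as a 4-D NIfTI volume with a JSON sidecar
#' carrying the acquisition times, stack assignment, pixel geometry, aorta
#' region and a spec echo; the ground truth as a companion NIfTI volume
#' plus a CSV of per-sector truth.
#'
#' @param phantom a `ctmpi_phantom` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ctmpi_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- phantom$series
  RNifti::writeNifti(RNifti::asNifti(
    s$volumes, pixdim = c(s$pixel_mm, s$pixel_mm, s$slice_thickness_mm, 1)),
    file.path(dir, "series.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(
    phantom$truth$true_mbf,
    pixdim = c(s$pixel_mm, s$pixel_mm, s$slice_thickness_mm)),
    file.path(dir, "true_mbf.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(
    phantom$truth$sector_of_voxel + 0,
    pixdim = c(s$pixel_mm, s$pixel_mm, s$slice_thickness_mm)),
    file.path(dir, "sectors.nii.gz"))
  spec <- phantom$truth$spec
  sidecar <- list(
    times_s = s$times_s, stack_of_slice = s$stack_of_slice,
    pixel_mm = s$pixel_mm, slice_thickness_mm = s$slice_thickness_mm,
    aif_region = which(s$aif_mask) - 1L,  # 0-based voxel indices
    spec = spec[setdiff(names(spec), c("sectors", "aif_params"))],
    aif_params = unclass(spec$aif_params),
    sectors = lapply(spec$sectors, unclass)
  )
  jsonlite::write_json(sidecar, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(phantom$truth$sector_table,
                   file.path(dir, "sector_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phantom container directory
#'
#' @param dir directory written by [write_phantom()].
#' @return a `ctmpi_phantom`-like list with `series` and partial `truth`
#'   (the true MBF volume, sector labels and sector table).
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  volumes <- array(as.numeric(RNifti::readNifti(
    file.path(dir, "series.nii.gz"))), dim = dim(RNifti::readNifti(
      file.path(dir, "series.nii.gz"))))
  times <- matrix(as.numeric(side$times_s), nrow = 2, byrow = FALSE)
  rownames(times) <- c("cranial", "caudal")
  aif_mask <- array(FALSE, dim(volumes)[1:3])
  aif_mask[side$aif_region + 1L] <- TRUE
  series <- structure(
    list(volumes = volumes, times_s = times,
         stack_of_slice = side$stack_of_slice, pixel_mm = side$pixel_mm,
         slice_thickness_mm = side$slice_thickness_mm, aif_mask = aif_mask),
    class = "perfusion_series"
  )
  tm <- RNifti::readNifti(file.path(dir, "true_mbf.nii.gz"))
  sec <- RNifti::readNifti(file.path(dir, "sectors.nii.gz"))
  truth <- structure(
    list(true_mbf = array(as.numeric(tm), dim(tm)),
         sector_of_voxel = array(as.integer(round(as.numeric(sec))),
                                 dim(sec)),
         sector_table = utils::read.csv(file.path(dir, "sector_truth.csv")),
         true_aif = do.call(aif_params, as.list(side$aif_params)),
         spec = side$spec),
    class = "phantom_truth"
  )
  structure(list(series = series, truth = truth), class = "ctmpi_phantom")
}

#' Write an MBF map container
#'
#' @param map an `mbf_map`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_mbf_map <- function(map, dir) {
  stopifnot(inherits(map, "mbf_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- map$mbf
  vol[is.na(vol)] <- -1  # sentinel outside the mask
  RNifti::writeNifti(RNifti::asNifti(
    vol, pixdim = c(map$pixel_mm, map$pixel_mm, map$slice_thickness_mm)),
    file.path(dir, "mbf.nii.gz"))
  jsonlite::write_json(
    list(pixel_mm = map$pixel_mm,
         slice_thickness_mm = map$slice_thickness_mm,
         slice_increment_mm = map$slice_increment_mm,
         na_sentinel = -1),
    file.path(dir, "mbf.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an MBF map container
#'
#' @param dir directory written by [write_mbf_map()].
#' @return an `mbf_map`.
#' @export
read_mbf_map <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "mbf.json"),
                              simplifyVector = TRUE)
  vol <- RNifti::readNifti(file.path(dir, "mbf.nii.gz"))
  dm <- dim(vol)
  if (length(dm) == 2) dm <- c(dm, 1L)  # singleton slice dropped by NIfTI
  mbf <- array(as.numeric(vol), dm)
  mbf[mbf == side$na_sentinel] <- NA_real_
  structure(
    list(mbf = mbf, mask = !is.na(mbf), converged = !is.na(mbf),
         transit_s = NULL, delay_s = NULL, pixel_mm = side$pixel_mm,
         slice_thickness_mm = side$slice_thickness_mm,
         slice_increment_mm = side$slice_increment_mm),
    class = "mbf_map"
  )
}

#' Write / read a territory table
#'
#' @param records territory data.frame.
#' @param path CSV path.
#' @return the path / the data.frame.
#' @export
write_territories <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_territories
#' @export
read_territories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
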