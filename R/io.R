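# On-disk dialect shared by the generator and the quantification stages.
#
# Histology masks: single-page 8-bit TIFF, 255 = tissue, 0 = air; the pixel
# size travels in the manifest, never in TIFF tags. Leukocyte coordinates:
# CSV with header x_um,y_um. Volumes and slices: NIfTI-1 float32, label masks
# as NIfTI integer codes (1 lung, 2 muscle, 3 kidney, 4 water, 5 air, 6 VOI).
# Manifest: CSV subject_id,group,week,modality,path,pixel_size_um,area_mm2,
# aux_path,truth_json (paths relative to the manifest's directory).

#' Write / read a histology mask TIFF
#'
#' @param section A [histology_section()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_histology_tiff <- function(section, path) {
  stopifnot(inherits(section, "histology_section"))
  tiff::writeTIFF(section$tissue_mask * 1, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_histology_tiff
#' @param pixel_size_um Pixel size, um (from the manifest).
#' @param invert Set `TRUE` when the file uses the opposite polarity
#'   (255 = air); the mask is inverted on read.
#' @param section_id,subject_id Identifiers for the returned section.
#' @export
read_histology_tiff <- function(path, pixel_size_um, invert = FALSE,
                                section_id = "S1", subject_id = "M1") {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]   # tolerate grey-stored RGB
  mask <- img > 0.5
  if (invert) mask <- !mask
  histology_section(mask, pixel_size_um, section_id = section_id,
                    subject_id = subject_id)
}

#' Write / read leukocyte coordinates
#'
#' @param points A [leukocyte_points()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(inherits(points, "leukocyte_points"))
  utils::write.csv(data.frame(x_um = points$x_um, y_um = points$y_um),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @param section_area_mm2 Scored area, mm^2 (from the manifest).
#' @param section_id,subject_id Identifiers for the returned point set.
#' @export
read_points_csv <- function(path, section_area_mm2,
                            section_id = "S1", subject_id = "M1") {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("points CSV must have columns x_um,y_um")
  leukocyte_points(df$x_um, df$y_um, section_area_mm2, section_id, subject_id)
}

#' Write / read a volume or slice as NIfTI-1
#'
#' @param data Numeric array (2-D or 3-D); integer label arrays are stored as
#'   float and rounded back on read by [read_labels_nifti()].
#' @param path Output `.nii` path.
#' @param voxel_size_um Isotropic voxel size, um (stored in the header).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(data, path, voxel_size_um = 18) {
  arr <- array(as.numeric(data), dim = dim(data))
  attr(arr, "pixdim") <- rep(voxel_size_um / 1000, length(dim(arr)))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_size_um") <- RNifti::pixdim(img)[1L] * 1000
  arr
}

#' @rdname write_volume_nifti
#' @export
read_labels_nifti <- function(path) {
  arr <- read_volume_nifti(path)
  vs <- attr(arr, "voxel_size_um")
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  attr(arr, "voxel_size_um") <- vs
  arr
}

#' Read a study manifest
#'
#' @param path Manifest CSV path.
#' @return Data frame with an attribute `manifest_dir` used to resolve the
#'   relative `path`/`aux_path` columns.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "week", "modality", "path", "truth_json")
  if (!all(need %in% names(mf)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(mf)), collapse = ", "))
  attr(mf, "manifest_dir") <- dirname(normalizePath(path))
  mf
}

.resolve_path <- function(mf, p) file.path(attr(mf, "manifest_dir"), p)
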