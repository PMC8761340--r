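#' 3D scalar volume
#'
#' Core grid data model: a 3D array of intensities with voxel spacing (mm),
#' a voxel-to-world affine, and a sequence label. Voxel indexing is 0-based
#' throughout the package and axis order is (x, y, z), matching the on-disk
#' array order of NIfTI.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param sequence sequence label, one of `"T1"`, `"T1GAD"`, `"STIR"`,
#'   `"OTHER"`.
#' @param v2w optional 4x4 voxel-to-world affine (0-based voxel indices to
#'   world mm). Defaults to `diag(spacing)` with origin 0.
#' @return An object of class `mvseg_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), sequence = "OTHER", v2w = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), "D")
  if (any(dim(data) < 1L)) stop("volume dimensions must all be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  sequence <- match.arg(sequence, c("T1", "T1GAD", "STIR", "OTHER"))
  if (is.null(v2w)) v2w <- diag(c(spacing, 1))
  stopifnot(is.matrix(v2w), all(dim(v2w) == c(4L, 4L)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 v2w = unname(v2w), sequence = sequence),
            class = "mvseg_volume")
}

#' Binary label mask
#'
#' A volume whose voxels are restricted to \{0, 1\}; used for reference tumor
#' segmentations, occupancy masks, and predictions. Stored as integer data so
#' NIfTI round trips are exact.
#'
#' @inheritParams volume
#' @return An object of class `c("mvseg_mask", "mvseg_volume")`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), v2w = NULL) {
  data <- as.array(data)
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(data) <- "integer"
  v <- volume(data, spacing, "OTHER", v2w)
  class(v) <- c("mvseg_mask", "mvseg_volume")
  v
}

is_mask <- function(x) inherits(x, "mvseg_mask")

#' @export
print.mvseg_volume <- function(x, ...) {
  cat(sprintf("<%s> %s  dim %s  spacing %s mm\n",
              class(x)[1], x$sequence, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' One subject with all sequences and the reference segmentation
#'
#' @param case_id character identifier.
#' @param t1,stir [volume()] objects; required.
#' @param t1gad [volume()] or `NULL` (the contrast channel may be absent; the
#'   channel is zeroed downstream).
#' @param reference [label_mask()] on the T1 grid.
#' @param location tumor site: `"ORAL_CAVITY"`, `"OROPHARYNX"` or
#'   `"HYPOPHARYNX"`.
#' @param t_stage,n_stage TNM strings (`"T2"`..`"T4"`, `"N0"`..`"N3"`).
#' @return An object of class `mvseg_case`.
#' @export
multiseq_case <- function(case_id, t1, stir, t1gad = NULL, reference,
                          location = "OROPHARYNX", t_stage = "T2",
                          n_stage = "N0") {
  stopifnot(inherits(t1, "mvseg_volume"), inherits(stir, "mvseg_volume"),
            is_mask(reference))
  if (!identical(dim(t1$data), dim(reference$data)))
    stop("reference mask grid must match the T1 grid for case ", case_id)
  if (!is.null(t1gad)) stopifnot(inherits(t1gad, "mvseg_volume"))
  location <- match.arg(location, c("ORAL_CAVITY", "OROPHARYNX", "HYPOPHARYNX"))
  t_stage <- match.arg(t_stage, c("T2", "T3", "T4"))
  n_stage <- match.arg(n_stage, c("N0", "N1", "N2", "N3"))
  structure(list(case_id = as.character(case_id), t1 = t1, stir = stir,
                 t1gad = t1gad, reference = reference, location = location,
                 t_stage = t_stage, n_stage = n_stage),
            class = "mvseg_case")
}

#' Read a NIfTI volume
#'
#' @param path path to a 3D `.nii` or `.nii.gz` file.
#' @param sequence sequence label to attach.
#' @param mask if `TRUE`, return a [label_mask()].
#' @return An [volume()] (or [label_mask()]) with spacing and voxel-to-world
#'   affine taken from the header.
#' @export
read_volume <- function(path, sequence = "OTHER", mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI image, got ", length(d), "D: ", path)
  v2w <- unname(structure(RNifti::xform(img), class = NULL))
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = d)
  if (mask) {
    if (!all(arr %in% c(0, 1))) stop("mask file has non-binary values: ", path)
    label_mask(arr, spacing = sp, v2w = v2w)
  } else {
    volume(arr, spacing = sp, sequence = sequence, v2w = v2w)
  }
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as unsigned 8-bit integers so the round trip is exact;
#' intensity volumes are written as 32-bit floats.
#'
#' @param v an [volume()] or [label_mask()].
#' @param path destination `.nii` or `.nii.gz` path; the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "mvseg_volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  dtype <- if (is_mask(v)) "uint8" else "float"
  # voxel sizes must be present at construction (they are immutable on the
  # resulting image); the qform then carries orientation and origin
  img <- RNifti::asNifti(structure(v$data, pixdim = v$spacing),
                         datatype = dtype)
  RNifti::qform(img) <- structure(v$v2w, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Zero-pad a volume on all sides
#'
#' Adds a border of `width` zero voxels along every axis (the network input
#' convention uses a border of 32 so patches never run off the grid).
#'
#' @param v an [volume()] or [label_mask()], or a bare 3D array.
#' @param width non-negative integer border width in voxels.
#' @return Same type as `v`, with shape `dim(v) + 2 * width`.
#' @export
zero_pad <- function(v, width) {
  if (length(width) != 1L || !is.finite(width) || width < 0 ||
      width != round(width))
    stop("width must be a single non-negative integer")
  width <- as.integer(width)
  pad_arr <- function(a) {
    out <- array(if (is.integer(a)) 0L else 0, dim = dim(a) + 2L * width)
    d <- dim(a)
    out[width + seq_len(d[1]), width + seq_len(d[2]), width + seq_len(d[3])] <- a
    out
  }
  if (is.array(v) && !inherits(v, "mvseg_volume")) return(pad_arr(v))
  out <- v
  out$data <- pad_arr(v$data)
  out
}

#' Crop the central block of a volume
#'
#' Inverse of [zero_pad()]: removes a border of `width` voxels from every side.
#'
#' @inheritParams zero_pad
#' @return Same type as `v`, with shape `dim(v) - 2 * width`.
#' @export
center_crop <- function(v, width) {
  if (length(width) != 1L || width < 0 || width != round(width))
    stop("width must be a single non-negative integer")
  width <- as.integer(width)
  crop_arr <- function(a) {
    d <- dim(a) - 2L * width
    if (any(d < 1L)) stop("crop width too large for volume")
    a[width + seq_len(d[1]), width + seq_len(d[2]), width + seq_len(d[3]),
      drop = FALSE]
  }
  if (is.array(v) && !inherits(v, "mvseg_volume")) return(crop_arr(v))
  out <- v
  out$data <- crop_arr(v$data)
  out
}
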