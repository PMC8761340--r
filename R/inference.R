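#' Segment a standard-space case
#'
#' Classifies every voxel inside the mask with the trained network in
#' inference mode (running batch-norm statistics, no dropout): a voxel is
#' labelled tumor iff its tumor-class probability exceeds 0.5 (strictly, so
#' an exactly ambivalent 0.5 maps to non-tumor). Voxels outside the mask are
#' 0. Voxels are processed in batches for throughput; the result is
#' batch-independent and deterministic.
#'
#' @param params trained `mvseg_params`.
#' @param prep a [prepare_case()] result (normalized, padded channels).
#' @param mask [label_mask()] of voxels to classify (the template occupancy
#'   mask in the pipeline), on the case's standard grid.
#' @param batch_size voxels per forward batch.
#' @return A [label_mask()] with attribute `prob` holding the in-mask
#'   tumor probabilities.
#' @export
segment_volume <- function(params, prep, mask, batch_size = 2048L) {
  stopifnot(inherits(params, "mvseg_params"), is_mask(mask))
  if (!identical(as.integer(prep$dim), as.integer(dim(mask$data))))
    stop("mask grid does not match the case grid")
  d <- dim(mask$data)
  out <- array(0L, d)
  idx <- which(mask$data == 1L)
  if (length(idx) > 0L) {
    lin0 <- idx - 1L
    vox <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2],
                 lin0 %/% (d[1] * d[2]))
    storage.mode(vox) <- "integer"
    p <- cpp_mvcnn_predict(prep$vols, vox, unclass_params(params),
                           attr(params, "config"), as.integer(batch_size))
    out[idx] <- as.integer(p > 0.5)
  } else {
    p <- numeric(0)
  }
  res <- label_mask(out, spacing = mask$spacing, v2w = mask$v2w)
  attr(res, "prob") <- p
  res
}

#' Volume of a binary mask in cubic centimeters
#'
#' Voxel count times voxel volume; on the 1-mm isotropic standard grid each
#' voxel is 1 mm^3, so 1000 voxels are 1 cm^3.
#'
#' @param m a [label_mask()].
#' @return Volume in cm^3.
#' @export
predicted_volume_cm3 <- function(m) {
  stopifnot(is_mask(m))
  if (!all(m$data %in% c(0L, 1L))) stop("mask must be binary")
  sum(m$data == 1L) * prod(m$spacing) / 1000
}
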