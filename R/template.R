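#' Build a template space by non-zero averaging
#'
#' Given a stack of T1 volumes already registered and resampled to a common
#' grid, computes per voxel the fraction of volumes with a non-zero value
#' (occupancy), keeps voxels whose occupancy reaches `threshold`, and sets the
#' template value to the mean over the non-zero contributors inside that
#' occupancy mask (0 elsewhere).
#'
#' @param t1_stack list of at least two [volume()] objects on identical grids.
#' @param threshold occupancy fraction in (0, 1]; default 0.30.
#' @param min_value intensity floor: a voxel counts as covered when its value
#'   exceeds this. The default 0 is the literal non-zero rule; pipeline
#'   callers raise it slightly so that sub-voxel interpolation tails around
#'   the field of view do not count as coverage.
#' @return An object of class `mvseg_template`: list with `template`
#'   ([volume()]), `occupancy` ([label_mask()]), and `threshold`.
#' @export
build_template <- function(t1_stack, threshold = 0.30, min_value = 0) {
  if (!is.list(t1_stack) || length(t1_stack) < 2L)
    stop("template construction needs at least two volumes")
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  d <- dim(t1_stack[[1]]$data)
  for (v in t1_stack) {
    stopifnot(inherits(v, "mvseg_volume"))
    if (!identical(dim(v$data), d))
      stop("all stack volumes must share one grid")
  }
  nz_count <- array(0, dim = d)
  nz_sum <- array(0, dim = d)
  for (v in t1_stack) {
    nz <- v$data > min_value | (min_value == 0 & v$data != 0)
    nz_count <- nz_count + nz
    nz_sum <- nz_sum + v$data * nz
  }
  occ <- nz_count / length(t1_stack)
  mask <- (occ >= threshold) * 1L
  tmpl <- array(0, dim = d)
  inside <- mask == 1L & nz_count > 0
  tmpl[inside] <- nz_sum[inside] / nz_count[inside]
  g <- t1_stack[[1]]
  structure(list(template = volume(tmpl, g$spacing, "T1", g$v2w),
                 occupancy = label_mask(mask, g$spacing, v2w = g$v2w),
                 threshold = threshold),
            class = "mvseg_template")
}

#' @export
print.mvseg_template <- function(x, ...) {
  cat(sprintf("<mvseg_template> dim %s, occupancy threshold %.2f, %d voxels in mask\n",
              paste(dim(x$template$data), collapse = "x"), x$threshold,
              sum(x$occupancy$data)))
  invisible(x)
}

#' Build a template space from native-space cases
#'
#' Picks a reference case (by index), registers every other T1 to it with a
#' full affine transform, resamples the stack onto the reference grid (cubic
#' interpolation), and applies [build_template()]. Reference selection by
#' visual quality control is replaced by an explicit index.
#'
#' @param cases list of [multiseq_case()] objects.
#' @param ref_index 1-based index of the reference case; default 1.
#' @param threshold occupancy fraction; default 0.30.
#' @param ... passed to [register_affine()].
#' @return An `mvseg_template`.
#' @export
build_template_from_cases <- function(cases, ref_index = 1L, threshold = 0.30,
                                      ...) {
  stopifnot(length(cases) >= 2L, ref_index >= 1L, ref_index <= length(cases))
  ref <- cases[[ref_index]]$t1
  g <- vol_grid(ref)
  stack <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    if (i == ref_index) {
      stack[[i]] <- ref
    } else {
      t <- register_affine(cases[[i]]$t1, ref, dof = "AFFINE", ...)
      stack[[i]] <- resample(cases[[i]]$t1, t, g, "SPLINE")
    }
  }
  # interpolation spreads a thin tail of small values past the field of
  # view; a floor at 2% of the typical foreground intensity keeps such
  # tails from counting as subject coverage
  pos <- ref$data[ref$data > 0]
  floor_val <- if (length(pos)) 0.02 * stats::median(pos) else 0
  build_template(stack, threshold, min_value = floor_val)
}
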