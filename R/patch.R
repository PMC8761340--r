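#' Sample training voxels with class rebalancing
#'
#' Draws a fixed-size sample without replacement: `round(tumor_frac * N_tumor)`
#' voxels from the reference tumor mask and `round(healthy_frac * N_healthy)`
#' from the healthy stratum (body mask minus tumor). Defaults follow the
#' 50% tumor / 1% healthy rebalancing; voxels outside the body mask are never
#' sampled. Deterministic under a fixed seed.
#'
#' @param reference tumor [label_mask()].
#' @param body_mask [label_mask()] of voxels counting as tissue (the template
#'   occupancy mask in the pipeline); must contain every tumor voxel.
#' @param tumor_frac,healthy_frac sampling fractions in (0, 1].
#' @param seed integer seed.
#' @param case_id identifier attached to the samples.
#' @return data.frame with columns `case_id`, `i`, `j`, `k` (0-based voxel
#'   indices), `label` (1 tumor, 0 healthy).
#' @export
sample_voxels <- function(reference, body_mask, tumor_frac = 0.5,
                          healthy_frac = 0.01, seed = 1L, case_id = "case") {
  stopifnot(is_mask(reference), is_mask(body_mask))
  if (!identical(dim(reference$data), dim(body_mask$data)))
    stop("reference and body mask must share a grid")
  if (!(tumor_frac > 0 && tumor_frac <= 1 && healthy_frac > 0 &&
        healthy_frac <= 1))
    stop("sampling fractions must lie in (0, 1]")
  tum <- which(reference$data == 1L)
  if (length(tum) == 0L) stop("empty tumor mask for case ", case_id)
  if (any(body_mask$data[tum] == 0L))
    stop("body mask must contain all tumor voxels (case ", case_id, ")")
  hea <- which(body_mask$data == 1L & reference$data == 0L)
  n_t <- round(tumor_frac * length(tum))
  n_h <- round(healthy_frac * length(hea))
  if (n_h == 0L) stop("healthy sample count is zero for case ", case_id)
  set.seed(seed)
  picks <- list(t = sort(sample(tum, n_t)), h = sort(sample(hea, n_h)))
  d <- dim(reference$data)
  to_ijk <- function(lin) {
    lin0 <- lin - 1L
    cbind(i = lin0 %% d[1], j = (lin0 %/% d[1]) %% d[2],
          k = lin0 %/% (d[1] * d[2]))
  }
  out <- rbind(data.frame(to_ijk(picks$t), label = 1L),
               data.frame(to_ijk(picks$h), label = 0L))
  data.frame(case_id = case_id, out, stringsAsFactors = FALSE)
}

#' Variance-normalize the channels of a case
#'
#' Per sequence and per case, computes mean and standard deviation over the
#' body-mask voxels, maps intensities to z-scores and clips them to
#' \[-4, 4\] (intensities within four standard deviations from the mean).
#' A constant image maps to all zeros; an absent sequence is represented by a
#' `NULL`, which downstream becomes an all-zero channel.
#'
#' @param case an [multiseq_case()] in standard space.
#' @param body_mask [label_mask()] over which the statistics are computed.
#' @return The case with normalized `t1`, `stir`, and (if present) `t1gad`.
#' @export
normalize_channels <- function(case, body_mask) {
  stopifnot(inherits(case, "mvseg_case"), is_mask(body_mask))
  norm1 <- function(v) {
    if (is.null(v)) return(NULL)
    if (!identical(dim(v$data), dim(body_mask$data)))
      stop("volume and body mask must share a grid")
    idx <- body_mask$data == 1L
    mu <- mean(v$data[idx])
    sig <- sd(v$data[idx])
    out <- v
    if (!is.finite(sig) || sig == 0) {
      out$data <- array(0, dim(v$data))
    } else {
      out$data <- array(pmin(4, pmax(-4, (v$data - mu) / sig)), dim(v$data))
    }
    out
  }
  case$t1 <- norm1(case$t1)
  case$stir <- norm1(case$stir)
  case$t1gad <- norm1(case$t1gad)
  case
}

# Assemble the padded channel arrays (T1, T1gad, STIR) the compiled engine
# consumes. Channels are zero-padded with the 32-voxel border; an absent
# contrast channel becomes all zeros.
prepare_case_channels <- function(case) {
  d <- dim(case$t1$data)
  gad <- if (is.null(case$t1gad)) array(0, d) else case$t1gad$data
  list(zero_pad(case$t1$data, 32L), zero_pad(gad, 32L),
       zero_pad(case$stir$data, 32L))
}

#' Prepare a standard-space case for the network
#'
#' Normalizes channels over the body mask and builds the padded channel
#' arrays used for patch extraction, training, and inference.
#'
#' @inheritParams normalize_channels
#' @return List with `case_id`, `vols` (list of 3 padded arrays in channel
#'   order T1, T1gad, STIR), `dim` (unpadded grid), `reference` and metadata.
#' @export
prepare_case <- function(case, body_mask) {
  nc <- normalize_channels(case, body_mask)
  list(case_id = case$case_id, vols = prepare_case_channels(nc),
       dim = dim(case$t1$data), reference = case$reference,
       location = case$location, t_stage = case$t_stage,
       n_stage = case$n_stage, has_t1gad = !is.null(case$t1gad))
}

#' Extract the tri-planar pyramid patch set around a voxel
#'
#' Returns the six 32x32x3 network inputs centered on one voxel: axial,
#' coronal and sagittal in-plane windows at two scales. Scale 0 is the
#' 32x32 window with the center voxel at in-window position (16, 16)
#' (0-based; the window spans center-16 .. center+15); scale 1 is the 64x64
#' window around the same voxel, 2x2 mean-pooled down to 32x32. Channels are
#' the three sequences (T1, T1gad, STIR).
#'
#' @param prep a [prepare_case()] result (padded, normalized channels), or a
#'   list of three padded 3D arrays.
#' @param index length-3 0-based voxel index in the unpadded grid.
#' @return An object of class `mvseg_patchset`: list with `scale0` and
#'   `scale1`, each holding `axial`, `coronal`, `sagittal` 32x32x3 arrays.
#' @export
extract_patchset <- function(prep, index) {
  vols <- if (!is.null(prep$vols)) prep$vols else prep
  d <- if (!is.null(prep$dim)) prep$dim else dim(vols[[1]]) - 64L
  index <- as.integer(index)
  if (length(index) != 3L || any(index < 0L) || any(index >= d))
    stop("index must be a 0-based voxel inside the unpadded grid")
  p <- cpp_extract_patchset(vols, index[1], index[2], index[3])
  structure(list(
    scale0 = list(axial = p[[1]], coronal = p[[3]], sagittal = p[[5]]),
    scale1 = list(axial = p[[2]], coronal = p[[4]], sagittal = p[[6]])),
    class = "mvseg_patchset")
}

# Branch-ordered 3072 x n matrices from a list of patch sets (engine layout).
patchsets_to_blocks <- function(patchsets) {
  n <- length(patchsets)
  views <- c("axial", "coronal", "sagittal")
  X <- vector("list", 6L)
  for (v in 1:3) for (s in 0:1) {
    b <- (v - 1L) * 2L + s + 1L
    m <- matrix(0, 3072L, n)
    for (it in seq_len(n)) {
      ps <- patchsets[[it]]
      arr <- if (s == 0) ps$scale0[[views[v]]] else ps$scale1[[views[v]]]
      m[, it] <- as.numeric(arr)
    }
    X[[b]] <- m
  }
  X
}

#' Downsample a 64x64 patch by 2x2 mean pooling
#'
#' The scale-1 context window is reduced to the 32x32 network input size by
#' averaging disjoint 2x2 blocks per channel, which preserves the patch mean
#' exactly.
#'
#' @param patch array of shape (2m, 2n) or (2m, 2n, C) with even spatial
#'   dimensions.
#' @return Array of shape (m, n) or (m, n, C).
#' @export
downsample_scale1 <- function(patch) {
  d <- dim(patch)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("patch must be a 2D or 3D array")
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("spatial dimensions must be even for 2x2 pooling")
  if (length(d) == 2L) dim(patch) <- c(d, 1L)
  d3 <- dim(patch)
  out <- (patch[seq(1, d3[1], 2), seq(1, d3[2], 2), , drop = FALSE] +
          patch[seq(2, d3[1], 2), seq(1, d3[2], 2), , drop = FALSE] +
          patch[seq(1, d3[1], 2), seq(2, d3[2], 2), , drop = FALSE] +
          patch[seq(2, d3[1], 2), seq(2, d3[2], 2), , drop = FALSE]) / 4
  if (length(d) == 2L) dim(out) <- dim(out)[1:2]
  out
}

#' Serialize or read voxel sample lists
#'
#' @param samples data.frame from [sample_voxels()].
#' @param path CSV destination.
#' @return `path` (write) or the samples data.frame (read).
#' @export
write_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) read.csv(path, stringsAsFactors = FALSE)
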