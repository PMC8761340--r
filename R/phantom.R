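#' Phantom generator configuration
#'
#' Synthetic multi-sequence head-and-neck-like cases with known ground truth:
#' a smoothed ellipsoidal "neck" body with internal texture (zero outside, so
#' the non-zero-average template logic is exercised), a randomized smooth
#' blob tumor of controllable volume that is hyperintense on STIR and
#' enhancing on the contrast channel, a known rigid case pose relative to the
#' canonical (standard) orientation, known rigid inter-sequence
#' misalignments, additive noise, and an occasionally missing contrast
#' channel. Phantoms are deliberately simple: the point is mechanism
#' recovery with known truth, not anatomical realism.
#'
#' @param grid grid shape in voxels (default 64x64x64 at 1 mm; the full
#'   224x192x117 standard grid is a configuration choice).
#' @param spacing voxel spacing in mm.
#' @param target_volume_cm3 tumor volume target; the generated mask voxel
#'   count lands within 5% of it.
#' @param location tumor site label.
#' @param texture_scale amplitude of the smooth internal body texture
#'   (intensity units on a body baseline of 100).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param misalign_mm,misalign_deg per-axis magnitude of the rigid
#'   inter-sequence misalignment (STIR and contrast T1 relative to T1).
#' @param pose_mm,pose_deg per-axis magnitude of the rigid case pose
#'   (native relative to canonical standard orientation).
#' @param t1gad_missing_prob probability that the contrast channel is absent
#'   (3% mirrors its availability in a clinical cohort).
#' @param seed integer seed; generation is bitwise reproducible.
#' @return An object of class `mvseg_phantom_config`.
#' @export
phantom_config <- function(grid = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                           target_volume_cm3 = 2.8, location = "OROPHARYNX",
                           texture_scale = 20, noise_sd = 4,
                           misalign_mm = 3, misalign_deg = 3,
                           pose_mm = 4, pose_deg = 4,
                           t1gad_missing_prob = 0.03, seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 48L), noise_sd >= 0,
            target_volume_cm3 > 0, t1gad_missing_prob >= 0,
            t1gad_missing_prob <= 1)
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 target_volume_cm3 = target_volume_cm3, location = location,
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 misalign_mm = misalign_mm, misalign_deg = misalign_deg,
                 pose_mm = pose_mm, pose_deg = pose_deg,
                 t1gad_missing_prob = t1gad_missing_prob,
                 seed = as.integer(seed)),
            class = "mvseg_phantom_config")
}

# Smooth random field on a grid: low-resolution Gaussian noise upsampled with
# cubic interpolation. Consumes the current RNG stream.
smooth_field <- function(dim, nctrl = 7L) {
  ctrl <- array(rnorm(nctrl^3), rep(nctrl, 3L))
  M <- diag(c((nctrl - 1) / (dim - 1), 1))
  cpp_resample(ctrl, rep(nctrl, 3L), as.integer(dim), M, 3L)
}

random_rigid <- function(mag_mm, mag_deg, center) {
  p <- c(runif(3, -mag_mm, mag_mm), runif(3, -mag_deg, mag_deg))
  params_to_affine(p, center)
}

#' Generate one phantom case
#'
#' Builds the canonical-pose body and tumor, derives the three sequences
#' (T1: texture only; STIR: tumor strongly hyperintense; contrast T1: tumor
#' enhancing), then resamples each sequence onto its native grid through the
#' known case pose and per-sequence misalignment, adds noise inside the body,
#' and transports the reference mask with nearest-neighbour interpolation.
#'
#' @param cfg an [phantom_config()].
#' @return List with `case` (native-space [multiseq_case()]), `std_mask`
#'   (ground-truth canonical/standard-space [label_mask()]), `truth`
#'   ([case_transforms()] with the true matrices), and `canonical` (the
#'   canonical-pose noise-free sequence volumes).
#' @export
generate_case <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "mvseg_phantom_config"))
  set.seed(cfg$seed)
  d <- cfg$grid
  g <- list(dim = d, spacing = cfg$spacing, v2w = diag(c(cfg$spacing, 1)))
  c0 <- (d - 1) / 2
  # clearly distinct semi-axes: a near-spherical body would leave rotation
  # ill-determined for registration, which real necks never do
  ra <- c(0.41, 0.33, 0.45) * d

  ii <- (seq_len(d[1]) - 1 - c0[1]) / ra[1]
  jj <- (seq_len(d[2]) - 1 - c0[2]) / ra[2]
  kk <- (seq_len(d[3]) - 1 - c0[3]) / ra[3]
  r2 <- outer(outer(ii^2, jj^2, "+"), kk^2, "+")
  body <- r2 <= 1

  # two-scale internal texture: coarse "organs" plus finer structure that
  # anchors rotation during registration
  tex <- 100 + cfg$texture_scale * (0.75 * smooth_field(d, 7L) +
                                      0.5 * smooth_field(d, 12L))

  vox_per_cm3 <- 1000 / prod(cfg$spacing)
  n_target <- cfg$target_volume_cm3 * vox_per_cm3
  r0 <- (3 * n_target * prod(cfg$spacing) / (4 * pi))^(1 / 3)

  # place the tumor center within the slack the body leaves at this size
  umax <- 1 - 1.35 * r0 / min(ra)
  if (umax < 0) stop("tumor cannot fit in body at target volume ",
                     cfg$target_volume_cm3, " cm^3")
  ct <- c0 + runif(3, -1, 1) * ra * umax / sqrt(3)

  # radial perturbation clamped so the blob stays within 1.35x its nominal
  # radius (the placement margin)
  pert <- pmax(-1.5, pmin(1.5, smooth_field(d, 6L)))
  di <- (seq_len(d[1]) - 1 - ct[1]) * cfg$spacing[1]
  dj <- (seq_len(d[2]) - 1 - ct[2]) * cfg$spacing[2]
  dk <- (seq_len(d[3]) - 1 - ct[3]) * cfg$spacing[3]
  dist <- sqrt(outer(outer(di^2, dj^2, "+"), dk^2, "+")) * (1 + 0.15 * pert)
  lo <- 0.4 * r0; hi <- 2.5 * r0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    cnt <- sum(dist <= mid)
    if (cnt < n_target) lo <- mid else hi <- mid
  }
  tum <- dist <= hi
  if (abs(sum(tum) - n_target) / n_target > 0.05)
    stop("could not match target tumor volume within 5%")
  if (any(tum & !body)) stop("tumor cannot fit in body (extends outside)")

  mk_seq <- function(gain, contrast, sequence) {
    arr <- gain * tex * body + contrast * tum
    volume(arr, cfg$spacing, sequence, g$v2w)
  }
  canon <- list(t1 = mk_seq(1, 0, "T1"), stir = mk_seq(0.85, 80, "STIR"),
                t1gad = mk_seq(0.9, 60, "T1GAD"))
  std_mask <- label_mask(tum * 1L, cfg$spacing, v2w = g$v2w)

  center_w <- as.numeric(g$v2w %*% c(c0, 1))[1:3]
  pose <- random_rigid(cfg$pose_mm, cfg$pose_deg, center_w)
  s_stir <- random_rigid(cfg$misalign_mm, cfg$misalign_deg, center_w)
  s_gad <- random_rigid(cfg$misalign_mm, cfg$misalign_deg, center_w)
  has_gad <- runif(1) >= cfg$t1gad_missing_prob

  # native grids are enlarged so the moved body never leaves the field of
  # view, as a scanner operator would ensure; with zero configured motion
  # the native grid equals the canonical grid
  motion <- cfg$pose_mm + cfg$misalign_mm +
    max(ra) * max(cfg$spacing) * (cfg$pose_deg + cfg$misalign_deg) * pi / 180
  pad_n <- if (motion == 0) 0L else as.integer(ceiling(motion) + 2L)
  v2w_n <- g$v2w
  v2w_n[1:3, 4] <- v2w_n[1:3, 4] - as.numeric(g$v2w[1:3, 1:3] %*%
                                                rep(pad_n, 3))
  g_n <- list(dim = d + 2L * pad_n, spacing = cfg$spacing, v2w = v2w_n)

  to_native <- function(v, total) {
    out <- resample(v, invert(total), g_n, "LINEAR")
    if (cfg$noise_sd > 0) {
      nz <- out$data > 0
      out$data[nz] <- out$data[nz] + rnorm(sum(nz), sd = cfg$noise_sd)
    }
    out
  }
  t1_n <- to_native(canon$t1, pose)
  stir_n <- to_native(canon$stir, compose(pose, s_stir))
  gad_n <- if (has_gad) to_native(canon$t1gad, compose(pose, s_gad)) else NULL
  ref_n <- resample(std_mask, invert(pose), g_n, "NEAREST")

  vgrp <- volume_group(cfg$target_volume_cm3)
  t_stage <- c(V1 = "T2", V2 = "T2", V3 = "T3", V4 = "T4")[[vgrp]]
  n_stage <- sample(c("N0", "N1", "N2"), 1, prob = c(0.35, 0.19, 0.46))

  case <- multiseq_case(paste0("phantom", cfg$seed), t1 = t1_n, stir = stir_n,
                        t1gad = gad_n, reference = ref_n,
                        location = cfg$location, t_stage = t_stage,
                        n_stage = n_stage)
  list(case = case, std_mask = std_mask,
       truth = case_transforms(pose, s_stir, if (has_gad) s_gad else NULL),
       canonical = canon)
}

#' Generate a phantom cohort
#'
#' Draws cases with stratified tumor-volume targets over four size groups
#' mirroring the V1-V4 strata, site labels with clinically plausible
#' frequencies, and the configured probability of a missing contrast
#' channel. Deterministic under the seed.
#'
#' The default group volumes (0.5, 1.2, 2.8, 4.5 cm^3 with 10% jitter) are
#' the clinical V-group volumes scaled to the phantom neck: a 64^3 phantom
#' mask holds roughly 85 cm^3 against roughly 2000 cm^3 for a clinical
#' head-and-neck mask, and these targets restore the ~2% tumor prevalence
#' the class-rebalanced sampling scheme (50% tumor / 1% healthy) was
#' designed around, giving training mixes near 50/50. Group labels in the
#' manifest refer to these scaled strata.
#'
#' @param n number of cases.
#' @param seed integer seed.
#' @param groups volume groups to cycle over (`rep`-ed to length `n`).
#' @param group_volumes named representative volumes per group (cm^3).
#' @param cfg base [phantom_config()]; per-case seed, volume and location are
#'   derived from it.
#' @return List with `cases` (list of [generate_case()] outputs) and
#'   `manifest` (data.frame: case_id, location, volume group, target volume,
#'   contrast availability, seed).
#' @export
generate_cohort <- function(n, seed = 1L, groups = c("V1", "V2", "V3", "V4"),
                            group_volumes = c(V1 = 0.5, V2 = 1.2, V3 = 2.8,
                                              V4 = 4.5),
                            cfg = phantom_config()) {
  stopifnot(n >= 1L)
  rep_vol <- group_volumes
  grp <- rep(groups, length.out = n)
  set.seed(seed)
  vols <- rep_vol[grp] * runif(n, 0.9, 1.1)
  locs <- sample(c("ORAL_CAVITY", "OROPHARYNX", "HYPOPHARYNX"), n,
                 replace = TRUE, prob = c(0.24, 0.69, 0.07))
  seeds <- seed + 7919L * seq_len(n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$target_volume_cm3 <- vols[i]
    ci$location <- locs[i]
    ci$seed <- seeds[i]
    cases[[i]] <- generate_case(ci)
    cases[[i]]$case$case_id <- sprintf("phantom%03d", i)
    # T stage tracks the (scaled) size stratum, as size drives T in practice
    cases[[i]]$case$t_stage <-
      c(V1 = "T2", V2 = "T2", V3 = "T3", V4 = "T4")[[grp[i]]]
  }
  manifest <- data.frame(
    case_id = vapply(cases, function(x) x$case$case_id, character(1)),
    location = locs,
    volume_group = grp,
    target_volume_cm3 = unname(vols),
    t1gad = vapply(cases, function(x) !is.null(x$case$t1gad), logical(1)),
    seed = seeds, stringsAsFactors = FALSE)
  list(cases = cases, manifest = manifest)
}

#' Number of 6-connected components of a mask
#'
#' @param m a [label_mask()] or binary array.
#' @return Integer component count.
#' @export
n_components <- function(m) {
  a <- if (is_mask(m)) m$data else as.array(m)
  storage.mode(a) <- "integer"
  cpp_n_components6(a, dim(a))
}
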