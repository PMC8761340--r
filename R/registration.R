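#' Grid of a volume
#'
#' @param v an [volume()], [label_mask()], or template space.
#' @return List with `dim`, `spacing`, `v2w` describing the sampling grid.
#' @export
vol_grid <- function(v) {
  if (inherits(v, "mvseg_template")) v <- v$template
  if (inherits(v, "mvseg_volume"))
    return(list(dim = dim(v$data), spacing = v$spacing, v2w = v$v2w))
  stopifnot(is.list(v), !is.null(v$dim), !is.null(v$v2w))
  if (is.null(v$spacing)) v$spacing <- sqrt(colSums(v$v2w[1:3, 1:3]^2))
  v
}

interp_code <- function(interp) {
  switch(match.arg(interp, c("SPLINE", "LINEAR", "NEAREST")),
         NEAREST = 0L, LINEAR = 1L, SPLINE = 3L)
}

#' Resample a volume through an affine transform
#'
#' Samples `v` on the `target` grid through the world-coordinate transform `t`
#' (moving to fixed): the output voxel at fixed-world position `x` takes the
#' value of `v` at moving-world position `solve(t) %*% x`. Out-of-field voxels
#' are 0. `"SPLINE"` is cubic (Keys) interpolation for intensity images;
#' label masks must use `"NEAREST"`, which keeps values binary.
#'
#' @param v an [volume()] or [label_mask()].
#' @param t an [affine_transform()] mapping `v`'s world to target world.
#' @param target a volume, template space, or grid list ([vol_grid()]).
#' @param interp `"SPLINE"`, `"LINEAR"`, or `"NEAREST"`.
#' @return A volume (or mask) on the target grid.
#' @export
resample <- function(v, t, target, interp = c("SPLINE", "LINEAR", "NEAREST")) {
  interp <- match.arg(interp)
  g <- vol_grid(target)
  t <- as_affine(t)
  if (is_mask(v) && interp != "NEAREST")
    stop("label masks must be resampled with NEAREST interpolation")
  M <- solve(v$v2w) %*% solve(t$matrix) %*% g$v2w
  arr <- cpp_resample(as.numeric(v$data), dim(v$data), as.integer(g$dim),
                      M, interp_code(interp))
  if (is_mask(v)) label_mask(arr, spacing = g$spacing, v2w = g$v2w)
  else volume(arr, spacing = g$spacing, sequence = v$sequence, v2w = g$v2w)
}

# Block-mean pyramid level of a volume (integer factor); the new voxel-to-world
# affine maps each coarse voxel to the center of its source block.
pyramid_level <- function(v, f) {
  if (f == 1L) return(v)
  arr <- cpp_block_mean(as.numeric(v$data), dim(v$data), as.integer(f))
  shift <- diag(c(f, f, f, 1))
  shift[1:3, 4] <- (f - 1) / 2
  volume(arr, spacing = v$spacing * f, sequence = v$sequence,
         v2w = v$v2w %*% shift)
}

#' Intensity-based affine or rigid registration
#'
#' Estimates the world-coordinate transform mapping `moving` to `fixed` by
#' minimizing one minus the correlation ratio of the resampled moving
#' intensities given binned fixed intensities, with Nelder-Mead over a
#' 3-level block-mean multi-resolution pyramid. When a weight mask is given,
#' zero-weight fixed voxels contribute nothing to the metric; otherwise the
#' metric support is the non-zero fixed voxels.
#'
#' @param moving,fixed non-constant [volume()] objects.
#' @param init optional initial [affine_transform()].
#' @param weight_mask optional [label_mask()] on the fixed grid.
#' @param dof `"RIGID"` (6 dof) or `"AFFINE"` (12 dof).
#' @param levels integer pyramid factors, coarse to fine.
#' @param nbins number of fixed-intensity bins for the correlation ratio.
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @param max_support cap on metric support voxels per level (deterministic
#'   thinning above it).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param rot_search per-axis rotation angles (degrees) scanned at the
#'   coarsest level to pick the starting basin when no initial transform is
#'   given.
#' @return An [affine_transform()] with attributes `cost` (final metric) and
#'   `trace` (per-level costs).
#' @export
register_affine <- function(moving, fixed, init = NULL, weight_mask = NULL,
                            dof = c("AFFINE", "RIGID"), levels = c(4L, 2L, 1L),
                            nbins = 24L, maxit = c(3000L, 1500L, 1500L),
                            max_support = 30000L, reltol = 1e-5,
                            rot_search = seq(-10, 10, by = 5)) {
  dof <- match.arg(dof)
  stopifnot(inherits(moving, "mvseg_volume"), inherits(fixed, "mvseg_volume"))
  if (sd(moving$data) == 0 || sd(fixed$data) == 0)
    stop("registration requires non-constant images")
  np <- if (dof == "RIGID") 6L else 12L
  com_world <- function(v) {
    w <- pmax(v$data, 0)
    tot <- sum(w)
    d <- dim(w)
    ii <- sum(w * ((seq_len(d[1]) - 1))[slice.index(w, 1)]) / tot
    jj <- sum(w * ((seq_len(d[2]) - 1))[slice.index(w, 2)]) / tot
    kk <- sum(w * ((seq_len(d[3]) - 1))[slice.index(w, 3)]) / tot
    as.numeric(v$v2w %*% c(ii, jj, kk, 1))[1:3]
  }
  # a pyramid level below ~16 voxels a side has too little support for a
  # reliable metric; drop such levels (the finest always stays)
  ok_lvl <- levels == 1L | floor(min(dim(fixed$data)) / levels) >= 16L
  if (!any(ok_lvl)) {
    # requested levels are all too coarse for this grid: use the coarsest
    # power-of-two factor that still leaves >= 16 voxels a side
    levels <- max(1L, 2L^max(0L, floor(log2(min(dim(fixed$data)) / 16))))
  } else {
    levels <- levels[ok_lvl]
  }
  maxit <- rep_len(maxit, length(levels))
  no_init <- is.null(init)
  if (no_init) {
    # center-of-mass alignment: a robust deterministic translation start
    A <- diag(4)
    A[1:3, 4] <- com_world(fixed) - com_world(moving)
  } else {
    A <- as_affine(init)$matrix
  }

  ctr_vox <- (vol_grid(fixed)$dim - 1) / 2
  center <- as.numeric((fixed$v2w %*% c(ctr_vox, 1))[1:3])
  parscale <- c(rep(1, 6), rep(0.02, 6))[seq_len(np)]
  trace <- numeric(0)
  conv <- 0L

  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    w <- if (is.null(weight_mask)) NULL else pyramid_level(
      volume(weight_mask$data + 0, weight_mask$spacing,
             v2w = weight_mask$v2w), f)
    fdat <- fx$data
    if (is.null(w)) {
      sup <- which(fdat != 0)
      wts <- rep(1, length(sup))
    } else {
      sup <- which(w$data > 0)
      wts <- w$data[sup]
    }
    if (length(sup) < 50)
      stop("registration support nearly empty at pyramid level ", f)
    if (length(sup) > max_support) {
      keep <- unique(as.integer(round(seq(1, length(sup),
                                          length.out = max_support))))
      sup <- sup[keep]; wts <- wts[keep]
    }
    dms <- dim(fdat)
    sup0 <- sup - 1L
    vox <- cbind(sup0 %% dms[1],
                 (sup0 %/% dms[1]) %% dms[2],
                 sup0 %/% (dms[1] * dms[2]))
    fv <- fdat[sup]
    rng <- range(fv)
    if (diff(rng) <= 0) stop("fixed image constant over the metric support")
    # keep at least ~50 support voxels per intensity bin so the per-bin
    # variances that make up the correlation ratio are stable
    nbins_l <- max(6L, min(nbins, length(sup) %/% 50L))
    bin <- pmin(nbins_l - 1L, pmax(0L, as.integer(floor(
      (fv - rng[1]) / diff(rng) * nbins_l))))

    w2v_mov <- solve(mv$v2w)
    v2w_fix <- fx$v2w
    mdat <- as.numeric(mv$data)
    mdim <- dim(mv$data)
    cost_fn <- function(p) {
      At <- params_to_affine(p, center)$matrix %*% A
      M <- w2v_mov %*% solve(At) %*% v2w_fix
      cpp_cr_cost(mdat, mdim, vox, bin, wts, nbins_l, M)
    }
    # Full dof is searched at the coarsest level only (seeded by a rigid
    # pre-solve when affine); finer levels refine the rigid parameters of
    # the increment, which dominate the residual once scale and shear are
    # locked in. Nelder-Mead re-converges far faster in 6 dimensions.
    np_l <- if (li == 1L) np else 6L
    pad <- function(p) if (np_l == np) p else c(p, rep(0, np - 6L))
    p0 <- rep(0, np_l)
    if (li == 1L && no_init) {
      # rotation basin search on top of the center-of-mass translation:
      # near-symmetric subjects give the local optimizer little rotational
      # signal, so the best starting basin is picked from a coarse grid
      best_rot <- c(0, 0, 0)
      best_val <- cost_fn(rep(0, np))
      for (rx in rot_search) for (ry in rot_search) for (rz in rot_search) {
        v <- cost_fn(c(0, 0, 0, rx, ry, rz, rep(0, np - 6L)))
        if (v < best_val) { best_val <- v; best_rot <- c(rx, ry, rz) }
      }
      p0[4:6] <- best_rot
    }
    if (li == 1L && np == 12L) {
      pre <- optim(p0[1:6], function(p) cost_fn(c(p, rep(0, 6))),
                   method = "Nelder-Mead",
                   control = list(maxit = maxit[li], reltol = reltol,
                                  parscale = parscale[1:6]))
      p0[1:6] <- pre$par
    }
    ctrl <- list(maxit = maxit[li], reltol = reltol,
                 parscale = parscale[seq_len(np_l)])
    res <- optim(p0, function(p) cost_fn(pad(p)), method = "Nelder-Mead",
                 control = ctrl)
    if (res$convergence != 0L) {
      # restart once from the returned point: a fresh simplex settles fast
      # when the previous run merely stalled at the metric noise floor
      res <- optim(res$par, function(p) cost_fn(pad(p)),
                   method = "Nelder-Mead", control = ctrl)
    }
    A <- params_to_affine(pad(res$par), center)$matrix %*% A
    trace <- c(trace, res$value)
    conv <- res$convergence
  }
  if (conv != 0L) {
    cond <- structure(class = c("mvseg_registration_error", "error",
                                "condition"),
                      list(message = "registration did not converge at the finest pyramid level",
                           call = sys.call(), transform = affine_transform(A),
                           trace = trace))
    stop(cond)
  }
  out <- affine_transform(A)
  attr(out, "cost") <- trace[length(trace)]
  attr(out, "trace") <- trace
  out
}

#' Two-step registration: affine, then rigid re-initialized
#'
#' Step 1 estimates a full affine transform; step 2 re-estimates a rigid
#' transform initialized with the rigid component of step 1, optionally
#' weighting the metric (used with the template occupancy mask to filter out
#' background). The returned transform is the rigid result of step 2.
#'
#' @inheritParams register_affine
#' @param weight_mask optional weight mask applied in step 2 only.
#' @param step1_levels pyramid factors for the affine first step. Only its
#'   rigid component seeds step 2, so by default it runs at the coarsest
#'   level only.
#' @return An [affine_transform()] (rigid) with attribute `step1` holding the
#'   first-step affine transform.
#' @export
register_two_step <- function(moving, fixed, weight_mask = NULL,
                              step1_levels = 4L, ...) {
  step1 <- register_affine(moving, fixed, dof = "AFFINE",
                           levels = step1_levels,
                           maxit = 3000L, ...)
  init <- rigid_component(step1)
  out <- register_affine(moving, fixed, init = init,
                         weight_mask = weight_mask, dof = "RIGID", ...)
  attr(out, "step1") <- step1
  out
}

#' Per-case transform bundle
#'
#' @param t1_to_std [affine_transform()] from native T1 world to standard
#'   space.
#' @param stir_to_t1 [affine_transform()] from STIR to native T1 world.
#' @param t1gad_to_t1 [affine_transform()] or `NULL` when the contrast scan is
#'   absent.
#' @return An object of class `mvseg_case_transforms`.
#' @export
case_transforms <- function(t1_to_std, stir_to_t1, t1gad_to_t1 = NULL) {
  t1_to_std <- as_affine(t1_to_std)
  stir_to_t1 <- as_affine(stir_to_t1)
  if (!is.null(t1gad_to_t1)) t1gad_to_t1 <- as_affine(t1gad_to_t1)
  structure(list(t1_to_std = t1_to_std, stir_to_t1 = stir_to_t1,
                 t1gad_to_t1 = t1gad_to_t1),
            class = "mvseg_case_transforms")
}

#' Move a case into standard space
#'
#' Registers the T1 to the template with the two-step scheme (step 2 weighted
#' by the occupancy mask), registers STIR and the optional contrast T1 to the
#' native T1 with the same two-step scheme, concatenates the matrices, and
#' resamples every sequence (cubic interpolation) and the reference mask
#' (nearest neighbour) onto the template grid. An absent contrast channel
#' stays absent.
#'
#' @param case an [multiseq_case()] in native space.
#' @param tpl an [build_template()] result.
#' @param ... passed to [register_affine()].
#' @return List with `case` (standard-space [multiseq_case()]) and
#'   `transforms` ([case_transforms()]).
#' @export
case_to_standard <- function(case, tpl, ...) {
  stopifnot(inherits(case, "mvseg_case"), inherits(tpl, "mvseg_template"))
  reg <- function(moving, fixed, wm, seq_name) {
    tryCatch(register_two_step(moving, fixed, weight_mask = wm, ...),
             error = function(e) stop("registration failed for case ",
                                      case$case_id, " sequence ", seq_name,
                                      ": ", conditionMessage(e)))
  }
  t1_to_std <- reg(case$t1, tpl$template, tpl$occupancy, "T1")
  stir_to_t1 <- reg(case$stir, case$t1, NULL, "STIR")
  t1gad_to_t1 <- if (is.null(case$t1gad)) NULL else
    reg(case$t1gad, case$t1, NULL, "T1GAD")
  g <- vol_grid(tpl)
  std <- multiseq_case(
    case_id = case$case_id,
    t1 = resample(case$t1, t1_to_std, g, "SPLINE"),
    stir = resample(case$stir, compose(t1_to_std, stir_to_t1), g, "SPLINE"),
    t1gad = if (is.null(case$t1gad)) NULL else
      resample(case$t1gad, compose(t1_to_std, t1gad_to_t1), g, "SPLINE"),
    reference = resample(case$reference, t1_to_std, g, "NEAREST"),
    location = case$location, t_stage = case$t_stage, n_stage = case$n_stage)
  list(case = std,
       transforms = case_transforms(t1_to_std, stir_to_t1, t1gad_to_t1))
}

#' Map a standard-space mask back to a native grid
#'
#' Applies the inverse of the case's T1-to-standard matrix with
#' nearest-neighbour interpolation, so automatic segmentations can be reported
#' on the original scan.
#'
#' @param m a [label_mask()] in standard space.
#' @param ct a [case_transforms()] bundle.
#' @param native_grid the native T1 volume or its [vol_grid()].
#' @return A [label_mask()] on the native grid.
#' @export
mask_to_native <- function(m, ct, native_grid) {
  stopifnot(is_mask(m), inherits(ct, "mvseg_case_transforms"))
  resample(m, invert(ct$t1_to_std), vol_grid(native_grid), "NEAREST")
}
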