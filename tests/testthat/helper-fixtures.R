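# Shared fixtures. Everything is generated in code; heavier objects are
# memoized per test run so several tests can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# Small phantom on a 48^3 grid with a V1-sized tumor: fast to generate,
# big enough for patch geometry and registration.
tiny_phantom <- function(seed = 5, volume = 2, pose_mm = 4, pose_deg = 4,
                         misalign_mm = 2, misalign_deg = 2, noise_sd = 4) {
  generate_case(phantom_config(
    grid = c(48L, 48L, 48L), target_volume_cm3 = volume,
    pose_mm = pose_mm, pose_deg = pose_deg,
    misalign_mm = misalign_mm, misalign_deg = misalign_deg,
    noise_sd = noise_sd, seed = seed))
}

tiny_phantom_memo <- function() memo("tiny_phantom", function() tiny_phantom())

# A canonical-pose prepared case (no registration needed): body mask from the
# noise-free canonical T1, channels normalized and padded.
prepared_canonical <- function(ph, case_id = "canon") {
  body <- label_mask((ph$canonical$t1$data > 0) * 1L,
                     spacing = ph$canonical$t1$spacing,
                     v2w = ph$canonical$t1$v2w)
  case <- multiseq_case(case_id, ph$canonical$t1, ph$canonical$stir,
                        ph$canonical$t1gad, ph$std_mask,
                        location = "OROPHARYNX", t_stage = "T2",
                        n_stage = "N0")
  list(prep = prepare_case(case, body), body = body, case = case)
}

# The output layer is zero-initialized by design, which makes an untrained
# model output exactly 0.5 everywhere; behavioural tests need a head that
# actually reacts to its input.
randomize_head <- function(params, seed = 99) {
  set.seed(seed)
  params$Wo <- matrix(rnorm(length(params$Wo), sd = 0.5),
                      nrow(params$Wo), ncol(params$Wo))
  params
}

small_model_config <- function() {
  model_config(conv_filters = 4L, dense_units_branch = 8L,
               dense_units_head = 16L)
}

# Random patch blocks in the engine layout (list of six 3072 x n matrices).
random_patch_blocks <- function(n, seed = 1) {
  set.seed(seed)
  lapply(1:6, function(b) matrix(rnorm(3072 * n), 3072L, n))
}

# Patch blocks carrying a label-separable signal: tumor patches have a mean
# shift in the STIR channel (rows 2049..3072), mimicking real contrast.
separable_patch_blocks <- function(n, labels, shift = 2, seed = 1) {
  set.seed(seed)
  lapply(1:6, function(b) {
    m <- matrix(rnorm(3072 * n), 3072L, n)
    m[2049:3072, labels == 1] <- m[2049:3072, labels == 1] + shift
    m
  })
}

engine_opt <- function(epochs, seed = 1, batch_size = 512L, lr0 = 1e-3) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr0 = lr0, lr_decay = 0.8, lr_decay_every = 5L, epoch_offset = 0L,
       adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
       dice_eps = 1e-7, seed = as.double(seed), shuffle = TRUE)
}

# Brute-force in-plane window extraction used as the oracle for patch tests:
# takes the padded array directly and cuts the window with plain indexing.
oracle_window <- function(padded, center, view, halfwidth) {
  ci <- center + 32L  # padded coordinates, 0-based
  idx <- function(c0) (c0 - halfwidth):(c0 + halfwidth - 1L) + 1L
  if (view == "axial")
    padded[idx(ci[1]), idx(ci[2]), ci[3] + 1L]
  else if (view == "coronal")
    padded[idx(ci[1]), ci[2] + 1L, idx(ci[3])]
  else
    padded[ci[1] + 1L, idx(ci[2]), idx(ci[3])]
}

expect_affine_close <- function(a, b, center = c(0, 0, 0), rot_tol = 0.5,
                                trans_tol = 0.5) {
  d <- transform_discrepancy(a, b, center)
  expect_lt(d$rot_deg, rot_tol)
  expect_lt(d$trans_mm, trans_tol)
}

grid_center_world <- function(v) {
  g <- vol_grid(v)
  as.numeric(g$v2w %*% c((g$dim - 1) / 2, 1))[1:3]
}
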