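test_that("resampling identities and label preservation hold", {
  ph <- tiny_phantom_memo()
  v <- ph$canonical$t1
  # identity transform on the same grid returns the input
  same <- resample(v, identity_transform(), vol_grid(v), "LINEAR")
  expect_equal(same$data, v$data, tolerance = 1e-12)
  same_c <- resample(v, identity_transform(), vol_grid(v), "SPLINE")
  expect_equal(same_c$data, v$data, tolerance = 1e-8)

  # integer-voxel translation with nearest neighbour is an exact shift
  m <- ph$std_mask
  t <- params_to_affine(c(3, 0, 0, 0, 0, 0))
  shifted <- resample(m, t, vol_grid(m), "NEAREST")
  d <- dim(m$data)
  expect_identical(shifted$data[4:d[1], , ], m$data[1:(d[1] - 3), , ])
  expect_true(all(shifted$data %in% c(0L, 1L)))
  # masks refuse interpolating resampling
  expect_error(resample(m, t, vol_grid(m), "SPLINE"), "NEAREST")
})

test_that("self-registration stays at the identity", {
  ph <- tiny_phantom_memo()
  v <- ph$canonical$t1
  tr <- register_affine(v, v, dof = "RIGID")
  expect_affine_close(tr, identity_transform(), grid_center_world(v),
                      rot_tol = 0.1, trans_tol = 0.1)
})

test_that("known rigid perturbations are recovered by registration", {
  ph <- tiny_phantom(seed = 50, volume = 3, noise_sd = 3)
  fixed <- ph$canonical$t1
  ctr <- grid_center_world(fixed)
  # pure translation
  t_true <- params_to_affine(c(4, -3, 2, 0, 0, 0), ctr)
  moving <- resample(fixed, invert(t_true), vol_grid(fixed), "LINEAR")
  got <- register_affine(moving, fixed, dof = "RIGID")
  d <- transform_discrepancy(got, t_true, ctr)
  expect_lt(d$trans_mm, 0.5)
  # rotation about z plus translation
  r_true <- params_to_affine(c(2, 1, -1, 0, 0, 5), ctr)
  moving2 <- resample(fixed, invert(r_true), vol_grid(fixed), "LINEAR")
  got2 <- register_affine(moving2, fixed, dof = "RIGID")
  expect_affine_close(got2, r_true, ctr, rot_tol = 0.5, trans_tol = 0.5)
})

test_that("registration rejects constant images", {
  flat <- volume(array(1, c(48, 48, 48)))
  expect_error(register_affine(flat, flat), "non-constant")
})

test_that("two-step case registration recovers pose and transports masks", {
  # single-phantom mechanism check; the tight 0.5 mm / 0.5 deg recovery
  # surface is asserted over twenty phantoms in the acceptance suite
  ph <- tiny_phantom(seed = 60, volume = 3)
  ctr <- grid_center_world(ph$canonical$t1)
  tr <- register_two_step(ph$case$t1, ph$canonical$t1)
  expect_affine_close(tr, ph$truth$t1_to_std, ctr, rot_tol = 1, trans_tol = 1)
  expect_s3_class(attr(tr, "step1"), "mvseg_affine")

  # transported reference overlaps the canonical ground truth
  moved <- resample(ph$case$reference, tr, vol_grid(ph$canonical$t1),
                    "NEAREST")
  expect_gt(dsc(moved, ph$std_mask), 0.9)
})

test_that("case_to_standard handles an absent contrast channel", {
  cfg <- phantom_config(grid = c(48L, 48L, 48L), target_volume_cm3 = 2,
                        t1gad_missing_prob = 1, seed = 70)
  ph <- generate_case(cfg)
  ref_cfg <- phantom_config(grid = c(48L, 48L, 48L), target_volume_cm3 = 2,
                            pose_mm = 0, pose_deg = 0, misalign_mm = 0,
                            misalign_deg = 0, t1gad_missing_prob = 0,
                            seed = 71)
  ref <- generate_case(ref_cfg)
  tpl <- build_template_from_cases(list(ref$case, ph$case), ref_index = 1)
  res <- case_to_standard(ph$case, tpl)
  expect_null(res$transforms$t1gad_to_t1)
  expect_null(res$case$t1gad)
  expect_s3_class(res$transforms$t1_to_std, "mvseg_affine")
  expect_true(all(res$case$reference$data %in% c(0L, 1L)))
})

test_that("standard-native mask round trips preserve overlap", {
  ph <- tiny_phantom(seed = 80, volume = 3)
  # exact recovery for an integer-translation-only transform
  m <- ph$std_mask
  ct_int <- case_transforms(params_to_affine(c(5, -2, 7, 0, 0, 0)),
                            identity_transform())
  native <- mask_to_native(m, ct_int, vol_grid(m))
  back <- resample(native, ct_int$t1_to_std, vol_grid(m), "NEAREST")
  expect_identical(back$data, m$data)

  # general rigid round trip keeps DSC high
  ctr <- grid_center_world(m)
  ct_gen <- case_transforms(params_to_affine(c(3.3, -1.7, 2.9, 4, -3, 6), ctr),
                            identity_transform())
  native2 <- mask_to_native(m, ct_gen, vol_grid(m))
  back2 <- resample(native2, ct_gen$t1_to_std, vol_grid(m), "NEAREST")
  expect_gt(dsc(back2, m), 0.9)

  # empty masks stay empty
  em <- label_mask(array(0L, dim(m$data)))
  expect_equal(sum(mask_to_native(em, ct_gen, vol_grid(m))$data), 0)
})
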