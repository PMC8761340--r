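mk_masks <- function(d = c(20L, 20L, 20L), n_tumor = 100L, body_frac = 0.8) {
  set.seed(17)
  body <- array(0L, d)
  body[2:19, 2:19, 2:19] <- rbinom(18^3, 1, body_frac)
  tum <- array(0L, d)
  cand <- which(body == 1L)
  tum[sample(cand, n_tumor)] <- 1L
  body[tum == 1L] <- 1L
  list(reference = label_mask(tum), body = label_mask(body))
}

test_that("sampling counts follow round(frac * N) exactly and stay in strata", {
  m <- mk_masks()
  n_tumor <- sum(m$reference$data)
  n_healthy <- sum(m$body$data == 1L & m$reference$data == 0L)
  s <- sample_voxels(m$reference, m$body, 0.5, 0.01, seed = 3, case_id = "x")
  expect_equal(sum(s$label == 1), round(0.5 * n_tumor))
  expect_equal(sum(s$label == 0), round(0.01 * n_healthy))
  # every sample lies in its stratum
  lin <- s$i + dim(m$body$data)[1] * (s$j + dim(m$body$data)[2] * s$k) + 1L
  expect_true(all(m$reference$data[lin[s$label == 1]] == 1L))
  expect_true(all(m$reference$data[lin[s$label == 0]] == 0L))
  expect_true(all(m$body$data[lin] == 1L))
  # no duplicates (sampling without replacement)
  expect_false(any(duplicated(lin)))
})

test_that("sampling is deterministic under seed and exhaustive at frac 1", {
  m <- mk_masks()
  s1 <- sample_voxels(m$reference, m$body, seed = 9)
  s2 <- sample_voxels(m$reference, m$body, seed = 9)
  expect_identical(s1, s2)
  s3 <- sample_voxels(m$reference, m$body, seed = 10)
  expect_false(identical(s1$i, s3$i))

  all_s <- sample_voxels(m$reference, m$body, 1.0, 1.0, seed = 1)
  expect_equal(nrow(all_s), sum(m$body$data))
  lin <- all_s$i + 20L * (all_s$j + 20L * all_s$k) + 1L
  expect_false(any(duplicated(lin)))
})

test_that("sampling contract violations error", {
  m <- mk_masks()
  empty <- label_mask(array(0L, c(20, 20, 20)))
  expect_error(sample_voxels(empty, m$body), "empty tumor")
  expect_error(sample_voxels(m$reference, m$body, tumor_frac = 1.5),
               "fractions")
  # body mask must contain the tumor
  expect_error(sample_voxels(m$reference, empty), "contain")
})

test_that("channel normalization is a clipped z-score over the body mask", {
  d <- c(10L, 10L, 10L)
  body <- label_mask(array(1L, d))
  set.seed(5)
  base <- array(rnorm(1000, 100, 10), d)
  base[1, 1, 1] <- 200   # beyond four standard deviations
  case <- multiseq_case("n", volume(base, sequence = "T1"),
                        volume(base, sequence = "STIR"), NULL,
                        label_mask(array(rep(c(1, 0), c(10, 990)), d)))
  norm <- normalize_channels(case, body)
  mu <- mean(base); sig <- sd(base)
  expect_equal(norm$t1$data[2, 1, 1], max(-4, min(4, (base[2, 1, 1] - mu) / sig)))
  expect_equal(max(norm$t1$data), 4)  # clipped
  expect_true(all(norm$t1$data >= -4 & norm$t1$data <= 4))
  # in-mask mean ~ 0, sd ~ 1 before clipping dominates
  expect_lt(abs(mean(norm$stir$data)), 0.05)

  # constant image maps to zeros; absent contrast stays absent
  const_case <- case
  const_case$t1 <- volume(array(7, d), sequence = "T1")
  cn <- normalize_channels(const_case, body)
  expect_true(all(cn$t1$data == 0))
  expect_null(cn$t1gad)
})

test_that("patch extraction windows match a plain-indexing oracle", {
  ph <- tiny_phantom_memo()
  pc <- prepared_canonical(ph)
  prep <- pc$prep
  idx <- c(24L, 20L, 26L)
  ps <- extract_patchset(prep, idx)

  for (v in c("axial", "coronal", "sagittal")) {
    for (ch in 1:3) {
      got0 <- ps$scale0[[v]][, , ch]
      want0 <- oracle_window(prep$vols[[ch]], idx, v, 16L)
      expect_equal(got0, unname(want0))
      got1 <- ps$scale1[[v]][, , ch]
      want1 <- downsample_scale1(oracle_window(prep$vols[[ch]], idx, v, 32L))
      expect_equal(got1, unname(want1))
    }
  }
})

test_that("delta image puts its spike at in-window position (16,16)", {
  d <- c(48L, 48L, 48L)
  idx <- c(20L, 25L, 30L)
  delta <- array(0, d)
  delta[idx[1] + 1L, idx[2] + 1L, idx[3] + 1L] <- 1
  vols <- list(zero_pad(delta, 32L), zero_pad(delta, 32L), zero_pad(delta, 32L))
  ps <- extract_patchset(vols, idx)
  for (v in c("axial", "coronal", "sagittal")) {
    p <- ps$scale0[[v]][, , 1]
    expect_equal(p[17, 17], 1)       # 0-based (16,16)
    expect_equal(sum(p), 1)
  }
})

test_that("corner voxels still give full 32x32 patches with zero fill", {
  d <- c(48L, 48L, 48L)
  arr <- array(1, d)
  vols <- lapply(1:3, function(i) zero_pad(arr, 32L))
  ps <- extract_patchset(vols, c(0L, 0L, 0L))
  expect_identical(dim(ps$scale0$axial), c(32L, 32L, 3L))
  expect_identical(dim(ps$scale1$sagittal), c(32L, 32L, 3L))
  # window spans [-16, 15]: positions below 0 are zero fill
  expect_true(all(ps$scale0$axial[1:16, , ] == 0))
  expect_true(all(ps$scale0$axial[17:32, 17:32, ] == 1))
  expect_error(extract_patchset(vols, c(48L, 0L, 0L)), "inside")
})

test_that("constant volume yields constant scale-0 and scale-1 patches", {
  # the voxel must sit >= 32 from every face so even the 64-wide scale-1
  # window stays inside the constant region
  d <- c(72L, 72L, 72L)
  vols <- lapply(1:3, function(i) zero_pad(array(2, d), 32L))
  ps <- extract_patchset(list(vols = vols, dim = d), c(36L, 36L, 36L))
  expect_true(all(ps$scale0$coronal == 2))
  expect_true(all(ps$scale1$coronal == 2))
})

test_that("extraction is translation equivariant", {
  ph <- tiny_phantom_memo()
  prep <- prepared_canonical(ph)$prep
  idx <- c(22L, 23L, 24L)
  shift <- c(3L, -2L, 1L)
  shifted_vols <- lapply(prep$vols, function(a) {
    d <- dim(a)
    out <- array(0, d)
    src <- a[(1 + 32):(d[1] - 32), (1 + 32):(d[2] - 32), (1 + 32):(d[3] - 32)]
    ds <- dim(src)
    out[(1 + 32 + shift[1]):(ds[1] + 32 + shift[1]),
        (1 + 32 + shift[2]):(ds[2] + 32 + shift[2]),
        (1 + 32 + shift[3]):(ds[3] + 32 + shift[3])] <- src
    out
  })
  ps1 <- extract_patchset(prep, idx)
  ps2 <- extract_patchset(list(vols = shifted_vols, dim = prep$dim),
                          idx + shift)
  expect_equal(ps1, ps2)
})

test_that("downsample_scale1 performs exact 2x2 block averaging", {
  cb <- array(0, c(64, 64, 1))
  cb[, , 1] <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  expect_true(all(downsample_scale1(cb) == 0.5))
  expect_true(all(downsample_scale1(array(3, c(64, 64, 3))) == 3))

  set.seed(23)
  p <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  got <- downsample_scale1(p)
  expect_equal(mean(got), mean(p))   # mean preserved exactly
  # loop-based oracle
  for (rep in 1:20) {
    i <- sample(32, 1); j <- sample(32, 1); ch <- sample(3, 1)
    expect_equal(got[i, j, ch],
                 mean(p[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch]))
  }
  expect_error(downsample_scale1(array(0, c(63, 64, 3))), "even")
})
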