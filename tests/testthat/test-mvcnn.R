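patchsets_from_blocks <- function(X, item) {
  # engine-layout blocks -> a user-facing patch set for forward()
  arr <- function(b) array(X[[b]][, item], c(32, 32, 3))
  structure(list(
    scale0 = list(axial = arr(1), coronal = arr(3), sagittal = arr(5)),
    scale1 = list(axial = arr(2), coronal = arr(4), sagittal = arr(6))),
    class = "mvseg_patchset")
}

test_that("forward output is a probability simplex point", {
  params <- randomize_head(build_model(small_model_config(), seed = 2))
  X <- random_patch_blocks(8, seed = 3)
  ps <- lapply(1:8, function(i) patchsets_from_blocks(X, i))
  p <- forward(params, ps)
  expect_identical(dim(p), c(8L, 2L))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-6)
})

test_that("model building is deterministic under seed", {
  a <- build_model(model_config(), seed = 7)
  b <- build_model(model_config(), seed = 7)
  expect_identical(unclass_params <- mvseg:::unclass_params(a),
                   mvseg:::unclass_params(b))
  c2 <- build_model(model_config(), seed = 8)
  expect_false(identical(a$Wc1, c2$Wc1))
})

test_that("parameter count matches an independent shape-arithmetic oracle", {
  count_oracle <- function(F, D1, D2) {
    conv <- 3 * 3 * 3 * F          # 3x3 kernel, 3 channels, no bias (BN)
    bn <- 2 * F                    # gamma, beta
    dense_b <- (16 * 16 * F) * D1 + D1
    head <- (6 * D1) * D2 + D2 + D2 * 2 + 2
    6 * (conv + bn + dense_b) + head
  }
  for (cfgv in list(c(32L, 64L, 128L), c(4L, 8L, 16L), c(7L, 5L, 3L))) {
    cfg <- model_config(cfgv[1], cfgv[2], cfgv[3])
    params <- build_model(cfg, seed = 1)
    expect_equal(n_params(params), count_oracle(cfgv[1], cfgv[2], cfgv[3]))
  }
})

test_that("soft-dice loss matches hand evaluation and its limits", {
  g <- c(1, 1, 0, 0, 1, 0, 1, 0)
  expect_equal(softdice_loss(g, g, epsilon = 0), 0)       # perfect match
  expect_equal(softdice_loss(rep(0, 10), c(rep(1, 10))), 1,
               tolerance = 1e-6)                          # total miss
  # p uniform 0.5 over 8 items, 4 positives: 1 - (2*2)/(4+4) = 0.5
  expect_equal(softdice_loss(rep(0.5, 8), c(1, 1, 1, 1, 0, 0, 0, 0),
                             epsilon = 0), 0.5)
  # enumerated small batches against the formula
  set.seed(13)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    p <- runif(n); gg <- rbinom(n, 1, 0.5); eps <- 1e-7
    expect_equal(softdice_loss(p, gg, eps),
                 1 - (2 * sum(p * gg) + eps) / (sum(p) + sum(gg) + eps))
  }
  expect_error(softdice_loss(c(0.2, 0.3), c(1)), "equal length")
  expect_error(softdice_loss(c(1.2), c(1)), "\\[0, 1\\]")
})

test_that("soft-dice loss moves the right way with each probability", {
  set.seed(19)
  p <- runif(10); g <- rbinom(10, 1, 0.5)
  g[1] <- 1; g[2] <- 0
  base <- softdice_loss(p, g)
  up <- p; up[1] <- min(1, p[1] + 0.05)
  expect_lt(softdice_loss(up, g), base)   # raising a true-positive prob helps
  up2 <- p; up2[2] <- min(1, p[2] + 0.05)
  expect_gt(softdice_loss(up2, g), base)  # raising a false-positive prob hurts
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(conv_filters = 2L, dense_units_branch = 3L,
                      dense_units_head = 4L, dropout_rate = 0)
  params <- build_model(cfg, seed = 5)
  up <- mvseg:::unclass_params(params)
  X <- random_patch_blocks(4, seed = 6)
  labels <- c(1, 0, 1, 0)
  got <- mvseg:::cpp_mvcnn_loss_grad(X, labels, up, cfg, 1e-7)
  loss_at <- function(p) mvseg:::cpp_mvcnn_loss_grad(X, labels, p, cfg, 1e-7)$loss
  h <- 1e-5
  set.seed(7)
  for (nm in c("Wc1", "gamma3", "beta5", "Wd2", "bd4", "Wh", "bh", "Wo", "bo")) {
    for (rep in 1:4) {
      i <- sample(length(up[[nm]]), 1)
      pp <- up; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- up; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      an <- got$grads[[nm]][i]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d] analytic", nm, i))
    }
  }
})

test_that("inference is deterministic, batch independent and per-item", {
  params <- randomize_head(build_model(small_model_config(), seed = 9))
  X <- random_patch_blocks(16, seed = 10)
  ps <- lapply(1:16, function(i) patchsets_from_blocks(X, i))
  p_all <- forward(params, ps)
  # identical items give identical outputs
  p_dup <- forward(params, list(ps[[1]], ps[[1]]))
  expect_equal(p_dup[1, ], p_dup[2, ])
  # a singleton equals the same item inside a larger batch
  p_one <- forward(params, ps[[5]])
  expect_equal(unname(p_one[1, ]), unname(p_all[5, ]), tolerance = 1e-5)
  # permuting the batch permutes the outputs
  perm <- c(4, 1, 16, 9)
  p_perm <- forward(params, ps[perm])
  expect_equal(p_perm, p_all[perm, ], tolerance = 1e-12)
})

test_that("training mode differs from inference mode (dropout active)", {
  params <- randomize_head(build_model(model_config(conv_filters = 4L,
                                                    dense_units_branch = 8L,
                                                    dense_units_head = 16L,
                                                    dropout_rate = 0.5),
                                       seed = 3))
  X <- random_patch_blocks(6, seed = 4)
  ps <- lapply(1:6, function(i) patchsets_from_blocks(X, i))
  p_inf <- forward(params, ps, training_mode = FALSE)
  p_tr1 <- forward(params, ps, training_mode = TRUE, seed = 1)
  p_tr2 <- forward(params, ps, training_mode = TRUE, seed = 2)
  expect_false(isTRUE(all.equal(p_inf, p_tr1)))
  expect_false(isTRUE(all.equal(p_tr1, p_tr2)))
  expect_equal(forward(params, ps, training_mode = TRUE, seed = 1), p_tr1)
})

test_that("a tiny model overfits a fixed batch of separable patches", {
  n <- 512L
  labels <- rep(c(1, 0), length.out = n)
  X <- separable_patch_blocks(n, labels, shift = 2, seed = 8)
  cfg <- small_model_config()
  params <- build_model(cfg, seed = 1)
  res <- mvseg:::cpp_mvcnn_train_patches(X, labels,
                                         mvseg:::unclass_params(params), cfg,
                                         engine_opt(100, seed = 1), NULL)
  expect_lt(min(res$history), 0.05)
  expect_lt(res$history[100], res$history[1])
})

test_that("checkpoints round trip exactly", {
  dir <- withr::local_tempdir()
  params <- build_model(small_model_config(), seed = 12)
  p <- file.path(dir, "ck.rds")
  save_checkpoint(params, p, history = c(0.5, 0.2))
  back <- load_checkpoint(p)
  expect_identical(mvseg:::unclass_params(back), mvseg:::unclass_params(params))
  expect_equal(attr(back, "history"), c(0.5, 0.2))
  expect_equal(attr(back, "config"), attr(params, "config"))
})
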