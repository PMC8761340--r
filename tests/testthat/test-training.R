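test_that("learning-rate schedule is 0.001 * 0.8^floor(epoch/5)", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.001)
  expect_equal(lr_schedule(4, cfg), 0.001)
  expect_equal(lr_schedule(5, cfg), 0.0008)
  expect_equal(lr_schedule(24, cfg), 0.001 * 0.8^4)  # 4.096e-4
  expect_equal(lr_schedule(0:24, cfg), 0.001 * 0.8^(0:24 %/% 5))
  # non-increasing, piecewise constant on 5-epoch blocks
  lrs <- lr_schedule(0:24, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(unique(table(lrs)), 5L, ignore_attr = TRUE)
  expect_error(lr_schedule(-1, cfg), "non-negative")
  expect_error(lr_schedule(25, cfg), "epochs")
})

test_that("train_config validates its contract", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(lr_decay = 0), "lr_decay")
  cfg <- train_config()
  expect_equal(cfg$epochs, 25L)
  expect_equal(cfg$batch_size, 512L)
  expect_equal(cfg$tumor_frac, 0.5)
  expect_equal(cfg$healthy_frac, 0.01)
})

fold_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(case_id = sprintf("c%03d", 1:n),
             ref_volume_cm3 = runif(n, 0.5, 30),
             location = sample(c("ORAL_CAVITY", "OROPHARYNX", "HYPOPHARYNX"),
                               n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("make_folds builds a balanced stratified partition", {
  df <- fold_df(220)
  fs <- make_folds(df, k = 5, seed = 2)
  expect_equal(sort(unique(fs$fold)), 0:4)
  expect_equal(nrow(fs), 220)
  expect_false(any(duplicated(fs$case_id)))           # partition
  expect_equal(unname(table(fs$fold)), rep(44L, 5), ignore_attr = TRUE)
  # fold sizes within each stratum differ by at most 1
  for (s in split(fs, paste(fs$volume_group, fs$location))) {
    cnt <- table(factor(s$fold, levels = 0:4))
    expect_lte(max(cnt) - min(cnt), 1L)
  }
})

test_that("make_folds is seeded and handles degenerate strata", {
  df <- fold_df(30)
  f1 <- make_folds(df, k = 5, seed = 3)
  f2 <- make_folds(df, k = 5, seed = 3)
  expect_identical(f1, f2)
  f3 <- make_folds(df, k = 5, seed = 4)
  expect_false(identical(f1$fold, f3$fold))
  # same per-stratum balance regardless of seed
  bal <- function(f) lapply(split(f, paste(f$volume_group, f$location)),
                            function(s) sort(table(factor(s$fold, 0:4))))
  expect_equal(bal(f1), bal(f3))

  # 10 cases, all one stratum -> folds of 2
  df1 <- data.frame(case_id = paste0("x", 1:10), ref_volume_cm3 = rep(5, 10),
                    location = "OROPHARYNX")
  fs <- make_folds(df1, k = 5, seed = 1)
  expect_equal(unname(table(fs$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_error(make_folds(df1, k = 11), "more folds")
})

test_that("training declines the empty set and zero epochs", {
  expect_error(train_fold(list(), train_config(), model_config(),
                          label_mask(array(1L, c(4, 4, 4)))), "empty")
  expect_error(train_config(epochs = 0L), "epochs")
})

test_that("short training is reproducible and reduces the loss", {
  ph <- tiny_phantom_memo()
  pc <- prepared_canonical(ph)
  cfg <- train_config(epochs = 6L, seed = 2)
  fit1 <- train_fold(list(pc$prep), cfg, small_model_config(), pc$body)
  fit2 <- train_fold(list(pc$prep), cfg, small_model_config(), pc$body)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params$Wc1, fit2$params$Wc1)
  expect_lt(fit1$history[6], fit1$history[1])

  cfg3 <- train_config(epochs = 6L, seed = 3)
  fit3 <- train_fold(list(pc$prep), cfg3, small_model_config(), pc$body)
  expect_false(identical(fit1$history, fit3$history))
})

test_that("cross-validation holds out every case exactly once", {
  phs <- lapply(1:5, function(i) tiny_phantom(seed = 100 + i, volume = 1.5))
  preps <- lapply(seq_along(phs), function(i)
    prepared_canonical(phs[[i]], case_id = sprintf("cv%d", i))$prep)
  body <- prepared_canonical(phs[[1]])$body
  cfg <- train_config(epochs = 1L, folds = 5L, seed = 4)
  cv <- cross_validate(preps, cfg, small_model_config(), body)
  held <- unlist(lapply(cv$models, function(m) m$heldout))
  expect_setequal(held, sprintf("cv%d", 1:5))
  expect_false(any(duplicated(held)))
  # per-fold held-out list lengths equal the fold sizes
  sizes <- table(cv$folds$fold)
  for (m in cv$models)
    expect_length(m$heldout, sizes[[as.character(m$fold)]])
  # models trained on different data differ
  expect_false(identical(cv$models[[1]]$params$Wd1, cv$models[[2]]$params$Wd1))
})
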