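mk_mask <- function(vals, d = c(4, 4, 4)) label_mask(array(vals, d))

test_that("dsc matches set arithmetic, is symmetric and bounded", {
  a <- mk_mask(c(rep(1, 4), rep(0, 60)))
  b <- mk_mask(c(0, 1, 1, 1, 1, 1, 1, rep(0, 57)))
  # |a| = 4, |b| = 6, |a & b| = 3 -> 0.6
  expect_equal(dsc(a, b), 0.6)
  expect_equal(dsc(b, a), 0.6)
  expect_equal(dsc(a, a), 1)
  disj <- mk_mask(c(rep(0, 4), 1, 1, rep(0, 58)))
  expect_equal(dsc(a, disj), 0)
  expect_warning(d0 <- dsc(mk_mask(rep(0, 64)), mk_mask(rep(0, 64))), "empty")
  expect_equal(d0, 1)
  expect_error(dsc(a, mk_mask(rep(0, 27), c(3, 3, 3))), "share a grid")

  # brute-force oracle on random mask pairs
  set.seed(11)
  for (i in 1:200) {
    x <- rbinom(64, 1, runif(1, 0.1, 0.9))
    y <- rbinom(64, 1, runif(1, 0.1, 0.9))
    if (sum(x) + sum(y) == 0) next
    oracle <- 2 * length(intersect(which(x == 1), which(y == 1))) /
      (sum(x) + sum(y))
    expect_equal(dsc(mk_mask(x), mk_mask(y)), oracle)
  }
})

test_that("ICC(2,1) matches a from-scratch two-way ANOVA oracle", {
  icc_oracle <- function(x) {
    # independent route: mean squares from stats::aov on the long layout
    n <- nrow(x)
    long <- data.frame(y = c(x[, 1], x[, 2]),
                       case = factor(rep(seq_len(n), 2)),
                       rater = factor(rep(1:2, each = n)))
    ms <- summary(aov(y ~ case + rater, data = long))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  }
  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    ref <- runif(n, 1, 40)
    pred <- ref * runif(1, 0.6, 1.4) + rnorm(n, sd = runif(1, 0.5, 8)) +
      runif(1, -10, 10)
    x <- cbind(ref, pred)
    expect_equal(icc_absolute_agreement(x), icc_oracle(x), tolerance = 1e-10)
  }
})

test_that("ICC rewards agreement and penalizes bias", {
  ref <- c(2, 8, 14, 21, 30, 5)
  expect_equal(icc_absolute_agreement(cbind(ref, ref)), 1)
  biased <- cbind(ref, ref + 15)
  expect_lt(icc_absolute_agreement(biased), 0.6)
  expect_equal(cor(ref, ref + 15), 1)  # absolute agreement != correlation
  expect_error(icc_absolute_agreement(cbind(1:2, 1:2)), "at least 3")
  expect_error(icc_absolute_agreement(cbind(rep(2, 5), rep(2, 5))),
               "variance")
})

test_that("volume groups partition [0, Inf) with the standard boundaries", {
  expect_identical(volume_group(3.0), "V1")     # closed upper boundary
  expect_identical(volume_group(13.9), "V3")    # the median reference volume
  expect_identical(volume_group(15.000001), "V4")
  expect_identical(volume_group(0), "V1")
  expect_identical(volume_group(7), "V2")
  expect_identical(volume_group(7.0001), "V3")
  expect_error(volume_group(-1), "non-negative")
  set.seed(31)
  for (v in runif(100, 0, 40))
    expect_length(volume_group(v), 1L)
})

test_that("wilcoxon rank-sum is exact for small groups and symmetric", {
  # fully separated 3 vs 3: the minimal exact two-sided p is 2/C(6,3) = 0.1
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxon_ranksum(c(10, 11, 12), c(1, 2, 3)), 0.1)
  x <- c(1, 3, 5, 7, 9)
  expect_gt(wilcoxon_ranksum(x, x + 0.001), 0.5)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")

  # oracle: enumerate all rank assignments for a 3 vs 3 case
  x <- c(1.2, 4.5, 6.1); y <- c(2.2, 3.3, 9.9)
  pool <- c(x, y)
  w_obs <- sum(rank(pool)[1:3])
  combs <- combn(6, 3)
  ws <- apply(combs, 2, function(id) sum(rank(pool)[id]))
  mu <- mean(ws)
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(wilcoxon_ranksum(x, y), p_exact)
})

test_that("evaluate_cohort summarizes folds, subgroups and comparisons", {
  set.seed(41)
  n <- 40
  res <- do.call(rbind, lapply(seq_len(n), function(i) {
    vol <- runif(1, 0.5, 30)
    case_result(sprintf("c%02d", i), dsc = runif(1, 0.2, 0.9),
                ref_volume_cm3 = vol,
                pred_volume_cm3 = vol * runif(1, 0.7, 1.5),
                fold = (i - 1) %% 5,
                t_stage = sample(c("T2", "T3", "T4"), 1),
                n_stage = sample(c("N0", "N1", "N2"), 1),
                location = sample(c("ORAL_CAVITY", "OROPHARYNX"), 1))
  }))
  rep <- evaluate_cohort(res)
  expect_equal(rep$n, n)
  expect_length(rep$icc_per_fold, 5)
  # subgroup n sums to the cohort size within every stratification
  for (tab in rep$subgroups) expect_equal(sum(tab$n), n)
  # invariant to case order
  rep2 <- evaluate_cohort(res[sample(n), ])
  expect_equal(rep2$dsc_cases, rep$dsc_cases)
  expect_equal(rep2$icc, rep$icc)
  expect_equal(rep2$subgroups, rep$subgroups)

  # degenerate cohort: perfect everywhere
  perf <- do.call(rbind, lapply(1:9, function(i)
    case_result(paste0("p", i), 1, i, i, fold = (i - 1) %% 3)))
  rp <- evaluate_cohort(perf)
  expect_equal(unname(rp$dsc_cases["mean"]), 1)
  expect_equal(unname(rp$dsc_cases["sd"]), 0)

  # a fold with < 3 cases is skipped with a warning
  small <- do.call(rbind, lapply(1:5, function(i)
    case_result(paste0("s", i), 0.5, i, i + 1,
                fold = if (i <= 4) 0L else 1L)))
  expect_warning(rs <- evaluate_cohort(small), "fewer than 3")
  expect_length(rs$icc_per_fold, 1)
})

test_that("separated subgroups yield small rank-sum p at realistic n", {
  set.seed(51)
  res <- do.call(rbind, c(
    lapply(1:20, function(i) case_result(paste0("v1_", i),
      dsc = min(1, max(0, rnorm(1, 0.3, 0.12))), ref_volume_cm3 = runif(1, 0.5, 3),
      pred_volume_cm3 = 1, fold = i %% 5)),
    lapply(1:20, function(i) case_result(paste0("v4_", i),
      dsc = min(1, max(0, rnorm(1, 0.6, 0.12))), ref_volume_cm3 = runif(1, 16, 30),
      pred_volume_cm3 = 17, fold = i %% 5))))
  rep <- evaluate_cohort(res)
  pv <- rep$pairwise$volume_group
  expect_lt(pv$p_value[pv$group1 == "V1" & pv$group2 == "V4"], 0.05)
})
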