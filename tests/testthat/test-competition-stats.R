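test_that("per-disc ratios divide and validate", {
  df <- data.frame(loser_area = c(0, 100, 30),
                   winner_area = c(100, 100, 120))
  expect_equal(per_disc_ratio(df), c(0, 1, 0.25))
  expect_error(per_disc_ratio(data.frame(loser_area = 1, winner_area = 0)),
               "winner_area")
  expect_error(per_disc_ratio(data.frame(loser_area = -1,
                                         winner_area = 2)),
               "loser_area")
})

test_that("genotype summaries report mean, SEM and full n", {
  df <- data.frame(genotype = "a",
                   loser_area = c(0.5, 1.0, 1.5), winner_area = 1)
  s <- summarize_genotypes(df)
  expect_equal(s$mean_ratio, 1)
  expect_equal(s$sem, 0.5 / sqrt(3))
  expect_equal(s$n, 3)
  # constant ratios: SEM 0; n is conserved with no silent filtering
  df2 <- data.frame(genotype = rep(c("a", "b"), c(4, 6)),
                    loser_area = 0.7, winner_area = 1)
  s2 <- summarize_genotypes(df2)
  expect_equal(s2$sem, c(0, 0))
  expect_equal(sort(s2$n), c(4, 6))
  expect_equal(sum(s2$n), nrow(df2))
  expect_error(summarize_genotypes(df[0, ]), "input error")
})

test_that("D'Agostino-Pearson matches the reference implementation", {
  # expected values frozen from scipy.stats.normaltest / skewtest /
  # kurtosistest on the identical vectors (contract: agree within 1e-6)
  x1 <- c(2.1, 3.4, 1.9, 5.6, 4.2, 3.3, 2.8, 4.9, 3.1, 2.2, 6.0, 3.7)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 1.04586547068397, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.5927795307668322, tolerance = 1e-9)
  expect_equal(r1$z_skew, 0.9100557214678947, tolerance = 1e-9)
  expect_equal(r1$z_kurt, -0.46654480439451856, tolerance = 1e-9)
  x2 <- c(1, 1, 2, 2, 3, 10, 1, 2, 4, 1, 2, 3, 20, 1, 2)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 27.607693338053114, tolerance = 1e-9)
  expect_equal(r2$p_value, 1.011732177334785e-06, tolerance = 1e-12)
  x3 <- c(0.5, -1.2, 0.3, 2.1, -0.7, 0.9, -0.4, 1.5, 0.1, -2.0, 0.8,
          -0.3, 1.1, 0.6, -1.5, 0.2, 1.9, -0.9, 0.4, -0.1)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 0.10365399502970238, tolerance = 1e-9)
  expect_equal(r3$p_value, 0.9494931173035361, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
  expect_error(dagostino_pearson(rep(3, 20)), "zero-variance")
})

test_that("D'Agostino-Pearson holds its type-I rate and has power", {
  # type I: ~5% rejections on normal samples
  set.seed(2024)
  rej <- 0
  for (i in 1:200) rej <- rej + (dagostino_pearson(rnorm(5000))$p_value
                                 < 0.05)
  expect_gte(rej / 200, 0.03)
  expect_lte(rej / 200, 0.08)
  # power: a strongly skewed alternative is crushed
  set.seed(7)
  expect_lt(dagostino_pearson(rexp(1000))$p_value, 0.001)
})

test_that("rank_group_test: identical data, separation, pipeline groups", {
  expect_equal(rank_group_test(list(rep(2, 5), rep(2, 5))), 1)
  # complete separation at n=3,3: exact one-sided rank p is 1/20
  w <- stats::wilcox.test(c(101, 102, 103), c(1, 2, 3),
                          alternative = "greater")
  expect_equal(w$p.value, 1 / 20)
  expect_lt(rank_group_test(list(c(1, 2, 3), c(101, 102, 103))), 0.1)
  # k = 2 honours the Mann-Whitney (normal approximation) contract
  set.seed(3)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  kw <- rank_group_test(list(a, b))
  mw <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(kw, mw, tolerance = 1e-10)
  # strongly separated synthetic genotypes
  lo <- gen_clone_dataset(clone_dataset_spec("lo", 45, 0.95, seed = 21))
  hi <- gen_clone_dataset(clone_dataset_spec("hi", 45, 0.05, seed = 22))
  expect_lt(rank_group_test(list(per_disc_ratio(lo),
                                 per_disc_ratio(hi))), 0.001)
})

test_that("suppressor calls implement both criteria", {
  ctrl <- gen_clone_dataset(clone_dataset_spec("loser", 47, 0.95,
                                               seed = 101))
  resc <- gen_clone_dataset(clone_dataset_spec("rescue", 45, 0.05,
                                               noise_sd = 0.1, seed = 102))
  call <- call_suppressor(resc, ctrl, genotype = "rescue")
  expect_true(call$is_suppressor)
  expect_lt(call$ratio_test_p, 0.05)
  expect_gte(call$normality_p, 0.05)
  # candidate identical to control can never be a suppressor
  same <- call_suppressor(ctrl, ctrl)
  expect_false(same$is_suppressor)
  # asymmetry: swapping candidate and control cannot create a call
  expect_false(isTRUE(call_suppressor(ctrl, resc)$is_suppressor))
  # bimodal candidate (eliminated + fully rescued discs mixed) passes the
  # ratio criterion when rescued discs dominate the ranks, but the broken
  # distribution fails the normality criterion, so no call is made
  lo <- gen_clone_dataset(clone_dataset_spec("bim_lo", 16, 1, seed = 103))
  hi <- gen_clone_dataset(clone_dataset_spec("bim_hi", 31, 0,
                                             noise_sd = 0.05, seed = 104))
  bim <- rbind(lo, hi)
  bc <- call_suppressor(bim, ctrl, genotype = "bimodal")
  expect_lt(bc$ratio_test_p, 0.05)      # clone ratios did increase...
  expect_lt(bc$normality_p, 0.05)       # ...but the distribution is broken
  expect_false(bc$is_suppressor)
  # n < 8 refuses to call with a diagnostic rather than guessing
  small <- call_suppressor(resc[1:5, ], ctrl)
  expect_true(is.na(small$is_suppressor))
  expect_match(small$reason, "n < 8")
})

test_that("paired ratio t-test handles identity, degeneracy and power", {
  expect_equal(paired_ratio_test(c(2, 3, 4), c(2, 3, 4))$p_value, 1)
  deg <- paired_ratio_test(2 * (1:10), 1:10)
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
  expect_error(paired_ratio_test(c(1, -1), c(1, 1)), "input error")
  expect_error(paired_ratio_test(1:3, 1:2), "paired")
  # power: 1.5x effect with sigma = 0.2 lognormal noise, n = 20 pairs
  set.seed(55)
  hits <- 0
  for (i in 1:200) {
    ctrl <- rlnorm(20, log(100), 0.3)
    trt <- ctrl * 1.5 * rlnorm(20, 0, 0.2)
    hits <- hits + (paired_ratio_test(trt, ctrl)$p_value < 0.05)
  }
  expect_gt(hits / 200, 0.9)
})
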