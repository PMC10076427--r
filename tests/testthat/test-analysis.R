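## printed group summaries used as worked examples throughout:
## full session  (-76, 174.5, n=22) naltrexone vs (-39, 166.7, n=24) placebo
## ascending     (-32,  67.2, n=19)            vs ( +6,  53.1, n=24)
## plateau       (-64.7, 119.4, n=19)          vs (-46, 143.1, n=24)
nx_full <- function() group_summary(22, -76, 174.5)
pl_full <- function() group_summary(24, -39, 166.7)
nx_asc <- function() group_summary(19, -32, 67.2)
pl_asc <- function() group_summary(24, 6, 53.1)
nx_plat <- function() group_summary(19, -64.7, 119.4)
pl_plat <- function() group_summary(24, -46, 143.1)

test_that("pooled t statistics reproduce the printed worked examples", {
  plat <- two_sample_t(pl_plat(), nx_plat())
  expect_lt(abs(plat$t - 0.457), 0.005)
  expect_identical(plat$df, 41)
  full <- two_sample_t(pl_full(), nx_full())
  expect_lt(abs(full$t - 0.735), 0.005)
  expect_identical(full$df, 44)
  ## identical groups: t = 0
  g <- group_summary(10, 5, 2)
  expect_equal(two_sample_t(g, g)$t, 0)
  expect_error(two_sample_t(group_summary(5, 1, 0), group_summary(5, 1, 0)),
               "pooled")
})

test_that("Cohen's d and its normal-approximation CI match the printed values", {
  full <- cohens_d_ci(pl_full(), nx_full())
  expect_lt(abs(full$d - 0.217), 0.001)
  expect_lt(abs(full$lo - (-0.363)), 0.005)
  expect_lt(abs(full$hi - 0.797), 0.005)
  asc <- cohens_d_ci(pl_asc(), nx_asc())
  expect_lt(abs(asc$d - 0.643), 0.01)
  plat <- cohens_d_ci(pl_plat(), nx_plat())
  expect_lt(abs(plat$d - 0.140), 0.005)
  ## equal means: d = 0, CI symmetric
  g1 <- group_summary(12, 3, 1); g2 <- group_summary(15, 3, 2)
  dd <- cohens_d_ci(g1, g2)
  expect_equal(dd$d, 0)
  expect_equal(dd$lo, -dd$hi)
})

test_that("summary-based t and d equal per-observation brute force", {
  set.seed(77)
  for (i in 1:1000) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -5, 5), sd = runif(1, .5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -5, 5), sd = runif(1, .5, 3))
    tt <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
    expect_equal(cohens_d_ci(x, y)$d, brute_cohens_d(x, y), tolerance = 1e-12)
  }
})

test_that("d is scale invariant and t is shift invariant", {
  set.seed(3)
  x <- rnorm(15); y <- rnorm(20, 0.4)
  expect_equal(cohens_d_ci(3.7 * x, 3.7 * y)$d, cohens_d_ci(x, y)$d,
               tolerance = 1e-12)
  expect_equal(two_sample_t(x + 11, y + 11)$t, two_sample_t(x, y)$t,
               tolerance = 1e-12)
})

test_that("the missing-session imputation carries the group mean change", {
  expect_equal(impute_missing_change(500, c(-100, -60))$imputed_session2, 420)
  expect_equal(impute_missing_change(500, c(-100, -60))$imputed_change, -80)
  expect_equal(impute_missing_change(300, c(0, 0, 0))$imputed_session2, 300)
  expect_equal(impute_missing_change(40, -10)$imputed_session2, 30)
  expect_error(impute_missing_change(10, numeric(0)), "nonempty")
})

test_that("correlations behave on degenerate and random inputs", {
  expect_equal(pearson_r(1:3, c(2, 4, 6))$r, 1)
  expect_error(pearson_r(1:5, rep(2, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3")
  ## spearman equals rank-transformed pearson
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(spearman_rho(x, y)$rho,
                 unname(cor(rank(x), rank(y))), tolerance = 1e-12)
  }
  ## independent permutations have mean rho ~ 0
  set.seed(10)
  rhos <- replicate(10000, cor(sample(10), sample(10), method = "spearman"))
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("subjective slopes follow the assessment-pair definition", {
  sl <- subjective_slopes(c(10, 20, 50, 50), c(-25, 15, 75, 150))
  expect_equal(sl$ascending, 0.5)
  expect_equal(sl$plateau, 0)
  flat <- subjective_slopes(c(30, 30, 30, 30))
  expect_equal(flat$ascending, 0)
  expect_equal(flat$plateau, 0)
  rev <- subjective_slopes(-c(10, 20, 50, 50), c(-25, 15, 75, 150))
  expect_equal(rev$ascending, -0.5)
  expect_error(subjective_slopes(c(1, 2, 3)), "four")
  ## data-frame form: one slope pair per scale
  df <- data.frame(t = c(-25, 15, 75, 150), stimulation = c(10, 20, 50, 50),
                   desire = c(30, 30, 40, 70))
  out <- subjective_slopes(df)
  expect_equal(out$ascending[out$scale == "stimulation"], 0.5)
  expect_equal(out$plateau[out$scale == "desire"], 0.4)
})

test_that("endpoint analysis wires group summaries, d, and correlation", {
  set.seed(123)
  n <- 16
  ep <- data.frame(
    subject = sprintf("s%02d", 1:n),
    group = rep(c("placebo", "naltrexone"), each = n / 2),
    drug_level = c(rep(0, n / 2), runif(n / 2, 20, 90)),
    cwfa_1 = rpois(n, 300), cwfa_2 = rpois(n, 260),
    cwfs_1 = rpois(n, 60), cwfs_2 = rpois(n, 60),
    cwfa_asc_1 = rpois(n, 120), cwfa_asc_2 = rpois(n, 100),
    cwfa_plat_1 = rpois(n, 180), cwfa_plat_2 = rpois(n, 160),
    peak_brac_1 = rnorm(n, 120, 10), peak_brac_2 = rnorm(n, 115, 10),
    mean_brac_1 = rnorm(n, 95, 8), mean_brac_2 = rnorm(n, 92, 8))
  st <- analyze_endpoints(ep)
  expect_identical(st$control, "placebo")
  ch_p <- ep$cwfa_2[ep$group == "placebo"] - ep$cwfa_1[ep$group == "placebo"]
  ch_n <- ep$cwfa_2[ep$group == "naltrexone"] -
    ep$cwfa_1[ep$group == "naltrexone"]
  expect_equal(st$full$d, brute_cohens_d(ch_p, ch_n), tolerance = 1e-12)
  expect_equal(st$full$t, unname(t.test(ch_p, ch_n,
                                        var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(st$blood_level_correlation$r,
               unname(cor(ep$drug_level[ep$group == "naltrexone"], ch_n)),
               tolerance = 1e-12)
})
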