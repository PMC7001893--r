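test_that("constant differences give a degenerate but consistent summary", {
  ba <- bland_altman(c(5, 6, 7) + 2.5, c(5, 6, 7))
  expect_equal(ba$bias, 2.5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa, c(2.5, 2.5))
  expect_true(ba$degenerate)
  expect_true(is.na(ba$p))
})

test_that("limits of agreement follow bias +/- 1.96 SD", {
  # pairs constructed to have exact mean difference 0.12 and SD 0.38
  d <- 0.12 + c(-1, 1) * 0.38 / sqrt(2)
  ba <- bland_altman(c(3, 3) + d, c(3, 3))
  expect_equal(ba$bias, 0.12, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.38, tolerance = 1e-12)
  expect_equal(round_half_away(ba$loa), c(-0.62, 0.86))
  # LOA always brackets the bias; widening spread widens the limits
  set.seed(2)
  base <- rnorm(30)
  w1 <- bland_altman(base * 1 + 0.5, rep(0, 30))
  w2 <- bland_altman(base * 2 + 0.5, rep(0, 30))
  expect_lte(w1$loa[1], w1$bias); expect_gte(w1$loa[2], w1$bias)
  expect_lt(w2$loa[1], w1$loa[1]); expect_gt(w2$loa[2], w1$loa[2])
})

test_that("bland_altman is antisymmetric in its arguments", {
  set.seed(3)
  a <- rnorm(25, 5); b <- rnorm(25, 4.5)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(f$bias, -g$bias)
  expect_equal(f$sd_diff, g$sd_diff)
  expect_equal(f$loa, -rev(g$loa))
  expect_equal(f$p, g$p)
})

test_that("bland_altman recovers a known additive bias from noisy pairs", {
  # Monte-Carlo recovery: bias estimate within 3 sigma/sqrt(n) of truth
  beta <- 0.8; sigma <- 0.5; n <- 40
  set.seed(4)
  hits <- 0L
  for (r in 1:200) {
    truth <- runif(n, 2, 6)
    ba <- bland_altman(truth + beta + rnorm(n, sd = sigma), truth)
    if (abs(ba$bias - beta) <= 3 * sigma / sqrt(n)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99) # 3-sigma coverage ~ 99.7%
})

test_that("repeatability gives the within-subject SD and CR = 1.96*sqrt(2)*SD", {
  # identical repeats: no within-subject variation
  r0 <- repeatability(c(4, 4, 7, 7), c(1, 1, 2, 2))
  expect_equal(r0$sd, 0); expect_equal(r0$cr, 0)
  # the CR/SD ratio is the constant 2.7718... for any input
  set.seed(5)
  vals <- rnorm(20); subj <- rep(1:10, each = 2)
  r <- repeatability(vals, subj)
  expect_equal(r$cr / r$sd, 1.96 * sqrt(2), tolerance = 1e-12)
  # hand-computed oracle on a small case
  v <- c(3, 5, 10, 9); s <- c("a", "a", "b", "b")
  expect_equal(repeatability(v, s)$sd, sqrt((2^2 + 1^2) / 4))
  expect_error(repeatability(c(1, 2), c(1, 2)), "2 repeats")
})

test_that("printed repeatability rows reproduce at 2 dp from their SDs", {
  # construct repeats whose within-subject SD is exactly the given value,
  # then check the 95% CR the report prints
  for (case in list(c(sd = 7.37, cr = 20.43), c(sd = 1.14, cr = 3.16))) {
    d <- case[["sd"]] * sqrt(2)
    r <- repeatability(c(10, 10 + d), c(1, 1))
    expect_equal(r$sd, case[["sd"]], tolerance = 1e-12)
    expect_equal(round_half_away(r$cr), case[["cr"]])
  }
  expect_equal(round_half_away(repeatability_coefficient(7.37)), 20.43)
  expect_equal(round_half_away(repeatability_coefficient(1.14)), 3.16)
})

test_that("the one-sample test flags degenerate input and matches t.test", {
  expect_true(one_sample_test(rep(2, 5))$degenerate)
  set.seed(6)
  d <- rnorm(30, 0.3)
  res <- one_sample_test(d)
  ref <- t.test(d, mu = 0)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("one-sample test is calibrated under the null", {
  # type-I error at alpha = 0.05 over seeded null replicates
  set.seed(7)
  rej <- 0L; B <- 500L
  for (r in seq_len(B))
    if (one_sample_test(rnorm(25))$p < 0.05) rej <- rej + 1L
  expect_gt(rej / B, 0.03)
  expect_lt(rej / B, 0.07)
})

test_that("one-sample test power matches the closed form", {
  # noncentral t oracle: power for mean delta, sd 1, n = 20 at alpha 0.05
  n <- 20; delta <- 0.7
  ncp <- delta * sqrt(n)
  tc <- qt(0.975, n - 1)
  power_cf <- pt(-tc, n - 1, ncp) + 1 - pt(tc, n - 1, ncp)
  set.seed(8)
  B <- 800L
  rej <- sum(replicate(B, one_sample_test(rnorm(n, delta))$p < 0.05))
  mc_se <- sqrt(power_cf * (1 - power_cf) / B)
  expect_lt(abs(rej / B - power_cf), 4 * mc_se)
})

test_that("the omnibus normality statistic matches an independent implementation", {
  # expected values frozen from scipy.stats.normaltest on the same inputs
  x <- c(3.1, -0.4, 2.2, 0.9, -1.7, 4.4, 0.2, 1.1, -2.6, 3.3, 0.7, 1.9,
         -0.8, 2.5, 5.1, -1.2, 0.3, 2.8, 1.4, -3.0)
  dp <- dagostino_pearson(x)
  expect_equal(dp$k2, 0.2556242229, tolerance = 1e-9)
  expect_equal(dp$p, 0.8800187090, tolerance = 1e-9)
  y <- exp(seq(0.1, 3, length.out = 25))
  dy <- dagostino_pearson(y)
  expect_equal(dy$k2, 4.8975429146, tolerance = 1e-9)
  expect_equal(dy$p, 0.0863996670, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("normality screens accept normal samples and catch heavy skew", {
  set.seed(9)
  B <- 200L
  ok_norm <- 0L; catch_skew <- 0L
  for (r in seq_len(B)) {
    ns <- normality_screen(rnorm(50))
    if (ns$dagostino_p > 0.05 && ns$shapiro_p > 0.05) ok_norm <- ok_norm + 1L
    if (normality_screen(rexp(50))$dagostino_p < 0.05)
      catch_skew <- catch_skew + 1L
  }
  expect_gte(ok_norm / B, 0.85)
  expect_gte(catch_skew / B, 0.90)
  small <- normality_screen(rnorm(5))
  expect_true(small$skipped)
  expect_true(is.na(small$dagostino_p))
})

test_that("agreement and repeatability reports run per condition on long data", {
  set.seed(10)
  n_sub <- 8
  grid <- expand.grid(subject = 1:n_sub, condition = c("a", "e"),
                      repeat_idx = 1:2)
  truth <- 3 + 10 * (grid$condition == "e") + rnorm(nrow(grid))
  long <- rbind(
    data.frame(grid, method = "pendulum",
               sway_rms_mm = truth + 0.5 + rnorm(nrow(grid), sd = 0.2)),
    data.frame(grid, method = "three_joint",
               sway_rms_mm = truth + rnorm(nrow(grid), sd = 0.2)))
  rep_ <- agreement_report(long)
  expect_setequal(rep_$table$condition, c("a", "e"))
  expect_equal(rep_$table$n, c(16, 16))
  expect_true(all(abs(rep_$table$bias - 0.5) < 0.5))
  expect_true(all(rep_$table$loa_lo <= rep_$table$bias &
                    rep_$table$bias <= rep_$table$loa_hi))
  # averaging repeats halves n per condition
  rep_avg <- agreement_report(long, average_repeats = TRUE)
  expect_equal(rep_avg$table$n, c(8, 8))
  # unpaired records are refused with the orphan named
  expect_error(agreement_report(long[-1, ]), "unpaired")

  rpt <- repeatability_report(long)
  expect_equal(nrow(rpt), 4)
  expect_equal(rpt$cr / rpt$sd, rep(1.96 * sqrt(2), 4), tolerance = 1e-12)
})
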