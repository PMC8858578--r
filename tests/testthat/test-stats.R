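test_that("required significant count matches brute enumeration for all k <= 100", {
  for (k in 1:100) {
    for (frac in c(0.5, 0.8, 0.95, 1.0)) {
      # smallest m such that m/k >= frac, by enumeration
      want <- min(which(vapply(1:k, function(m) m / k >= frac - 1e-12,
                               logical(1))))
      expect_equal(required_significant_count(k, frac), want)
    }
  }
  expect_equal(required_significant_count(20, 0.80), 16L)
  expect_equal(required_significant_count(20, 1.0), 20L)
  expect_equal(required_significant_count(7, 0.80), 6L)
})

test_that("signed-rank Z and p agree with exact enumeration at small n", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:9, 1)
    x <- round(stats::rnorm(n, 0.3), 3)
    y <- round(stats::rnorm(n), 3)
    d <- x - y
    if (any(d == 0) || any(duplicated(abs(d[d != 0])))) next
    got <- wilcoxon_signed_z(x, y)
    expect_equal(got$p, oracle_signrank_p(d), tolerance = 1e-10)
  }
  # Z sign follows the direction of the rank mass; all-zero -> p = 1
  up <- wilcoxon_signed_z(11:30 + 0.5, 11:30 - 0.5)
  dn <- wilcoxon_signed_z(11:30 - 0.5, 11:30 + 0.5)
  expect_gt(up$z, 0); expect_lt(dn$z, 0)
  expect_equal(up$z, -dn$z)
  z0 <- wilcoxon_signed_z(1:8, 1:8)
  expect_equal(z0$z, 0); expect_equal(z0$p, 1)
  # at n = 19 the normal-approximation Z reproduces the p it reports
  n19 <- wilcoxon_signed_z(stats::rnorm(19, 0.5), stats::rnorm(19))
  expect_equal(2 * stats::pnorm(-abs(n19$z)), n19$p, tolerance = 0.02)
})

test_that("effect size r is Z over root N", {
  expect_equal(effect_size_r(-2.34, 19), -2.34 / sqrt(19))
  expect_equal(effect_size_r(0, 19), 0)
  expect_equal(round(effect_size_r(-0.88, 19), 2), -0.20)
})

test_that("balanced subsamples respect size and pro-proportion constraints", {
  set.seed(3)
  trials <- data.frame(
    participant = rep(c("a", "b"), c(105, 60)),
    outcome = c(rep("error", 5), rep("correct", 100),
                rep("error", 4), rep("correct", 56)),
    trial_class = c(rep(c("pro", "pro", "anti", "anti", "nogo"), 1),
                    sample(rep(c("pro", "anti"), 50)),
                    rep("anti", 4), sample(rep(c("pro", "anti"), 28))))
  cfg <- replication_config(k_subsamples = 10, seed = 5)
  subs <- balanced_subsamples(trials, cfg)
  expect_length(subs, 10)
  for (k in seq_along(subs)) {
    ia <- subs[[k]][["a"]]; ib <- subs[[k]][["b"]]
    expect_length(ia, 5)              # a has 5 errors
    expect_length(ib, 4)
    expect_true(all(trials$outcome[c(ia, ib)] == "correct"))
    expect_equal(sum(trials$trial_class[ia] == "pro"), 2)  # 2 of a's errors are pro
    expect_equal(sum(trials$trial_class[ib] == "pro"), 0)  # b has no pro errors
  }
  # iterations are distinct draws but reproducible under the seed
  expect_false(identical(subs[[1]], subs[[2]]))
  expect_identical(subs, balanced_subsamples(trials, cfg))
  # a participant with zero errors is skipped
  trials0 <- rbind(trials, data.frame(participant = "c", outcome = "correct",
                                      trial_class = "pro"))
  expect_named(balanced_subsamples(trials0, cfg)[[1]], c("a", "b"))
  # infeasible pro counts are relaxed with a warning
  tr_inf <- data.frame(participant = "d",
                       outcome = c(rep("error", 4), rep("correct", 6)),
                       trial_class = c(rep("pro", 4), rep("anti", 6)))
  expect_warning(balanced_subsamples(tr_inf, cfg), "relaxed")
})

test_that("replication test decides, aggregates and is monotone in the effect", {
  set.seed(11)
  mk <- function(shift) {
    do.call(rbind, lapply(1:12, function(i) {
      n_e <- 8
      data.frame(participant = sprintf("p%02d", i),
                 outcome = rep(c("error", "correct"), c(n_e, 60)),
                 trial_class = sample(c("pro", "anti"), n_e + 60, TRUE),
                 value = c(stats::rnorm(n_e, shift, 1), stats::rnorm(60, 0, 1)))
    }))
  }
  cfg <- replication_config(seed = 7)
  null_res <- replication_test(mk(0), "value", cfg)
  expect_s3_class(null_res, "replication_result")
  expect_equal(nrow(null_res$iterations), 20)
  expect_equal(null_res$required, 16)
  expect_equal(null_res$n_sig, sum(null_res$iterations$p <= 0.05))
  expect_equal(null_res$decision, null_res$n_sig >= 16)
  expect_equal(null_res$mean_r, mean(null_res$iterations$z) / sqrt(12))
  strong <- replication_test(mk(1.5), "value", cfg)
  expect_true(strong$decision)
  # monotonicity on fixed subsample indices: pushing the error values
  # further in the effect direction never loses significant iterations
  base <- mk(1.0)
  r1 <- replication_test(base, "value", cfg)
  pushed <- base
  pushed$value[pushed$outcome == "error"] <-
    pushed$value[pushed$outcome == "error"] + 0.5
  r2 <- replication_test(pushed, "value", cfg)
  expect_gte(r2$n_sig, r1$n_sig)
  # too few participants errors out
  expect_error(replication_test(mk(0)[1:300, ], "value", cfg), "6 participants")
})

test_that("the normality gate routes sensible branches", {
  set.seed(21)
  expect_equal(normality_gate(stats::rnorm(18), stats::rnorm(18))$branch,
               "parametric")
  heavy <- replicate(40, normality_gate(stats::rcauchy(18))$branch)
  expect_gt(mean(heavy == "nonparametric"), 0.8)
  expect_equal(normality_gate(rep(1, 10))$branch, "nonparametric")
  # calibration: the gate false-switches on normal data at roughly alpha
  fp <- mean(replicate(300, normality_gate(stats::rnorm(18))$branch ==
                         "nonparametric"))
  expect_lt(abs(fp - 0.05), 0.04)
})

test_that("omnibus error-type comparison gates, tests and sizes effects", {
  set.seed(31)
  # no effect, normal, n >= small_n -> RM-ANOVA with F near 0..1, p spread
  v <- matrix(stats::rnorm(18 * 3), 18)
  res <- omnibus_error_types(v)
  expect_true(res$method %in% c("rm_anova", "friedman"))
  # identical condition means -> statistic exactly 0
  v0 <- matrix(rep(stats::rnorm(12), 3), ncol = 3)
  res0 <- omnibus_error_types(v0)
  expect_equal(unname(res0$statistic), 0, tolerance = 1e-10)
  # small samples use Friedman
  v8 <- matrix(stats::rnorm(8 * 3), 8)
  expect_equal(omnibus_error_types(v8)$method, "friedman")
  # type-I calibration and monotone power at moderate replicate count
  pvals_null <- replicate(150, omnibus_error_types(
    matrix(stats::rnorm(18 * 3), 18))$p)
  expect_lt(abs(mean(pvals_null < 0.05) - 0.05), 0.05)
  power_of <- function(d) mean(replicate(80, {
    m <- matrix(stats::rnorm(18 * 3), 18); m[, 1] <- m[, 1] + d
    omnibus_error_types(m)$p < 0.05
  }))
  expect_gt(power_of(1.2), power_of(0.3))
  # missing cells -> listwise drop with warning
  vna <- v; vna[1, 2] <- NA
  expect_warning(omnibus_error_types(vna), "dropped")
})

test_that("the JZS paired Bayes factor matches an independent quadrature", {
  for (case in list(c(t = 2.2, n = 15), c(t = 0.3, n = 25), c(t = -3.1, n = 19))) {
    got <- errtheta:::jzs_bf10(case[["t"]], case[["n"]])
    want <- oracle_jzs_bf10(case[["t"]], case[["n"]])
    expect_equal(got, want, tolerance = 1e-4)
  }
  set.seed(41)
  # evidence for the null accumulates with n under the null
  bf_small <- paired_bayes_factor(stats::rnorm(12), stats::rnorm(12))
  x <- stats::rnorm(200); y <- x + stats::rnorm(200, 0, 1)
  bf_big <- paired_bayes_factor(x, y)
  expect_gt(bf_big$bf01, 1)
  # a strong planted shift gives decisive evidence
  bf_eff <- paired_bayes_factor(stats::rnorm(20, 1.5), stats::rnorm(20))
  expect_gt(bf_eff$bf10, 10)
  # labels follow the conventional scale
  expect_match(errtheta:::bf_label(4.37), "moderate evidence for H1")
  expect_match(errtheta:::bf_label(1 / 20), "strong evidence for H0")
  # degenerate differences are flagged
  expect_match(paired_bayes_factor(1:10, 1:10 + 2)$label, "undefined")
})
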