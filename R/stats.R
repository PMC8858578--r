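# Statistical machinery: the 20-subsample class-balanced Wilcoxon
# replication procedure with pro-saccade proportion matching, signed-rank
# effect sizes, the Shapiro-Wilk parametric/nonparametric gate, the omnibus
# error-type comparison, and the JZS paired Bayes factor.

#' Replication-test configuration
#'
#' Because correct trials outnumber error trials roughly twenty-fold, the
#' correct-versus-error comparison is run on `k_subsamples` class-balanced
#' subsamples: per participant, each subsample draws as many correct trials
#' as that participant has error trials, keeping the pro-saccade proportion
#' equal to that of the participant's error set (anti-saccade and no-go
#' trials demand inhibitory control; pro-saccade trials do not). A
#' difference is declared significant when at least
#' `required_fraction` of the `k_subsamples` paired Wilcoxon tests reach
#' `alpha` (16 of 20 by default).
#'
#' @param k_subsamples Number of subsample iterations.
#' @param alpha Per-test significance level.
#' @param required_fraction Fraction of tests that must reach `alpha`.
#' @param match_pro_proportion Keep the pro-saccade proportion of each
#'   subsample equal to the participant's error set.
#' @param seed Integer seed for the subsample draws.
#' @return An object of class `replication_config`.
#' @export
replication_config <- function(k_subsamples = 20, alpha = 0.05,
                               required_fraction = 0.80,
                               match_pro_proportion = TRUE, seed = 1) {
  stopifnot(k_subsamples >= 1, alpha > 0, alpha < 1,
            required_fraction > 0, required_fraction <= 1)
  structure(as.list(environment()), class = "replication_config")
}

#' Number of significant tests required by the decision rule
#'
#' `ceiling(fraction * k)`, evaluated with a numeric guard so that exact
#' products (e.g. 0.80 x 20 = 16) are not pushed up by floating-point
#' round-off.
#'
#' @param k Number of tests.
#' @param fraction Required fraction in (0, 1].
#' @return Integer count.
#' @examples
#' required_significant_count(20, 0.80)  # 16
#' @export
required_significant_count <- function(k, fraction) {
  stopifnot(k >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * k - 1e-9))
}

#' Signed-rank effect size r = Z / sqrt(N)
#'
#' @param z Standardised Wilcoxon statistic.
#' @param n Number of participants.
#' @return `z / sqrt(n)`.
#' @examples
#' effect_size_r(-2.34, 19)  # -0.54
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n >= 1)
  z / sqrt(n)
}

#' Signed Z and p of the paired Wilcoxon signed-rank test
#'
#' Two-sided test on `x - y`. Zero differences are dropped (Wilcoxon's
#' convention); the standardised statistic uses the normal approximation
#' with tie correction and a continuity correction, signed by the direction
#' of the rank sum (negative when `x` tends below `y`); the p-value comes
#' from [stats::wilcox.test] (exact for fewer than 10 non-zero untied pairs,
#' normal approximation with continuity correction otherwise). All-zero
#' differences give `z = 0`, `p = 1`.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `z`, `p`, `n_nonzero`.
#' @export
wilcoxon_signed_z <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = 0, p = 1, n_nonzero = 0L))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  num <- w_pos - mu
  z <- if (sig2 > 0) (num - sign(num) * 0.5) / sqrt(sig2) else 0
  use_exact <- n < 10 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = use_exact,
                       correct = TRUE)$p.value)
  list(z = z, p = p, n_nonzero = as.integer(n))
}

#' Draw class-balanced correct-trial subsamples
#'
#' For each of `cfg$k_subsamples` iterations and each participant, draws
#' (without replacement within the iteration, independently across
#' iterations) as many correct trials as the participant has error trials.
#' With `match_pro_proportion`, the number of pro-saccade trials drawn
#' equals `round(pro fraction of the participant's errors x subsample
#' size)` (rounding half toward fewer pro trials), which for equally sized
#' subsamples is exactly the participant's pro-error count. Infeasible
#' pro counts are relaxed to the nearest feasible value with a warning.
#'
#' @param trials Data frame with columns `participant`, `outcome`
#'   (`"correct"`/`"error"`), `trial_class`.
#' @param cfg A [replication_config()].
#' @return List of `k_subsamples` lists: per participant, integer row
#'   indices (into `trials`) of the drawn correct trials. Participants
#'   without both an error and a correct trial are skipped.
#' @export
balanced_subsamples <- function(trials, cfg = replication_config()) {
  set.seed(as.integer(cfg$seed))
  parts <- unique(trials$participant)
  per_part <- lapply(parts, function(p) {
    rows <- which(trials$participant == p)
    corr <- rows[trials$outcome[rows] == "correct"]
    err <- rows[trials$outcome[rows] == "error"]
    n_e <- length(err)
    if (n_e == 0 || length(corr) == 0) return(NULL)
    corr_pro <- corr[trials$trial_class[corr] == "pro"]
    corr_other <- setdiff(corr, corr_pro)
    p_pro <- mean(trials$trial_class[err] == "pro")
    n_pro <- floor(p_pro * n_e + 0.5 - 1e-9)  # ties toward fewer pro
    n_sub <- min(n_e, length(corr))
    if (n_sub < n_e)
      warning("participant ", p, ": fewer correct than error trials; ",
              "subsample size reduced to ", n_sub)
    n_pro <- round(n_pro * n_sub / n_e)
    if (n_pro > length(corr_pro) || n_sub - n_pro > length(corr_other)) {
      n_pro <- min(max(n_pro, n_sub - length(corr_other)), length(corr_pro))
      warning("participant ", p, ": pro-proportion constraint relaxed")
    }
    list(corr_pro = corr_pro, corr_other = corr_other,
         n_pro = if (cfg$match_pro_proportion) n_pro else NA, n_sub = n_sub)
  })
  names(per_part) <- parts
  per_part <- per_part[!vapply(per_part, is.null, logical(1))]
  lapply(seq_len(cfg$k_subsamples), function(k)
    lapply(per_part, function(pp) {
      if (is.na(pp$n_pro)) {
        sample(c(pp$corr_pro, pp$corr_other), pp$n_sub)
      } else {
        c(if (pp$n_pro > 0) sample(pp$corr_pro, pp$n_pro) else integer(),
          if (pp$n_sub - pp$n_pro > 0)
            sample(pp$corr_other, pp$n_sub - pp$n_pro) else integer())
      }
    }))
}

#' Subsampled balanced Wilcoxon replication test
#'
#' Runs the full procedure on a tidy per-trial table: draws
#' [balanced_subsamples()], forms per-participant means of the error trials
#' and of each iteration's correct subsample, runs a two-sided paired
#' Wilcoxon signed-rank test across participants per iteration, and applies
#' the at-least-`required_fraction` decision rule. Participants without
#' errors are dropped with a warning.
#'
#' @param trials Data frame with `participant`, `outcome`, `trial_class`,
#'   and the metric column named by `value`.
#' @param value Name of the metric column.
#' @param cfg A [replication_config()].
#' @return A `replication_result`: list with `iterations` (data.frame `z`,
#'   `p`, `r` per iteration), `mean_z`, `sd_z`, `min_p`, `max_p`, `n_sig`,
#'   `required`, `decision` (`TRUE` = significant), `mean_r`, `sd_r`,
#'   `n_participants`.
#' @export
replication_test <- function(trials, value = "power_db",
                             cfg = replication_config()) {
  stopifnot(value %in% names(trials))
  trials <- trials[!is.na(trials[[value]]), , drop = FALSE]
  subs <- balanced_subsamples(trials, cfg)
  parts <- names(subs[[1]])
  dropped <- setdiff(unique(trials$participant), parts)
  if (length(dropped))
    warning("participants without paired data dropped: ",
            paste(dropped, collapse = ", "))
  n_part <- length(parts)
  if (n_part < 6) stop("need at least 6 participants with both conditions")
  err_mean <- vapply(parts, function(p)
    mean(trials[[value]][trials$participant == p & trials$outcome == "error"]),
    numeric(1))
  its <- lapply(subs, function(idx) {
    corr_mean <- vapply(parts, function(p) mean(trials[[value]][idx[[p]]]),
                        numeric(1))
    wt <- wilcoxon_signed_z(err_mean, corr_mean)
    c(z = wt$z, p = wt$p)
  })
  its <- as.data.frame(do.call(rbind, its))
  its$r <- effect_size_r(its$z, n_part)
  k <- cfg$k_subsamples
  req <- required_significant_count(k, cfg$required_fraction)
  n_sig <- sum(its$p <= cfg$alpha)
  structure(list(iterations = its, mean_z = mean(its$z), sd_z = stats::sd(its$z),
                 min_p = min(its$p), max_p = max(its$p),
                 n_sig = n_sig, required = req, decision = n_sig >= req,
                 mean_r = mean(its$r), sd_r = stats::sd(its$r),
                 n_participants = n_part, config = cfg),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result> %d iterations, N = %d participants\n",
              nrow(x$iterations), x$n_participants))
  cat(sprintf("  mean Z = %.2f +/- %.2f, r = %.2f +/- %.2f\n",
              x$mean_z, x$sd_z, x$mean_r, x$sd_r))
  cat(sprintf("  %d/%d tests with p <= %.2f (need %d): %s\n",
              x$n_sig, nrow(x$iterations), x$config$alpha, x$required,
              if (x$decision) "SIGNIFICANT" else "not significant"))
  invisible(x)
}

#' Shapiro-Wilk gate between parametric and nonparametric branches
#'
#' Tests each supplied dataset (for two-condition designs pass the paired
#' differences) at `alpha`; any rejection, or any degenerate sample on
#' which the test is undefined (e.g. constant data), routes to the
#' nonparametric branch.
#'
#' @param ... Numeric vectors (or one list of them).
#' @param alpha Gate level.
#' @return List with `branch` (`"parametric"`/`"nonparametric"`) and
#'   `p_values`.
#' @export
normality_gate <- function(..., alpha = 0.05) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !is.data.frame(xs[[1]]))
    xs <- xs[[1]]
  ps <- vapply(xs, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || stats::sd(v) == 0) return(0)  # undefined -> gate fires
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  list(branch = if (any(ps < alpha)) "nonparametric" else "parametric",
       p_values = ps)
}

#' Omnibus comparison of the three error types
#'
#' Compares per-participant values across the pro/anti/no-go conditions with
#' a repeated-measures ANOVA (reporting F, p and partial eta squared =
#' SS_effect / (SS_effect + SS_error)) when the Shapiro-Wilk gate passes and
#' the sample is not small, or a Friedman test (chi-squared, p) otherwise.
#' Participants with a missing cell are dropped listwise with a warning.
#'
#' @param values Matrix or data.frame, participants x 3 conditions.
#' @param small_n Friedman is always used below this many participants.
#' @param alpha Gate level.
#' @return List with `method`, `statistic`, `p`, `effect_size` (partial eta
#'   squared, ANOVA only), `n`.
#' @export
omnibus_error_types <- function(values, small_n = 10, alpha = 0.05) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 3)
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning(sum(!complete), " participants dropped (missing cells)")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values)
  stopifnot(n >= 3)
  if (all(apply(values, 1, function(r) diff(range(r)) == 0))) {
    # every participant identical across conditions: no effect by definition
    return(list(method = "friedman", statistic = 0, p = 1,
                effect_size = NA_real_, n = n))
  }
  gate <- normality_gate(as.list(as.data.frame(values)), alpha = alpha)
  if (gate$branch == "nonparametric" || n < small_n) {
    ft <- stats::friedman.test(values)
    return(list(method = "friedman", statistic = unname(ft$statistic),
                p = ft$p.value, effect_size = NA_real_, n = n))
  }
  long <- data.frame(y = as.numeric(values),
                     cond = factor(rep(seq_len(ncol(values)), each = n)),
                     id = factor(rep(seq_len(n), ncol(values))))
  fit <- stats::aov(y ~ cond + Error(id / cond), data = long)
  tab <- summary(fit)[["Error: id:cond"]][[1]]
  ss_eff <- tab["cond", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  list(method = "rm_anova", statistic = tab["cond", "F value"],
       p = tab["cond", "Pr(>F)"],
       effect_size = ss_eff / (ss_eff + ss_err), n = n)
}

#' Paired JZS (Cauchy-prior) Bayes factor
#'
#' Default-prior Bayes factor on the paired differences, computed from the
#' one-sample t statistic by numerical integration of the
#' Jeffreys-Zellner-Siow marginal likelihood (Cauchy prior with scale
#' `prior_scale` on the standardised effect). Both directions are reported:
#' `bf10` (evidence for a difference) and `bf01 = 1 / bf10`, with the
#' conventional evidence label for whichever exceeds 1 (3-10 "moderate",
#' etc.).
#'
#' @param x,y Paired numeric vectors.
#' @param prior_scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return List with `bf10`, `bf01`, `t`, `n`, `label`.
#' @export
paired_bayes_factor <- function(x, y, prior_scale = sqrt(2) / 2) {
  d <- (x - y)
  d <- d[!is.na(d)]
  n <- length(d)
  stopifnot(n >= 3)
  if (stats::sd(d) == 0)
    return(list(bf10 = NA_real_, bf01 = NA_real_, t = NA_real_, n = n,
                label = "undefined (zero-variance differences)"))
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  bf10 <- jzs_bf10(t_stat, n, prior_scale)
  list(bf10 = bf10, bf01 = 1 / bf10, t = t_stat, n = n,
       label = bf_label(bf10))
}

# JZS marginal-likelihood ratio via the g-prior integral
jzs_bf10 <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  h0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  f <- function(g) {
    (1 + n * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  h1 <- stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
  h1 / h0
}

bf_label <- function(bf10) {
  b <- max(bf10, 1 / bf10)
  side <- if (bf10 >= 1) "H1" else "H0"
  strength <- if (b < 3) "anecdotal" else if (b < 10) "moderate" else
    if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  sprintf("%s evidence for %s", strength, side)
}
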