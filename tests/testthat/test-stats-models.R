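test_that("LMM fixed effects match OLS when subject variance is zero", {
  d <- simulate_lmm_trials(30, beta = c(intercept = 0.5, cs = 0.1,
                                        trial = -0.01, cs_trial = 0.02),
                           sigma_b = 0, sigma_e = 0.2, seed = 42)
  fit <- fit_phase_lmm(d, "acquisition")
  ols <- lm(scr_sqrt ~ factor(trial_type, levels = c("CS-", "CS+")) *
              trial_index, data = d)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$n_subjects, 30L)
  # boundary variance is reported, not hidden
  expect_true(is.null(fit$note) || grepl("boundary", fit$note))
})

test_that("LMM coefficient table has the study's structure", {
  d <- simulate_lmm_trials(20, beta = c(intercept = 0.5, cs = 0.15),
                           seed = 7)
  fit <- fit_phase_lmm(d, "acquisition")
  expect_named(fit$coefficients,
               c("term", "estimate", "se", "statistic", "df", "p"))
  expect_equal(fit$coefficients$term,
               c("(Intercept)", "csCS+", "trial", "csCS+:trial"))
  expect_true(all(fit$coefficients$se > 0))
  expect_true(all(fit$coefficients$p >= 0 & fit$coefficients$p <= 1))
  expect_true(is.finite(fit$varcomp$subject_sd))
  # Satterthwaite df are fractional and less than n_obs
  expect_true(all(fit$coefficients$df < fit$n_obs))
})

test_that("marginal likelihood matches a direct evaluation on a tiny fit", {
  d <- simulate_lmm_trials(5, n_trials = 2, sigma_b = 0.3, sigma_e = 0.2,
                           beta = c(intercept = 0.4, cs = 0.2), seed = 11)
  d$cs <- factor(d$trial_type, levels = c("CS-", "CS+"))
  d$trial <- d$trial_index
  fit <- lme4::lmer(scr_sqrt ~ cs * trial + (1 | subject), data = d,
                    REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sb2 <- vc$vcov[vc$grp == "subject"][1]
  se2 <- vc$vcov[vc$grp == "Residual"][1]
  X <- model.matrix(~ cs * trial, d)
  ll <- direct_lmm_loglik(split(d$scr_sqrt, d$subject),
                          lapply(split(seq_len(nrow(d)), d$subject),
                                 function(i) X[i, , drop = FALSE]),
                          lme4::fixef(fit), sb2, se2)
  expect_equal(as.numeric(logLik(fit)), ll, tolerance = 1e-6)
})

test_that("group model is invariant to the reference-group coding", {
  d <- simulate_lmm_trials(c(child = 8, adolescent = 8, adult = 8),
                           beta = c(intercept = 0.5, cs = 0.1),
                           group_effects = list(child = 0.1, adult = -0.05),
                           seed = 13)
  f_adol <- fit_group_lmm(d, "acquisition", reference_group = "adolescent")
  f_child <- fit_group_lmm(d, "acquisition", reference_group = "child")
  # reparameterisation: identical fit quality, different coding
  expect_equal(as.numeric(logLik(f_adol$fit)),
               as.numeric(logLik(f_child$fit)), tolerance = 1e-6)
  expect_equal(fitted(f_adol$fit), fitted(f_child$fit), tolerance = 1e-6)
  expect_equal(nrow(f_adol$coefficients), 12L)  # 2 x 2 x 3 design

  # planted group main effect: children above adults, sign recovered
  d2 <- simulate_lmm_trials(c(child = 20, adolescent = 20, adult = 20),
                            beta = c(intercept = 0.5),
                            group_effects = list(child = 0.25),
                            sigma_b = 0.1, seed = 14)
  f2 <- fit_group_lmm(d2, "acquisition", reference_group = "child")
  co <- f2$coefficients
  expect_lt(co$estimate[co$term == "groupadult"], 0)
  expect_lt(co$p[co$term == "groupadult"], 0.05)

  expect_error(fit_group_lmm(d[, setdiff(names(d), "group")], "acquisition"),
               "group")
})

test_that("retention differential scores follow the first-two-trial rule", {
  mk <- function(subject, plus, minus) {
    data.frame(subject = subject, group = "child", phase = "retention",
               trial_type = rep(c("CS+", "CS-"), each = length(plus)),
               trial_index = rep(seq_along(plus), 2),
               scr_sqrt = c(plus, minus))
  }
  d <- rbind(mk("s1", c(0.3, 0.5), c(0.1, 0.1)),
             mk("s2", c(0.2, 0.2), c(0.2, 0.2)),
             mk("s3", c(0.4, NA), c(0.1, 0.2)))
  sc <- suppressMessages(retention_scores(d))
  expect_equal(sc$early_diff[sc$subject == "s1"], 0.3)
  expect_equal(sc$early_diff[sc$subject == "s2"], 0)
  expect_true(is.na(sc$early_diff[sc$subject == "s3"]))

  sc2 <- retention_scores(d, require_complete = FALSE)
  expect_equal(sc2$early_diff[sc2$subject == "s3"], 0.4 - 0.15)

  # trials beyond index 2 are ignored
  d4 <- mk("s4", c(0.3, 0.5, 9, 9), c(0.1, 0.1, 9, 9))
  d4 <- d4[d4$trial_index <= 4, ]
  sc4 <- retention_scores(rbind(d, d4)[rbind(d, d4)$subject == "s4", ])
  expect_equal(sc4$early_diff, 0.3)
})

test_that("retention group regression reports coefficients and overall F", {
  set.seed(21)
  sc <- data.frame(subject = sprintf("s%03d", 1:90),
                   group = rep(c("child", "adolescent", "adult"), each = 30),
                   early_diff = rnorm(90, 0.1, 0.2))
  fit <- retention_group_test(sc)
  expect_equal(fit$coefficients$term,
               c("(Intercept)", "groupchild", "groupadult"))
  expect_equal(fit$extra$f_test$df1, 2)
  expect_equal(fit$extra$f_test$df2, 87)
  expect_true(fit$extra$f_test$p > 0 && fit$extra$f_test$p <= 1)
})

test_that("null retention cohorts give uniform group-test p-values", {
  set.seed(22)
  pvals <- replicate(400, {
    sc <- data.frame(subject = sprintf("s%03d", 1:60),
                     group = rep(c("child", "adolescent", "adult"), 20),
                     early_diff = rnorm(60, 0, 0.2))
    retention_group_test(sc)$extra$f_test$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("US habituation model recovers a planted trial slope", {
  mk_us <- function(n_sub, slope, seed) {
    set.seed(seed)
    rows <- lapply(seq_len(n_sub), function(i) {
      b <- rnorm(1, 0, 0.2)
      data.frame(subject = sprintf("s%03d", i),
                 group = c("child", "adolescent", "adult")[1 + i %% 3],
                 phase = "acquisition", trial_type = "US", trial_index = 1:8,
                 scr_sqrt = 1 + slope * (1:8) + b + rnorm(8, 0, 0.25))
    })
    do.call(rbind, rows)
  }
  d <- mk_us(120, -0.05, 31)
  fit <- fit_us_habituation(d)
  est <- fit$coefficients
  expect_lt(est$estimate[est$term == "trial"], 0)
  expect_lt(est$p[est$term == "trial"], 0.05)

  # zero planted slope: estimate centred near zero
  ests <- vapply(1:30, function(s) {
    f <- fit_us_habituation(mk_us(40, 0, 100 + s))
    f$coefficients$estimate[f$coefficients$term == "trial"]
  }, numeric(1))
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(length(ests)) + 0.003)

  # degenerate input: one trial per subject
  d1 <- mk_us(10, 0, 1)
  expect_error(fit_us_habituation(d1[d1$trial_index == 1, ]), "at least 2")
})

test_that("contingency awareness implements the (yes, no) rule", {
  expect_true(contingency_aware(TRUE, FALSE))
  expect_false(contingency_aware(TRUE, TRUE))
  expect_false(contingency_aware(FALSE, FALSE))
  expect_false(contingency_aware(FALSE, TRUE))
  expect_true(is.na(contingency_aware(NA, FALSE)))
  expect_equal(contingency_aware(c(TRUE, TRUE), c(FALSE, TRUE)),
               c(TRUE, FALSE))
})

test_that("CLMM with zero variance matches the proportional-odds oracle", {
  set.seed(51)
  n <- 240
  d <- data.frame(subject = rep(sprintf("s%02d", 1:40), each = 6),
                  cs = rep(c("CS-", "CS+"), 120),
                  phase = rep(c("pre", "acquisition", "extinction"), 80))
  eta <- 1.2 * (d$cs == "CS+") + 0.4 * (d$phase == "extinction")
  u <- runif(n)
  cum <- sapply(c(-0.5, 0.6, 1.6, 2.6), function(t) plogis(t - eta))
  d$rating <- 1L + rowSums(u > cum)
  d$cs <- factor(d$cs, levels = c("CS-", "CS+"))
  d$phase <- factor(d$phase, levels = c("acquisition", "pre", "extinction"))

  ours <- fit_clmm(rating ~ cs + phase, d, sigma_fixed = 0)
  oracle <- MASS::polr(factor(rating, levels = 1:5) ~ cs + phase, data = d,
                       Hess = TRUE)
  expect_equal(unname(ours$coefficients$estimate), unname(coef(oracle)),
               tolerance = 1e-3)
  expect_equal(unname(ours$extra$thresholds), unname(oracle$zeta),
               tolerance = 1e-3)
  expect_equal(ours$extra$logLik, as.numeric(logLik(oracle)),
               tolerance = 1e-6)
})

test_that("CLMM recovers generative parameters with a random intercept", {
  rm_ <- rating_model()
  set.seed(61)
  reps <- 12
  est_cs <- numeric(reps)
  sigma_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    rows <- do.call(rbind, lapply(1:80, function(i) {
      sp <- subject_spec(sprintf("s%03d", i), "adolescent")
      simulate_ratings(sp, rm_, rnorm(1, 0, rm_$subject_sd))
    }))
    f <- fit_ratings_clmm(rows, nodes = 9)
    est_cs[r] <- f$coefficients$estimate[f$coefficients$term == "csCS+"]
    sigma_hat[r] <- f$varcomp$subject_sd
  }
  truth <- rm_$beta_cs + rm_$beta_cs_acq  # CS+ effect at acquisition
  mc_se <- sd(est_cs) / sqrt(reps)
  expect_lt(abs(mean(est_cs) - truth), 2 * mc_se + 0.05)
  expect_lt(abs(mean(sigma_hat) - rm_$subject_sd), 0.3)
})

test_that("CLMM rejects degenerate one-category outcomes", {
  d <- data.frame(subject = rep(c("a", "b"), each = 3),
                  cs = factor(rep(c("CS-", "CS+"), 3)),
                  rating = rep(1L, 6))
  expect_error(fit_clmm(rating ~ cs, d), "single observed category")
})

test_that("sensitivity suite refits, filters and tabulates stability", {
  d <- simulate_lmm_trials(c(child = 8, adolescent = 8, adult = 8),
                           beta = c(intercept = 0.5, cs = 0.2), seed = 71)
  md <- unique(d[, c("subject", "group")])
  set.seed(72)
  md$ses <- rnorm(nrow(md), 7, 1.5)
  md$us_sound_level <- rnorm(nrow(md), 40, 10)
  md$days_between_sessions <- sample(1:10, nrow(md), TRUE)
  md$aware <- rep(c(TRUE, FALSE), c(nrow(md) - 6, 6))
  d <- merge(d, md[, setdiff(names(md), "group")], by = "subject")
  d_ret <- transform(d, phase = "retention")
  d_all <- rbind(d, d_ret)

  out <- sensitivity_suite(d_all, phases = c("acquisition", "retention"))
  expect_true(all(c("acquisition_base", "acquisition_ses",
                    "acquisition_aware_only", "retention_days_between_sessions")
                  %in% names(out$fits)))
  # awareness filter drops exactly the unaware subjects
  expect_equal(out$fits$acquisition_base$n_subjects -
                 out$fits$acquisition_aware_only$n_subjects, 6L)
  # a covariate orthogonal to the outcome leaves the CS estimate stable
  cmp <- out$comparison
  cs_rows <- cmp[cmp$term == "csCS+" & cmp$phase == "acquisition", ]
  base_cs <- out$fits$acquisition_base$coefficients
  base_est <- base_cs$estimate[base_cs$term == "csCS+"]
  base_se <- base_cs$se[base_cs$term == "csCS+"]
  expect_true(all(abs(cs_rows$estimate - base_est) < 2 * base_se))
  expect_true(all(cs_rows$sign_stable))

  # constant covariate is dropped with a warning
  d_const <- transform(d_all, ses = 1)
  expect_warning(sensitivity_suite(d_const, phases = "acquisition"), "ses")
})

test_that("awareness rates in the generated cohort match the configured ones", {
  co <- simulate_cohort(99, group_params = local({
    gp <- default_group_params()
    for (g in names(gp)) gp[[g]]$n <- 40L
    gp
  }))
  ct <- co$contingency
  aware <- contingency_aware(ct$cs_plus_screamed, ct$cs_minus_screamed)
  md <- cohort_metadata(co)
  # classification agrees with the generator's awareness flag
  expect_equal(aware, md$aware[match(ct$subject, md$subject)])
  # binomial check against configured probabilities
  for (g in c("child", "adolescent", "adult")) {
    p_cfg <- default_group_params()[[g]]$p_aware
    obs <- mean(aware[ct$group == g])
    expect_lt(abs(obs - p_cfg), 3 * sqrt(p_cfg * (1 - p_cfg) / 40))
  }
})
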