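# Trajectory fitting: OLS oracles, AICc selection, positivity and
# leave-one-out screens, classification, peak ages, motion regression.

test_that("per-connection OLS matches the normal-equations oracle", {
  coh <- small_cohort(30, seed = 21)
  fx <- small_features(coh, m = 25, seed = 22)
  fits <- fit_trajectories(fx$features, coh)
  Y <- collapse_scans(fx$features, coh$subject_id)
  Xl <- cbind(1, coh$age, coh$sex, coh$center)
  Xq <- cbind(1, coh$age, coh$age^2, coh$sex, coh$center)
  for (j in seq_len(ncol(Y))) {
    ol <- ols_oracle(Xl, Y[, j])
    oq <- ols_oracle(Xq, Y[, j])
    expect_lt(abs(fits$lin_beta_age[j] - ol$beta[2]), 1e-8)
    expect_lt(abs(fits$lin_t_age[j] - ol$t[2]), 1e-8)
    expect_lt(abs(fits$quad_beta_age2[j] - oq$beta[3]), 1e-8)
    expect_lt(abs(fits$quad_t_age2[j] - oq$t[3]), 1e-8)
  }
  # statistics agree with stats::lm as an independent reference
  ref <- summary(lm(Y[, 1] ~ coh$age + I(coh$age^2) + coh$sex + coh$center))
  expect_equal(fits$quad_t_age2[1], ref$coefficients["I(coh$age^2)", 3],
               tolerance = 1e-10)
  expect_equal(fits$quad_p_age2[1], ref$coefficients["I(coh$age^2)", 4],
               tolerance = 1e-10)
  # AICc equals the closed-form correction of stats::AIC
  fit_lm <- lm(Y[, 1] ~ coh$age + coh$sex + coh$center)
  k <- 5                                   # 4 coefficients + variance
  n <- nrow(Y)
  expect_equal(fits$lin_aic[1],
               AIC(fit_lm) + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-8)
})

test_that("model selection recovers strongly planted shapes", {
  coh <- generate_cohort(137, seed = 23)
  fx <- small_features(coh, m = 120, seed = 24)
  fits <- fit_trajectories(fx$features, coh)
  lin <- fx$spec$class %in% c("pos_linear", "neg_linear")
  quad <- fx$spec$class %in% c("pos_quad", "neg_quad")
  # age terms are overwhelmingly significant where planted
  expect_gt(mean(fits$lin_p_age[lin] < 1e-4), 0.9)
  expect_gt(mean(fits$quad_p_age2[quad] < 1e-4), 0.9)
  # quadratic-true connections essentially always select quadratic
  expect_gt(mean(fits$best_model[quad] == "quadratic"), 0.95)
  expect_error(fit_trajectories(fx$features, coh[1:4, ]), "subjects")
})

test_that("null-connection age p-values are uniform (type-I calibration)", {
  # single scan per subject: the collapsed design is homoscedastic, so the
  # null age-term p-values must be exactly uniform (scan averaging halves
  # the residual variance of two-scan subjects and would blur this)
  coh <- generate_cohort(137, seed = 25)
  coh$n_scans <- 1L
  spec <- plant_trajectories(1000, c(0, 0, 0, 0, 1), seed = 26)
  feat <- generate_feature_matrix(coh, spec, seed = 27)
  fits <- fit_trajectories(feat, coh)
  ks <- suppressWarnings(ks.test(fits$lin_p_age, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(ks.test(fits$quad_p_age2, "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("positivity screen follows the one-sided t-test", {
  set.seed(28)
  n <- 50
  pos <- 0.5 + rnorm(n, 0, 0.01)
  sym <- rnorm(n, 0, 0.3)
  Y <- cbind(pos, sym)
  rownames(Y) <- paste0("s", seq_len(n))
  mask <- positivity_filter(Y, alpha = 0.001)
  expect_true(mask[1])
  expect_false(mask[2])
  # borderline decision matches a direct t CDF evaluation
  set.seed(29)
  for (shift in c(0.04, 0.06)) {
    x <- scale(rnorm(n))[, 1] * 0.1 + shift
    tstat <- mean(x) / (sd(x) / sqrt(n))
    expect_equal(unname(positivity_filter(matrix(x), alpha = 0.001)),
                 pt(tstat, n - 1, lower.tail = FALSE) < 0.001)
  }
  # zero-variance columns pass iff positive
  expect_warning(zv <- positivity_filter(cbind(rep(0.2, 10), rep(-0.2, 10))),
                 "zero-variance")
  expect_equal(unname(zv), c(TRUE, FALSE))
})

test_that("leave-one-out selection separates planted from null connections", {
  coh <- generate_cohort(137, seed = 30)
  fx <- small_features(coh, m = 80, seed = 31)
  sel <- loo_robust_selection(fx$features, coh)
  planted <- fx$spec$class != "null"
  expect_gt(mean(sel$loo_pass[planted]), 0.8)
  expect_true(all(!sel$loo_pass[!planted]))
  # permutation invariance to subject ordering
  perm <- sample(nrow(coh))
  coh2 <- coh[perm, ]
  sel2 <- loo_robust_selection(fx$features, coh2)
  expect_equal(sel2$loo_pass, sel$loo_pass)
  expect_equal(sel2$max_loo_p, sel$max_loo_p, tolerance = 1e-10)
  coh6 <- generate_cohort(6, seed = 42)
  fx6 <- small_features(coh6, m = 5, seed = 43)
  expect_error(loo_robust_selection(fx6$features, coh6), "insufficient")
})

test_that("combined selection keeps the null false-positive rate tiny", {
  # conservative bound: empirical rate on simulated nulls <= 5 * alpha
  coh <- generate_cohort(137, seed = 32)
  spec <- plant_trajectories(10000, c(0, 0, 0, 0, 1), seed = 33)
  feat <- generate_feature_matrix(coh, spec, seed = 34)
  sel <- loo_robust_selection(feat, coh, alpha = 1e-4)
  expect_lte(mean(sel$loo_pass), 5e-4)
})

test_that("peak ages follow the vertex formula and classes the sign rules", {
  expect_equal(peak_age(8, -0.1), 40)
  expect_equal(peak_age(-6.8, 0.1), 34)
  expect_error(peak_age(1, 0), "undefined")
  expect_warning(peak_age(8, -0.1, age_range = c(8, 30)), "outside")
  coh <- generate_cohort(137, seed = 35)
  fx <- small_features(coh, m = 150, seed = 36)
  fits <- fit_trajectories(fx$features, coh)
  sel <- loo_robust_selection(fx$features, coh, fits = fits)
  cls <- classify_trajectories(fits, sel)
  # recovered labels never flip shape within the selected set
  hit <- cls$class != "none"
  agree <- cls$class[hit] == fx$spec$class[hit]
  flip <- mapply(function(a, b) {
    (a %in% c("pos_quad", "neg_quad")) == (b %in% c("pos_quad", "neg_quad"))
  }, cls$class[hit], fx$spec$class[hit])
  expect_true(all(agree | !flip | !hit[hit]))  # sign errors absent
  expect_true(all(sign(cls$quad_beta_age2[cls$class == "neg_quad"]) == -1))
  expect_true(all(sign(cls$lin_beta_age[cls$class == "pos_linear"]) == 1))
  # failing selection maps to none
  expect_true(all(cls$class[!sel$loo_pass] == "none"))
  # peak ages recovered near the planted values for quadratic classes
  q <- cls$class %in% c("pos_quad", "neg_quad") &
    fx$spec$class %in% c("pos_quad", "neg_quad")
  expect_lt(median(abs(cls$peak_age[q] - fx$spec$peak_age[q])), 3)
  summ <- peak_age_summary(cls)
  expect_equal(summ$class, c("pos_quad", "neg_quad"))
  expect_true(all(summ$mean > 30 & summ$mean < 50, na.rm = TRUE))
})

test_that("motion regression removes exactly the motion-spanned variance", {
  coh <- small_cohort(40, seed = 37)
  set.seed(38)
  fd <- coh$mean_fd
  # a column that is an exact linear function of motion vanishes
  exact <- 0.3 + 2 * fd
  indep <- rnorm(40)
  Y <- cbind(exact, indep)
  rownames(Y) <- coh$subject_id
  res <- regress_motion(Y, fd)
  expect_lt(max(abs(res[, 1])), 1e-10)
  expect_equal(unname(res[, 2]), indep - mean(indep) -
                 cov(indep, fd) / var(fd) * (fd - mean(fd)),
               tolerance = 1e-10)
  expect_lt(abs(sum(res[, 2] * fd)), 1e-8)
  expect_warning(regress_motion(Y, rep(0.2, 40)), "constant")
  # age effects survive motion regression when planted strongly
  coh2 <- generate_cohort(137, seed = 39)
  fx <- small_features(coh2, m = 40, seed = 40, effect_scale = 10)
  mixed <- fx$features
  mixed$values <- mixed$values +
    0.5 * coh2$mean_fd[match(mixed$subject_id, coh2$subject_id)]
  clean <- regress_motion(mixed, cohort = coh2)
  fits_pre <- fit_trajectories(mixed, coh2)
  fits_post <- fit_trajectories(clean, coh2)
  lin <- fx$spec$class %in% c("pos_linear", "neg_linear")
  expect_lt(mean(abs(fits_post$lin_t_age[lin])),
            mean(abs(fits_pre$lin_t_age[lin])) + 1)  # attenuated or equal
  expect_true(all(fits_post$lin_p_age[lin] < 0.001))
})

test_that("degenerate designs are rejected with the offending column named", {
  coh <- small_cohort(20, seed = 41)
  coh$age <- 25                            # constant age
  Y <- matrix(rnorm(20), 20, 1)
  rownames(Y) <- coh$subject_id
  expect_error(fit_trajectories(Y, coh), "collinear")
})
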