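# Age regression: ridge/kernel-ridge solvers, LASVR local adjustment,
# error metrics, and the leave-one-out cross-validation engine.

test_that("linear SVR interpolates at large C and shrinks to the mean at
           small C", {
  z <- seq(0, 1, length.out = 12)
  ages <- 10 + 50 * z
  Z <- matrix(z)
  big <- svr_fit(Z, ages, svr_spec("linear_svr", C = 1e8))
  expect_lt(max(abs(predict(big, Z) - ages)), 1e-6)
  tiny <- svr_fit(Z, ages, svr_spec("linear_svr", C = 1e-9))
  expect_lt(max(abs(predict(tiny, Z) - mean(ages))), 1e-3)
  expect_warning(svr_fit(Z, rep(30, 12), svr_spec("linear_svr")),
                 "all training ages equal")
  expect_error(svr_spec("linear_svr", C = 0), "positive")
})

test_that("ridge solution matches the closed-form normal equations", {
  set.seed(71)
  Z <- matrix(rnorm(5), 5, 1)
  ages <- 30 + 8 * Z[, 1] + rnorm(5, 0, 0.5)
  C <- 0.7
  fit <- svr_fit(Z, ages, svr_spec("linear_svr", C = C))
  oracle <- ridge_oracle(Z, ages, lambda = 1 / (2 * C))
  Znew <- matrix(seq(-2, 2, length.out = 9))
  expect_equal(predict(fit, Znew), oracle(Znew), tolerance = 1e-10)
})

test_that("RBF SVR is exact on training data at large C and is smooth", {
  set.seed(72)
  Z <- matrix(seq(-1, 1, length.out = 15), ncol = 1)
  ages <- 40 + 20 * sin(2 * Z[, 1])
  fit <- svr_fit(Z, ages, svr_spec("rbf_svr", C = 1e5, sigma = 1))
  expect_lt(max(abs(predict(fit, Z) - ages)), 0.05)
  # interpolates reasonably between knots
  mid <- matrix(0.5 * (Z[3, 1] + Z[4, 1]))
  expect_lt(abs(predict(fit, mid) - (40 + 20 * sin(2 * mid[1, 1]))), 1)
})

test_that("LASVR reduces to the global model for wide windows and falls
           back for empty ones", {
  set.seed(73)
  Z <- matrix(rnorm(40), 20, 2)
  ages <- runif(20, 8, 79)
  span <- diff(range(ages))
  glob <- svr_fit(Z, ages, svr_spec("linear_svr", C = 0.1))
  las <- svr_fit(Z, ages, svr_spec("lasvr", C = 0.1, delta = span + 10))
  Znew <- matrix(rnorm(10), 5, 2)
  expect_lt(max(abs(predict(las, Znew) - predict(glob, Znew))), 1e-8)
  # tiny window: global prediction returned with the fallback flag
  las0 <- svr_fit(Z, ages, svr_spec("lasvr", C = 0.1, delta = 1e-6))
  out <- predict(las0, Znew, fallback = TRUE)
  expect_true(all(out$fallback))
  expect_equal(out$pred, predict(glob, Znew), tolerance = 1e-10)
})

test_that("LASVR beats the global fit on a planted piecewise-linear map", {
  # two linear regimes with a kink; local windows capture single regimes
  set.seed(74)
  n <- 200
  z <- runif(n, -1, 1)
  age_of <- function(z) ifelse(z < 0, 44 + 36 * z, 44 + 70 * z)
  ages <- age_of(z)
  Z <- cbind(z, matrix(rnorm(n * 3, 0, 0.05), n, 3))
  tr <- 1:150
  te <- 151:200
  glob <- svr_fit(Z[tr, ], ages[tr], svr_spec("linear_svr", C = 10))
  las <- svr_fit(Z[tr, ], ages[tr], svr_spec("lasvr", C = 10, delta = 8))
  err_g <- abs(predict(glob, Z[te, ]) - ages[te])
  err_l <- abs(predict(las, Z[te, ]) - ages[te])
  expect_lt(mean(err_l), mean(err_g))
})

test_that("error metrics match their definitions", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(15, 0, 25), c(10, 10, 10)), 10)
  set.seed(75)
  p <- rnorm(50)
  y <- rnorm(50)
  acc <- 0
  for (i in 1:50) acc <- acc + abs(p[i] - y[i])
  expect_equal(mae(p, y), acc / 50)
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
  # cumulative scores: monotone, capped, and 100% at the max error
  err <- abs(p - y)
  cs <- cumulative_score(p, y, c(0, 0.5, 1, max(err)))
  expect_true(all(diff(cs) >= 0))
  expect_equal(cs[4], 100)
  expect_equal(cumulative_score(p, y, 0), 100 * mean(err <= 0))
  expect_error(cumulative_score(p, y, -1), "non-negative")
})

test_that("LOOCV reports satisfy the MAE and CS identities", {
  coh <- small_cohort(25, seed = 76)
  fx <- small_features(coh, m = 40, seed = 77)
  rep <- loocv_predict(fx$features, coh, d = 2,
                       spec = svr_spec("linear_svr", C = 0.1), k = 5)
  expect_s3_class(rep, "fc_prediction_report")
  expect_equal(rep$mae, mean(rep$subjects$abs_error))
  expect_equal(unname(rep$cs),
               unname(cumulative_score(rep$subjects$predicted,
                                       rep$subjects$age, c(5, 10, 20))))
  expect_true(all(diff(rep$cs) >= 0))
  # the baseline equals the directly computed age-deviation benchmark
  manual <- sapply(seq_len(nrow(coh)), function(i)
    abs(mean(coh$age[-i]) - coh$age[i]))
  expect_equal(rep$baseline_mae, mean(manual))
})

test_that("LOOCV is order-invariant and leaks no label information", {
  coh <- small_cohort(20, seed = 78)
  fx <- small_features(coh, m = 30, seed = 79)
  rep <- loocv_predict(fx$features, coh, d = 2,
                       spec = svr_spec("linear_svr", C = 0.1), k = 5)
  # permuting subject order leaves per-subject predictions unchanged
  perm <- sample(nrow(coh))
  rep2 <- loocv_predict(fx$features, coh[perm, ], d = 2,
                        spec = svr_spec("linear_svr", C = 0.1), k = 5)
  m1 <- rep$subjects[order(rep$subjects$subject_id), ]
  m2 <- rep2$subjects[order(rep2$subjects$subject_id), ]
  expect_equal(m2$predicted, m1$predicted, tolerance = 1e-8)
  # replacing the held-out subject's age label changes nothing for them
  coh3 <- coh
  coh3$age[5] <- 999
  rep3 <- loocv_predict(fx$features, coh3, d = 2,
                        spec = svr_spec("linear_svr", C = 0.1), k = 5)
  expect_equal(rep3$subjects$predicted[5], rep$subjects$predicted[5],
               tolerance = 1e-10)
})

test_that("multi-scan subjects get averaged predictions in one fold", {
  coh <- small_cohort(20, seed = 80)
  expect_gt(sum(coh$n_scans == 2), 0)
  fx <- small_features(coh, m = 30, seed = 81)
  rep <- loocv_predict(fx$features, coh, d = 2,
                       spec = svr_spec("linear_svr", C = 0.1), k = 5)
  expect_equal(nrow(rep$subjects), nrow(coh))   # one row per subject
  expect_true(all(is.finite(rep$subjects$predicted)))
})

test_that("the sweep enumerates the grid and matches single calls", {
  coh <- small_cohort(22, seed = 82)
  fx <- small_features(coh, m = 30, seed = 83)
  sw <- sweep_parameters(fx$features, coh, d = c(2, 3),
                         specs = list(svr_spec("linear_svr", C = 0.1),
                                      svr_spec("lasvr", C = 0.1,
                                               delta = 8)),
                         k = 5)
  expect_equal(nrow(sw), 4)                      # 2 specs x 2 dims
  single <- loocv_predict(fx$features, coh, d = 2,
                          spec = svr_spec("linear_svr", C = 0.1), k = 5)
  expect_equal(sw$mae[sw$method == "linear_svr" & sw$d == 2], single$mae,
               tolerance = 1e-10)
  best <- best_by_method(sw)
  expect_equal(sort(rownames(best)), c("lasvr(8)", "linear_svr"))
  expect_true(all(best$mae <= tapply(sw$mae, sw$method, max)))
})
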