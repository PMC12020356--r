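test_that("min-max scaling follows the formula and inverts exactly", {
  d <- tibble::tibble(a = c(2, 4, 6), b = c(-1, 0, 3))
  bounds <- fit_minmax(d, c("a", "b"))
  scaled <- apply_minmax(d, bounds)
  expect_equal(scaled$a, c(0, 0.5, 1))
  back <- invert_minmax(scaled, bounds)
  expect_equal(back$a, d$a, tolerance = 1e-14)
  expect_equal(back$b, d$b, tolerance = 1e-14)
  # constant column is refused by name
  expect_error(fit_minmax(tibble::tibble(a = c(1, 1), b = 1:2), c("a", "b")),
               "a")
  # out-of-bounds values scale outside [0,1] with a warning, passed through
  expect_warning(out <- apply_minmax(tibble::tibble(a = 8, b = 0), bounds),
                 "outside")
  expect_equal(out$a, 1.5)
})

test_that("holdout split is disjoint, exhaustive and seed-stable", {
  d <- tibble::tibble(x = 1:100)
  parts <- split_holdout(d, fraction = 0.2, seed = 3)
  expect_equal(nrow(parts$train), 80)
  expect_equal(nrow(parts$test), 20)
  expect_length(intersect(parts$train$x, parts$test$x), 0)
  expect_setequal(c(parts$train$x, parts$test$x), 1:100)
  again <- split_holdout(d, fraction = 0.2, seed = 3)
  expect_identical(again$test$x, parts$test$x)
  # floor rule at the compiled-dataset scale
  parts2 <- split_holdout(tibble::tibble(x = 1:1227), 0.2, seed = 1)
  expect_equal(nrow(parts2$train), 982)
  expect_equal(nrow(parts2$test), 245)
  expect_error(split_holdout(d, fraction = 1.2), "fraction")
})

test_that("feature assembly speciates at the entry pH", {
  reg <- pfas_registry()
  entries <- tibble::tibble(
    entry_id = c("a", "b", "c", "d"),
    compound_id = c("ftoh_6_2", "tfa", "pfosa", "pfosa"),
    ph = c(5, 7, 3, 8), cec = 10, corg = 2,
    sand = 40, silt = 40, clay = 20, kd = c(1, 1, 1, 1)
  )
  f <- assemble_features(entries, reg)
  expect_named(f, c("entry_id", "compound_id", pssm_features(), "log_kd"),
               ignore.order = TRUE)
  expect_equal(f$charge_density[1], 0)                   # neutral FTOH
  expect_equal(round(f$charge_density[2]), -854)         # TFA anion
  # pKa ~ 6 compound: speciation differs strongly between pH 3 and 8
  expect_lt(abs(f$charge_density[3]), 1)
  expect_lt(f$charge_density[4], -150)
  expect_error(assemble_features(dplyr::mutate(entries,
                                               compound_id = "zzz"), reg),
               "not in registry")
  expect_error(assemble_features(dplyr::mutate(entries, cec = NA), reg),
               "impute")
})

test_that("closed-form ridge minimizes the penalized least-squares objective", {
  set.seed(40)
  X <- matrix(runif(120), 30, 4)
  y <- X %*% c(2, -1, 0.5, 0) + rnorm(30, 0, 0.1)
  alpha <- 1.0
  beta <- pfasorption:::fit_ridge(X, y, alpha)
  obj <- function(b) sum((y - cbind(1, X) %*% b)^2) + alpha * sum(b[-1]^2)
  num <- optim(rep(0, 5), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(beta), num$par, tolerance = 1e-5)
  expect_lte(obj(beta), num$value + 1e-8)
})

test_that("stacking fit is deterministic and reproducible end to end", {
  d <- gen_sorption_dataset(220, seed = 55)
  f <- assemble_features(d)
  m1 <- pssm_fit(f[1:160, ], seed = 9, config = fast_config())
  m2 <- pssm_fit(f[1:160, ], seed = 9, config = fast_config())
  p1 <- predict(m1, f[161:220, ])
  p2 <- predict(m2, f[161:220, ])
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)))
  # batch of one equals the row of a batch
  expect_equal(predict(m1, f[161, ]), p1[1])
})

test_that("constant targets yield constant predictions", {
  d <- gen_sorption_dataset(120, seed = 56)
  f <- assemble_features(d)
  f$log_kd <- 1.7
  m <- pssm_fit(f, seed = 2, config = fast_config())
  p <- predict(m, f[1:30, ])
  expect_equal(p, rep(1.7, 30), tolerance = 1e-2)
})

test_that("noise-free synthetic data is recovered almost perfectly", {
  d <- gen_sorption_dataset(400, seed = 57, effect = effect_spec(sigma = 0))
  f <- assemble_features(d)
  run <- pssm_pipeline(f, seed = 57)
  expect_gt(run$evaluation$rpd, 3)
  expect_lt(run$evaluation$nrmse, 0.05)
})

test_that("predictions rise with log Kow at fixed soil on monotone data", {
  d <- gen_sorption_dataset(300, seed = 58)
  f <- assemble_features(d)
  m <- pssm_fit(f, seed = 58, config = fast_config())
  probe <- f[rep(1, 7), ]
  probe$log_kow <- seq(1, 7, by = 1)
  p <- predict(m, probe)
  # hydrophobicity raises predicted sorption at fixed soil; the trend is
  # noisy pointwise because correlated compound descriptors stay fixed
  expect_gt(cor(probe$log_kow, p), 0.5)
  expect_gt(p[7], p[1])
})

test_that("predict_kd flags out-of-domain rows but still predicts", {
  d <- gen_sorption_dataset(150, seed = 59)
  f <- assemble_features(d)
  m <- pssm_fit(f, seed = 59, config = fast_config())
  probe <- f[1:2, ]
  probe$corg[2] <- max(f$corg) * 3
  out <- predict_kd(m, probe)
  expect_false(out$.out_of_domain[1])
  expect_true(out$.out_of_domain[2])
  expect_true(all(is.finite(out$.pred_log_kd)))
  expect_equal(out$.pred_kd, 10^out$.pred_log_kd)
})

test_that("meta-model training data leaks no target information", {
  # out-of-fold stacking: shuffling the *test* labels must not improve
  # test NRMSE relative to the true labels (systematically)
  d <- gen_sorption_dataset(260, seed = 60)
  f <- assemble_features(d)
  run <- pssm_pipeline(f, seed = 60, config = fast_config())
  true_nrmse <- run$evaluation$nrmse
  set.seed(61)
  shuffled <- vapply(1:5, function(i) {
    y <- sample(run$split$test$log_kd)
    evaluate_predictions(y, predict(run$model, run$split$test))$nrmse
  }, numeric(1))
  expect_true(all(shuffled > true_nrmse))
})

test_that("model bundle round-trips through disk", {
  d <- gen_sorption_dataset(150, seed = 62)
  f <- assemble_features(d)
  m <- pssm_fit(f, seed = 3, config = fast_config())
  dir <- withr::local_tempdir()
  write_pssm_model(m, dir)
  m2 <- read_pssm_model(dir)
  expect_equal(predict(m2, f[1:20, ]), predict(m, f[1:20, ]))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("tidy and glance expose the ensemble structure", {
  d <- gen_sorption_dataset(120, seed = 63)
  f <- assemble_features(d)
  m <- pssm_fit(f, seed = 4, config = fast_config())
  td <- tidy(m)
  expect_equal(td$learner,
               c("ridge", "random_forest", "extra_trees",
                 "gradient_boosting", "mlp_meta"))
  gl <- glance(m)
  expect_equal(gl$n_train, 120)
  expect_true(gl$stack_oof)
})

test_that("ablating a pure-noise feature is harmless; the informative one is not", {
  d <- gen_sorption_dataset(500, seed = 64)
  f <- assemble_features(d)
  set.seed(640)
  f$noise <- rnorm(nrow(f))  # pure-noise control feature
  with_noise <- c(pssm_features(), "noise")
  ref <- pssm_pipeline(f, seed = 64, features = with_noise)
  no_noise <- pssm_ablate(f, "noise", seed = 64, features = with_noise)
  expect_lt(abs(no_noise$evaluation$nrmse - ref$evaluation$nrmse), 0.01)
  # identical split under the shared seed
  expect_equal(no_noise$split$test$entry_id, ref$split$test$entry_id)

  # dataset where hydrophobicity is the only informative feature among
  # the ones offered: dropping it leaves nothing to learn
  d2 <- gen_sorption_dataset(500, seed = 65,
                             effect = effect_spec(b_corg = 0, b_cd = 0,
                                                  b_ph = 0))
  f2 <- assemble_features(d2)
  feats2 <- c("log_kow", "ph", "cec", "sand", "silt", "clay")
  kept <- pssm_pipeline(f2, seed = 65, features = feats2)
  dropped <- pssm_ablate(f2, "log_kow", seed = 65, features = feats2)
  expect_gt(kept$evaluation$rpd, 2)
  expect_lt(dropped$evaluation$rpd, 1.5)
  expect_gt(dropped$evaluation$nrmse, kept$evaluation$nrmse)
  expect_error(pssm_ablate(f, "zeta", seed = 1), "unknown feature")
})

test_that("cross-validation reports a fold-wise NRMSE table", {
  d <- gen_sorption_dataset(240, seed = 65)
  f <- assemble_features(d)
  cv <- cross_validate(f, k = 3, seed = 65, config = fast_config())
  expect_equal(nrow(cv), 3)
  expect_equal(sum(cv$n), 240)
  expect_true(all(cv$nrmse > 0))
  expect_equal(attr(cv, "cv_nrmse"), mean(cv$nrmse))
})
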