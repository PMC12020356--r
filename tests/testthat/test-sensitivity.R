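predict_linear <- function(model, data) {
  as.vector(as.matrix(data[, names(model$w)]) %*% model$w + model$b)
}

test_that("a constant model gets zero attributions everywhere", {
  const <- list(w = c(x1 = 0, x2 = 0), b = 3)
  bg <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
  s <- tibble::tibble(x1 = c(1, -2), x2 = c(0, 5))
  sh <- shapley_exact(const, s, bg, features = c("x1", "x2"),
                      predict_fn = predict_linear)
  expect_equal(sh$phi, rep(0, 4))
  expect_equal(attr(sh, "base_value"), 3)
  pd <- partial_dependence(const, bg, "x1", predict_fn = predict_linear)
  expect_equal(pd$pd, rep(3, 20))
})

test_that("linear models reproduce the closed-form attribution", {
  set.seed(70)
  w <- c(a = 2, b = -1.5, c = 0.7, d = 0)
  lin <- list(w = w, b = 1)
  bg <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(200), 50, 4)), names(w)))
  s <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(12), 3, 4)), names(w)))
  sh <- shapley_exact(lin, s, bg, features = names(w),
                      predict_fn = predict_linear)
  wide <- tidyr::pivot_wider(sh, names_from = "feature",
                             values_from = "phi")
  for (i in 1:3) {
    expected <- w * (unlist(s[i, ]) - colMeans(bg))
    expect_equal(unlist(wide[i, names(w)]), expected, tolerance = 1e-6)
  }
  # the dummy feature (zero weight) gets exactly zero
  expect_equal(sh$phi[sh$feature == "d"], rep(0, 3))
})

test_that("local accuracy holds for every sample on a 9-feature model", {
  set.seed(71)
  feats <- paste0("f", 1:9)
  w <- stats::setNames(rnorm(9), feats)
  nonlin <- list(w = w, b = 0.5)
  pf <- function(m, d) {
    x <- as.matrix(d[, names(m$w)])
    as.vector(x %*% m$w + 0.8 * x[, 1] * x[, 2] + sin(x[, 3]) + m$b)
  }
  bg <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(9 * 25), 25, 9)), feats))
  s <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(rnorm(9 * 4), 4, 9)), feats))
  sh <- shapley_exact(nonlin, s, bg, features = feats, predict_fn = pf)
  wide <- tidyr::pivot_wider(sh, names_from = "feature",
                             values_from = "phi")
  total <- rowSums(wide[, feats]) + attr(sh, "base_value")
  expect_equal(total, pf(nonlin, s), tolerance = 1e-6)
  expect_equal(attr(sh, "prediction"), pf(nonlin, s), tolerance = 1e-10)
})

test_that("symmetric duplicated features share their attribution", {
  sym <- list(w = c(u = 1, v = 1), b = 0)
  pf <- function(m, d) as.vector(as.matrix(d[, c("u", "v")]) %*% m$w)
  bg <- tibble::tibble(u = rep(0, 10), v = rep(0, 10))
  s <- tibble::tibble(u = 2, v = 2)
  sh <- shapley_exact(sym, s, bg, features = c("u", "v"), predict_fn = pf)
  expect_equal(sh$phi[1], sh$phi[2], tolerance = 1e-12)
})

test_that("enumeration refuses more than twelve features", {
  feats <- paste0("f", 1:13)
  bg <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(0, 2, 13)), feats))
  expect_error(
    shapley_exact(list(), bg[1, ], bg, features = feats,
                  predict_fn = function(m, d) rep(0, nrow(d))),
    "capped at 12")
})

test_that("partial dependence isolates additive components", {
  add <- list()
  pf <- function(m, d) d$x1^2 + 3 * d$x2
  set.seed(72)
  data <- tibble::tibble(x1 = runif(200, -2, 2), x2 = rnorm(200))
  grid <- seq(-2, 2, by = 0.5)
  pd <- partial_dependence(add, data, "x1", grid = grid, predict_fn = pf)
  expect_equal(pd$pd, grid^2 + 3 * mean(data$x2), tolerance = 1e-12)
  # a feature the model ignores is flat
  pf2 <- function(m, d) d$x1^2
  pd2 <- partial_dependence(add, data, "x2", predict_fn = pf2)
  expect_equal(diff(range(pd2$pd)), 0)
  expect_error(partial_dependence(add, data[0, ], "x1", predict_fn = pf),
               "empty")
})

test_that("trained model sensitivity recovers the planted directions", {
  d <- gen_sorption_dataset(400, seed = 73)
  f <- assemble_features(d)
  m <- pssm_fit(f, seed = 73, config = fast_config())
  # PD of log_kow trends up (correlated compound descriptors absorb part
  # of the effect, so the pointwise trend is noisy); PD of ph trends down
  pd_kow <- partial_dependence(m, f[1:150, ], "log_kow", n_grid = 8)
  expect_gt(cor(pd_kow$value, pd_kow$pd), 0.5)
  expect_gt(mean(pd_kow$pd[7:8]), mean(pd_kow$pd[1:2]))
  pd_ph <- partial_dependence(m, f[1:150, ], "ph", n_grid = 8)
  expect_lt(cor(pd_ph$value, pd_ph$pd), -0.5)
  # exact Shapley on the real 9-feature model: local accuracy + signs
  set.seed(74)
  bg <- f[sample(nrow(f), 40), ]
  samp <- f[1:5, ]
  sh <- shapley_exact(m, samp, bg)
  wide <- tidyr::pivot_wider(sh, names_from = "feature",
                             values_from = "phi")
  total <- rowSums(wide[, pssm_features()]) + attr(sh, "base_value")
  expect_equal(total, predict(m, samp), tolerance = 1e-6)
  imp <- shap_importance(sh)
  expect_true("log_kow" %in% imp$feature[1:4])
  expect_s3_class(autoplot(sh), "ggplot")
  expect_s3_class(autoplot(pd_kow), "ggplot")
})
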