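#' Stacking-model configuration
#'
#' Hyperparameters of the two-layer stacking ensemble. Defaults: ridge
#' penalty 1.0; 500 trees for the random forest and extremely randomized
#' trees (unrestricted depth); 500 gradient-boosting rounds at learning
#' rate 0.05 and depth 3; a single-hidden-layer perceptron meta-model
#' with 16 logistic hidden units and a linear output, trained for up to
#' 2000 iterations; 5 internal folds for out-of-fold stacking.
#'
#' @param ridge_alpha Ridge penalty on the scaled features.
#' @param n_trees Trees per forest-type learner.
#' @param min_node_size Minimal node size for the forest-type learners.
#' @param mtry Variables tried per split (default `floor(p / 3)`).
#' @param gb_rounds,gb_eta,gb_depth Gradient-boosting rounds, learning
#'   rate and maximum tree depth.
#' @param mlp_size,mlp_decay,mlp_maxit Meta-perceptron hidden units,
#'   weight decay and iteration cap.
#' @param cv_folds Internal folds used to build the out-of-fold base
#'   predictions the meta-model is trained on.
#' @param stack_oof If `TRUE` (default) the meta-model is trained on
#'   out-of-fold base predictions, preventing target leakage; `FALSE`
#'   trains it on in-sample base predictions (kept for fidelity
#'   comparisons; it overfits).
#' @param min_train Minimum number of training rows accepted by
#'   [pssm_fit()].
#' @return A named list of class `pssm_config`.
#' @export
pssm_config <- function(ridge_alpha = 1.0, n_trees = 500L,
                        min_node_size = 5L, mtry = NULL,
                        gb_rounds = 500L, gb_eta = 0.05, gb_depth = 3L,
                        mlp_size = 16L, mlp_decay = 1e-4, mlp_maxit = 2000L,
                        cv_folds = 5L, stack_oof = TRUE, min_train = 50L) {
  structure(
    list(ridge_alpha = ridge_alpha, n_trees = as.integer(n_trees),
         min_node_size = as.integer(min_node_size), mtry = mtry,
         gb_rounds = as.integer(gb_rounds), gb_eta = gb_eta,
         gb_depth = as.integer(gb_depth), mlp_size = as.integer(mlp_size),
         mlp_decay = mlp_decay, mlp_maxit = as.integer(mlp_maxit),
         cv_folds = as.integer(cv_folds), stack_oof = isTRUE(stack_oof),
         min_train = as.integer(min_train)),
    class = "pssm_config"
  )
}

# closed-form ridge on [1 | X]: penalty on slopes only
fit_ridge <- function(X, y, alpha) {
  Xi <- cbind(1, X)
  pen <- diag(c(0, rep(alpha, ncol(X))))
  drop(solve(crossprod(Xi) + pen, crossprod(Xi, y)))
}

fit_base_learners <- function(Xs, y, seed, config) {
  p <- ncol(Xs)
  mtry <- if (is.null(config$mtry)) max(1L, floor(p / 3)) else config$mtry
  df <- as.data.frame(Xs)
  rf <- ranger::ranger(
    y = y, x = df, num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size, seed = seed, num.threads = 1
  )
  et <- ranger::ranger(
    y = y, x = df, num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_node_size, splitrule = "extratrees",
    num.random.splits = 1, replace = FALSE, sample.fraction = 1,
    seed = seed + 1L, num.threads = 1
  )
  set.seed(seed + 2L)
  gb <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = config$gb_eta,
                  max_depth = config$gb_depth, nthread = 1,
                  seed = seed + 2L),
    data = xgboost::xgb.DMatrix(Xs, label = y),
    nrounds = config$gb_rounds, verbose = 0
  )
  list(ridge = fit_ridge(Xs, y, config$ridge_alpha), rf = rf, et = et,
       gb = gb, gb_raw = xgboost::xgb.save.raw(gb))
}

predict_base <- function(base, Xs) {
  if (is.null(base$gb)) base$gb <- xgboost::xgb.load.raw(base$gb_raw)
  cbind(
    ridge = drop(cbind(1, Xs) %*% base$ridge),
    rf = stats::predict(base$rf, data = as.data.frame(Xs),
                        num.threads = 1)$predictions,
    et = stats::predict(base$et, data = as.data.frame(Xs),
                        num.threads = 1)$predictions,
    gb = stats::predict(base$gb, xgboost::xgb.DMatrix(Xs))
  )
}

#' Fit the PFAS sorption stacking model
#'
#' Fits the two-layer stacking ensemble on a feature table: the nine
#' min-max-scaled features feed four base learners (closed-form ridge
#' regression, random forest, extremely randomized trees, gradient
#' boosting); their prediction vector Z feeds a single-hidden-layer
#' perceptron meta-model that produces the final log Kd. By default the
#' meta-model is trained on out-of-fold base predictions (internal
#' `cv_folds`-fold scheme) so it never sees in-sample base fits, then
#' the base learners are refit on all training rows. The whole fit is
#' deterministic for a given seed and data.
#'
#' @param data Training table holding [pssm_features()] columns (or the
#'   subset in `features`) and the target `log_kd`.
#' @param seed Integer seed controlling every stochastic component.
#' @param config A [pssm_config()] list.
#' @param features Feature columns to use (default all nine).
#' @return An object of class `pssm_model`.
#' @seealso [predict.pssm_model()], [predict_kd()], [pssm_pipeline()]
#' @export
pssm_fit <- function(data, seed = 1, config = pssm_config(),
                     features = pssm_features()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(features %in% names(data)), "log_kd" %in% names(data))
  n <- nrow(data)
  if (n < config$min_train) {
    stop("need at least ", config$min_train, " training rows (got ", n, ")",
         call. = FALSE)
  }
  y <- data$log_kd
  if (!all(is.finite(y))) stop("non-finite target values", call. = FALSE)
  X <- data[, features]
  if (!all(vapply(X, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite feature values", call. = FALSE)
  }
  bounds <- fit_minmax(X, features)
  Xs <- as.matrix(apply_minmax(X, bounds, warn_outside = FALSE))

  if (config$stack_oof) {
    set.seed(seed)
    fold <- sample(rep(seq_len(config$cv_folds), length.out = n))
    Z <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("ridge", "rf", "et", "gb")))
    for (f in seq_len(config$cv_folds)) {
      hold <- fold == f
      base_f <- fit_base_learners(Xs[!hold, , drop = FALSE], y[!hold],
                                  seed = seed + 100L * f, config = config)
      Z[hold, ] <- predict_base(base_f, Xs[hold, , drop = FALSE])
    }
  }
  base <- fit_base_learners(Xs, y, seed = seed, config = config)
  if (!config$stack_oof) Z <- predict_base(base, Xs)

  z_bounds <- tibble::tibble(
    feature = colnames(Z),
    min = apply(Z, 2, min),
    max = pmax(apply(Z, 2, max), apply(Z, 2, min) + .Machine$double.eps)
  )
  Zs <- as.matrix(apply_minmax(as.data.frame(Z), z_bounds,
                               warn_outside = FALSE))
  set.seed(seed + 7L)
  meta <- nnet::nnet(x = Zs, y = y, size = config$mlp_size, linout = TRUE,
                     decay = config$mlp_decay, maxit = config$mlp_maxit,
                     trace = FALSE)

  structure(
    list(bounds = bounds, base = base, meta = meta, z_bounds = z_bounds,
         manifest = list(
           n_train = n, features = features, seed = seed, config = config,
           feature_ranges = tibble::tibble(
             feature = features,
             min = vapply(X, min, numeric(1)),
             max = vapply(X, max, numeric(1))
           )
         )),
    class = "pssm_model"
  )
}

#' Predict log Kd from a fitted stacking model
#'
#' @param object A fitted `pssm_model`.
#' @param newdata Data frame holding the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted log Kd values.
#' @export
predict.pssm_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  feats <- object$manifest$features
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Xs <- as.matrix(apply_minmax(newdata[, feats], object$bounds,
                               warn_outside = FALSE))
  Z <- predict_base(object$base, Xs)
  Zs <- as.matrix(apply_minmax(as.data.frame(Z), object$z_bounds,
                               warn_outside = FALSE))
  drop(stats::predict(object$meta, Zs))
}

#' Tidy prediction with applicability flags
#'
#' Like [predict.pssm_model()] but returns a tibble with the prediction
#' on both scales and an `out_of_domain` flag raised when any feature
#' falls outside the training ranges recorded in the model manifest
#' (predictions are still emitted there, but the model extrapolates).
#'
#' @param model A fitted `pssm_model`.
#' @param newdata Data frame holding the model's feature columns.
#' @return Tibble with `.pred_log_kd`, `.pred_kd`, `.out_of_domain`.
#' @export
predict_kd <- function(model, newdata) {
  stopifnot(inherits(model, "pssm_model"))
  newdata <- tibble::as_tibble(newdata)
  pred <- stats::predict(model, newdata)
  rng <- model$manifest$feature_ranges
  ood <- rep(FALSE, nrow(newdata))
  for (i in seq_len(nrow(rng))) {
    v <- newdata[[rng$feature[i]]]
    ood <- ood | v < rng$min[i] | v > rng$max[i]
  }
  tibble::tibble(.pred_log_kd = pred, .pred_kd = 10^pred,
                 .out_of_domain = ood)
}

#' Split, fit and evaluate in one call
#'
#' Convenience wrapper running the reference workflow: seeded holdout
#' split, stacking fit on the training part, prediction on the held-out
#' part, and evaluation.
#'
#' @inheritParams pssm_fit
#' @param fraction Holdout test fraction.
#' @return A list with `model`, `evaluation` (a [evaluate_predictions()]
#'   report on the holdout), and `split`.
#' @export
pssm_pipeline <- function(data, seed = 1, config = pssm_config(),
                          fraction = 0.2, features = pssm_features()) {
  parts <- split_holdout(data, fraction = fraction, seed = seed)
  model <- pssm_fit(parts$train, seed = seed, config = config,
                    features = features)
  pred <- stats::predict(model, parts$test)
  corg <- if ("corg" %in% names(parts$test)) parts$test$corg else NULL
  evaluation <- evaluate_predictions(parts$test$log_kd, pred, corg = corg)
  list(model = model, evaluation = evaluation, split = parts)
}

#' Refit without one feature (ablation)
#'
#' Repeats the reference run of [pssm_pipeline()] with the identical
#' seed (hence identical train/test membership) but with one feature
#' removed, so metric differences are attributable to the feature alone.
#'
#' @inheritParams pssm_pipeline
#' @param drop_feature Feature to remove (must be one of the model's
#'   features).
#' @return The [pssm_pipeline()] list for the ablated run.
#' @export
pssm_ablate <- function(data, drop_feature, seed = 1,
                        config = pssm_config(), fraction = 0.2,
                        features = pssm_features()) {
  if (!drop_feature %in% features) {
    stop("unknown feature: ", drop_feature, call. = FALSE)
  }
  pssm_pipeline(data, seed = seed, config = config, fraction = fraction,
                features = setdiff(features, drop_feature))
}

#' k-fold cross-validated NRMSE
#'
#' Refits the full stacking pipeline on each of `k` seeded folds and
#' computes the NRMSE of each held-out fold. The mean over folds is the
#' CV-NRMSE reported alongside holdout metrics.
#'
#' @inheritParams pssm_fit
#' @param k Number of folds.
#' @return Tibble with one row per fold (`fold`, `n`, `nrmse`) and an
#'   attribute `cv_nrmse` holding the mean.
#' @export
cross_validate <- function(data, k = 10, seed = 1, config = pssm_config(),
                           features = pssm_features()) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  res <- purrr::map_dfr(seq_len(k), function(f) {
    hold <- fold == f
    m <- pssm_fit(data[!hold, ], seed = seed + f, config = config,
                  features = features)
    p <- stats::predict(m, data[hold, ])
    tibble::tibble(fold = f, n = sum(hold),
                   nrmse = evaluate_predictions(data$log_kd[hold], p)$nrmse)
  })
  attr(res, "cv_nrmse") <- mean(res$nrmse)
  res
}

#' @export
print.pssm_model <- function(x, ...) {
  m <- x$manifest
  cat("<pssm_model> stacking ensemble:",
      "ridge + random forest + extra trees + gradient boosting -> MLP\n")
  cat("  trained on", m$n_train, "entries,", length(m$features),
      "features, seed", m$seed, "\n")
  invisible(x)
}

#' @export
tidy.pssm_model <- function(x, ...) {
  cfg <- x$manifest$config
  tibble::tibble(
    learner = c("ridge", "random_forest", "extra_trees",
                "gradient_boosting", "mlp_meta"),
    layer = c(rep("base", 4), "meta"),
    hyperparameters = c(
      paste0("alpha=", cfg$ridge_alpha),
      paste0("trees=", cfg$n_trees),
      paste0("trees=", cfg$n_trees, ", extratrees"),
      paste0("rounds=", cfg$gb_rounds, ", eta=", cfg$gb_eta,
             ", depth=", cfg$gb_depth),
      paste0("size=", cfg$mlp_size, ", decay=", cfg$mlp_decay)
    )
  )
}

#' @export
glance.pssm_model <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(n_train = m$n_train, n_features = length(m$features),
                 seed = m$seed, stack_oof = m$config$stack_oof,
                 cv_folds = m$config$cv_folds)
}

#' Save or load a fitted stacking model
#'
#' Writes a directory bundle: a JSON manifest (features, seed, scaling
#' bounds, hyperparameters, training ranges) plus the learner objects.
#'
#' @param model A fitted `pssm_model`.
#' @param dir Bundle directory.
#' @export
write_pssm_model <- function(model, dir) {
  stopifnot(inherits(model, "pssm_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- model$manifest
  jsonlite::write_json(
    list(n_train = m$n_train, features = m$features, seed = m$seed,
         config = unclass(m$config), feature_ranges = m$feature_ranges,
         bounds = model$bounds, z_bounds = model$z_bounds),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  learners <- model
  learners$base$gb <- NULL  # external handle; rebuilt from gb_raw on load
  saveRDS(learners, file.path(dir, "learners.rds"))
  invisible(dir)
}

#' @rdname write_pssm_model
#' @export
read_pssm_model <- function(dir) {
  model <- readRDS(file.path(dir, "learners.rds"))
  model$base$gb <- xgboost::xgb.load.raw(model$base$gb_raw)
  model
}
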