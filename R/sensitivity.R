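#' Exact Shapley values by subset enumeration
#'
#' Computes exact, model-agnostic Shapley attributions for each sample
#' and feature by enumerating every feature subset (2^p coalitions; with
#' the model's nine features, 512). The coalition value f(S) is the
#' interventional expectation: features outside S are replaced by the
#' corresponding columns of the background rows and the predictions
#' averaged. Each feature's value is the permutation-weighted sum of its
#' marginal contributions, with weight |S|! (p - |S| - 1)! / p!.
#'
#' Local accuracy holds by construction: for every sample the feature
#' contributions plus the base value (mean background prediction) sum to
#' the model's prediction for that sample.
#'
#' @param model A fitted `pssm_model`, or any object accepted by
#'   `predict_fn`.
#' @param samples Data frame of rows to explain.
#' @param background Data frame of background rows defining the
#'   interventional expectation (e.g. a seed-fixed subsample of the
#'   training data; 100 rows is plenty).
#' @param features Feature columns (at most 12; enumeration is 2^p).
#' @param predict_fn Function `(model, data) -> numeric`; defaults to
#'   `predict()`.
#' @return A long tibble of class `pssm_shap` with columns `.row`
#'   (sample index), `feature`, `phi`, and attributes `base_value` and
#'   `prediction` (per-sample model output).
#' @seealso [shap_importance()], [partial_dependence()]
#' @export
shapley_exact <- function(model, samples, background,
                          features = NULL, predict_fn = NULL) {
  samples <- tibble::as_tibble(samples)
  background <- tibble::as_tibble(background)
  if (nrow(background) < 1) stop("background must be non-empty", call. = FALSE)
  if (is.null(features)) {
    features <- if (inherits(model, "pssm_model")) {
      model$manifest$features
    } else {
      names(samples)
    }
  }
  p <- length(features)
  if (p > 12) {
    stop("exact enumeration is capped at 12 features (2^p coalitions); ",
         "got ", p, call. = FALSE)
  }
  if (is.null(predict_fn)) {
    predict_fn <- function(object, data) stats::predict(object, data)
  }
  ns <- nrow(samples)
  nb <- nrow(background)
  n_sub <- 2^p
  subset_size <- vapply(0:(n_sub - 1), function(s) sum(bitwAnd(s, 2^(0:(p - 1))) > 0),
                        numeric(1))
  # weight by |S| for subsets S not containing i
  wt <- factorial(0:(p - 1)) * factorial(p - (0:(p - 1)) - 1) / factorial(p)

  # value matrix V[sample, subset]: mean prediction with subset features
  # taken from the sample and the rest from the background rows
  V <- matrix(NA_real_, ns, n_sub)
  bg <- background[rep(seq_len(nb), ns), , drop = FALSE]
  sample_rep <- samples[rep(seq_len(ns), each = nb), features, drop = FALSE]
  grp <- rep(seq_len(ns), each = nb)
  for (s in 0:(n_sub - 1)) {
    members <- features[bitwAnd(s, 2^(0:(p - 1))) > 0]
    x <- bg
    x[members] <- sample_rep[members]
    pred <- predict_fn(model, x)
    V[, s + 1] <- as.vector(tapply(pred, grp, mean))
  }

  phi <- matrix(0, ns, p, dimnames = list(NULL, features))
  for (i in seq_len(p)) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(0:(n_sub - 1), bit) == 0)  # 1-based indices
    w <- wt[subset_size[without] + 1]
    delta <- V[, without + bit, drop = FALSE] - V[, without, drop = FALSE]
    phi[, i] <- drop(delta %*% w)
  }

  out <- tibble::tibble(
    .row = rep(seq_len(ns), each = p),
    feature = rep(features, ns),
    phi = as.vector(t(phi))
  )
  class(out) <- c("pssm_shap", class(out))
  attr(out, "base_value") <- V[1, 1]
  attr(out, "prediction") <- V[, n_sub]
  out
}

#' Rank features by mean absolute Shapley value
#'
#' @param shap A `pssm_shap` result.
#' @return Tibble (`feature`, `mean_abs_phi`) sorted by importance.
#' @export
shap_importance <- function(shap) {
  stopifnot(inherits(shap, "pssm_shap"))
  out <- dplyr::summarise(dplyr::group_by(shap, .data$feature),
                          mean_abs_phi = mean(abs(.data$phi)),
                          .groups = "drop")
  dplyr::arrange(out, dplyr::desc(.data$mean_abs_phi))
}

#' @export
autoplot.pssm_shap <- function(object, ...) {
  imp <- shap_importance(object)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$mean_abs_phi,
                                    y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |phi| (log Kd units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Partial dependence of the model on one feature
#'
#' PD(x_j) = (1/n) sum_i f(x_j, x_i,\\j): the feature of interest is set
#' to each grid value in turn while every other feature keeps its
#' observed values, and predictions are averaged.
#'
#' @inheritParams shapley_exact
#' @param data Data frame of observations to average over.
#' @param feature Feature name.
#' @param grid Grid of feature values (default: `n_grid` equally spaced
#'   points spanning the observed range).
#' @param n_grid Grid size when `grid` is NULL.
#' @return A tibble of class `pssm_pd` with columns `feature`, `value`,
#'   `pd`, `n`.
#' @export
partial_dependence <- function(model, data, feature, grid = NULL,
                               n_grid = 20, predict_fn = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1) stop("empty sample set", call. = FALSE)
  if (!feature %in% names(data)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  if (is.null(predict_fn)) {
    predict_fn <- function(object, d) stats::predict(object, d)
  }
  if (is.null(grid)) {
    grid <- seq(min(data[[feature]]), max(data[[feature]]),
                length.out = n_grid)
  }
  pd <- vapply(grid, function(v) {
    d <- data
    d[[feature]] <- v
    mean(predict_fn(model, d))
  }, numeric(1))
  out <- tibble::tibble(feature = feature, value = grid, pd = pd,
                        n = nrow(data))
  class(out) <- c("pssm_pd", class(out))
  out
}

#' @export
autoplot.pssm_pd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$pd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = unique(object$feature), y = "partial dependence") +
    ggplot2::theme_minimal()
}
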