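#' Min-max feature scaling
#'
#' `fit_minmax()` learns per-column bounds (training data only);
#' `apply_minmax()` maps `x` to `(x - min) / (max - min)` with those
#' bounds; `invert_minmax()` is the exact inverse. Values outside the
#' fitted bounds scale outside `[0, 1]` and are passed through with a
#' warning: the model extrapolates there and predictions should be
#' treated with caution.
#'
#' @param data Data frame holding the columns to scale.
#' @param features Columns to scale (default: the model feature set).
#' @return `fit_minmax()`: a bounds tibble (`feature`, `min`, `max`).
#'   `apply_minmax()`/`invert_minmax()`: `data` with the columns
#'   (un)scaled.
#' @export
fit_minmax <- function(data, features = pssm_features()) {
  data <- tibble::as_tibble(data)
  stopifnot(all(features %in% names(data)))
  mins <- vapply(data[features], min, numeric(1))
  maxs <- vapply(data[features], max, numeric(1))
  constant <- features[maxs - mins <= 0]
  if (length(constant)) {
    stop("constant column(s), cannot min-max scale: ",
         paste(constant, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(feature = features, min = unname(mins), max = unname(maxs))
}

#' @rdname fit_minmax
#' @param bounds A bounds tibble from `fit_minmax()`.
#' @param warn_outside Warn when values fall outside the fitted bounds.
#' @export
apply_minmax <- function(data, bounds, warn_outside = TRUE) {
  data <- tibble::as_tibble(data)
  outside <- character(0)
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    x <- (data[[f]] - bounds$min[i]) / (bounds$max[i] - bounds$min[i])
    if (warn_outside && any(x < 0 | x > 1, na.rm = TRUE)) outside <- c(outside, f)
    data[[f]] <- x
  }
  if (length(outside)) {
    warning("values outside the fitted bounds for: ",
            paste(outside, collapse = ", "),
            " (scaled outside [0,1], passed through)", call. = FALSE)
  }
  data
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(data, bounds) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    data[[f]] <- data[[f]] * (bounds$max[i] - bounds$min[i]) + bounds$min[i]
  }
  data
}

#' Seed-reproducible random holdout split
#'
#' Randomly partitions `data` into disjoint, exhaustive train and test
#' sets. The test share uses the floor rule: `n_test = floor(n *
#' fraction)` (a 1,227-row dataset at fraction 0.2 gives 982 training and
#' 245 test rows).
#'
#' @param data Data frame to split.
#' @param fraction Test fraction in (0, 1).
#' @param seed Integer seed for the split.
#' @return A list with `train` and `test` tibbles.
#' @export
split_holdout <- function(data, fraction = 0.2, seed = 1) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 2) stop("need at least two rows to split", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n_test <- floor(n * fraction)
  test_idx <- sort(sample.int(n, n_test))
  list(train = data[-test_idx, ], test = data[test_idx, ])
}
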