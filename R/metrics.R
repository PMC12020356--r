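#' Evaluate predicted against observed log Kd
#'
#' Computes the evaluation statistics used throughout the package:
#' \itemize{
#'   \item RMSE = sqrt(mean((obs - pred)^2));
#'   \item NRMSE = RMSE normalized by the observed range (configurable to
#'     mean- or SD-normalization via `normalizer`);
#'   \item RPD = sd(obs) / RMSE with the sample (n-1) standard deviation;
#'   \item slope, intercept and r-squared of the OLS regression of
#'     predicted on observed;
#'   \item residual (obs - pred) mean, sample SD and Fisher skewness
#'     (g1 = m3 / m2^1.5).
#' }
#' When a `corg` vector is supplied, residual summaries stratified by
#' organic-carbon band are attached as an attribute (useful to check for
#' bias in organic vs. mineral soils).
#'
#' @param observed Observed log Kd vector (length >= 2, not constant).
#' @param predicted Predicted log Kd vector of the same length.
#' @param normalizer NRMSE normalizer: `"range"` (default), `"mean"`, or
#'   `"sd"`.
#' @param cv_nrmse Optional pre-computed k-fold CV-NRMSE (see
#'   [cross_validate()]) carried into the report.
#' @param corg Optional organic-carbon vector for stratified residuals.
#' @param corg_breaks Band edges for the stratification (% Corg).
#' @return A one-row tibble of class `pssm_evaluation` with columns
#'   `n`, `rmse`, `nrmse`, `cv_nrmse`, `rpd`, `slope`, `intercept`, `r2`,
#'   `residual_mean`, `residual_sd`, `residual_skewness`; residuals and
#'   any stratified summary are kept as attributes.
#' @examples
#' evaluate_predictions(c(0, 1, 2, 3), c(0, 1, 2, 4))
#' @export
evaluate_predictions <- function(observed, predicted,
                                 normalizer = c("range", "mean", "sd"),
                                 cv_nrmse = NA_real_, corg = NULL,
                                 corg_breaks = c(0, 2, 10, Inf)) {
  normalizer <- match.arg(normalizer)
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("observed and predicted must be finite", call. = FALSE)
  }
  rng <- max(observed) - min(observed)
  if (rng <= 0) {
    stop("observed values are constant: NRMSE and RPD are undefined",
         call. = FALSE)
  }
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  norm_by <- switch(normalizer,
    range = rng,
    mean = mean(observed),
    sd = stats::sd(observed)
  )
  fit <- stats::lm(predicted ~ observed)
  m2 <- mean((res - mean(res))^2)
  m3 <- mean((res - mean(res))^3)
  out <- tibble::tibble(
    n = n,
    rmse = rmse,
    nrmse = rmse / norm_by,
    cv_nrmse = cv_nrmse,
    rpd = stats::sd(observed) / rmse,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = stats::cor(observed, predicted)^2,
    residual_mean = mean(res),
    residual_sd = stats::sd(res),
    residual_skewness = if (m2 > 0) m3 / m2^1.5 else 0
  )
  class(out) <- c("pssm_evaluation", class(out))
  attr(out, "normalizer") <- normalizer
  attr(out, "observed") <- observed
  attr(out, "predicted") <- predicted
  if (!is.null(corg)) {
    stopifnot(length(corg) == n)
    band <- cut(corg, breaks = corg_breaks, include.lowest = TRUE)
    strat <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(band = band, res = res), .data$band),
      n = dplyr::n(),
      residual_mean = mean(.data$res),
      residual_sd = if (dplyr::n() > 1) stats::sd(.data$res) else NA_real_,
      .groups = "drop"
    )
    attr(out, "residuals_by_corg") <- strat
  }
  out
}

#' @export
glance.pssm_evaluation <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.pssm_evaluation <- function(x, ...) {
  cat("<pssm_evaluation> n =", x$n, "\n")
  cat(sprintf("  NRMSE %.4f (%s)  RPD %.3f", x$nrmse,
              attr(x, "normalizer"), x$rpd))
  if (!is.na(x$cv_nrmse)) cat(sprintf("  CV-NRMSE %.4f", x$cv_nrmse))
  cat("\n")
  cat(sprintf("  pred ~ obs: slope %.3f  intercept %.3f  r2 %.3f\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  residuals: mean %.4f  sd %.4f  skewness %.3f\n",
              x$residual_mean, x$residual_sd, x$residual_skewness))
  invisible(x)
}

#' @export
autoplot.pssm_evaluation <- function(object, ...) {
  df <- tibble::tibble(observed = attr(object, "observed"),
                       predicted = attr(object, "predicted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "observed log Kd", y = "predicted log Kd") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to JSON
#'
#' @param report A `pssm_evaluation` object.
#' @param path Output JSON path.
#' @export
write_evaluation_json <- function(report, path) {
  jsonlite::write_json(as.list(tibble::as_tibble(unclass(report))), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
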