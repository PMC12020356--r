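#' Predict log Kd across a gridded soil-property table
#'
#' Applies a trained stacking model to a table of grid cells (one row per
#' location with `lat`, `lon` and the six soil properties), producing a
#' per-compound tabular Kd map. Missing soil properties are filled with
#' the supplied imputer when one is given; cells that still lack any
#' model feature are emitted with `nodata = TRUE` and no prediction.
#' Cells whose features fall outside the model's training ranges carry
#' `out_of_domain = TRUE` (the prediction is still emitted, flagged as
#' extrapolation). Rasterization is left to GIS tools.
#'
#' @param model A fitted `pssm_model`.
#' @param grid Data frame with `lat`, `lon` (decimal degrees, WGS84) and
#'   soil property columns.
#' @param compound Compound key resolved via [registry_lookup()].
#' @param registry Compound registry.
#' @param imputer Optional fitted [fit_soil_imputer()].
#' @return A tibble with one row per input cell: `lat`, `lon`, the soil
#'   properties, `compound_id`, `log_kd`, `kd`, `nodata`,
#'   `out_of_domain`.
#' @export
predict_kd_map <- function(model, grid, compound,
                           registry = pfas_registry(), imputer = NULL) {
  stopifnot(inherits(model, "pssm_model"))
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  if (!all(c("lat", "lon") %in% names(grid))) {
    stop("grid must have `lat` and `lon` columns", call. = FALSE)
  }
  if (any(!is.na(grid$lat) & abs(grid$lat) > 90) ||
      any(!is.na(grid$lon) & abs(grid$lon) > 180)) {
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  }
  cmp <- registry_lookup(registry, compound)

  for (p in .soil_properties) if (!p %in% names(grid)) grid[[p]] <- NA_real_
  soils <- grid[, .soil_properties]
  if (!is.null(imputer) && anyNA(soils)) {
    any_obs <- rowSums(!is.na(as.matrix(soils))) > 0
    if (any(any_obs)) {
      filled <- suppressWarnings(impute_soils(imputer, soils[any_obs, ]))
      soils[any_obs, ] <- filled[, .soil_properties]
    }
  }
  complete <- stats::complete.cases(soils)

  out <- grid
  out[, .soil_properties] <- soils
  out$compound_id <- cmp$id
  out$log_kd <- NA_real_
  out$kd <- NA_real_
  out$nodata <- !complete
  out$out_of_domain <- NA

  if (any(complete)) {
    entries <- soils[complete, ]
    entries$compound_id <- cmp$id
    feats <- assemble_features(entries, registry)
    pred <- predict_kd(model, feats)
    out$log_kd[complete] <- pred$.pred_log_kd
    out$kd[complete] <- pred$.pred_kd
    out$out_of_domain[complete] <- pred$.out_of_domain
  }
  class(out) <- c("pssm_map", class(out))
  out
}

#' @export
autoplot.pssm_map <- function(object, ...) {
  ggplot2::ggplot(object[!object$nodata, ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$log_kd)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "log Kd") +
    ggplot2::theme_minimal()
}

#' Plot a tabular Kd map
#'
#' Tile plot of predicted log Kd over the grid; cells without data are
#' omitted.
#'
#' @param map Output of [predict_kd_map()].
#' @return A ggplot object.
#' @export
plot_kd_map <- function(map) {
  ggplot2::ggplot(map[!map$nodata, ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$log_kd)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "log Kd") +
    ggplot2::theme_minimal()
}
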