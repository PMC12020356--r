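.soil_properties <- c("ph", "cec", "corg", "sand", "silt", "clay")

#' Fit a K-nearest-neighbour soil-property imputer
#'
#' Trains an imputer on a complete reference table of the six soil
#' properties used by the model (`ph`, `cec`, `corg`, `sand`, `silt`,
#' `clay`). Properties are min-max scaled to the reference bounds;
#' distances between a query soil and reference rows are Euclidean over
#' the query's observed coordinates, rescaled by the fraction of observed
#' coordinates (nan-aware), so soils with different missingness patterns
#' are comparable. Missing values are imputed as the uniform-weight mean
#' of the k nearest reference rows; distance ties are broken by reference
#' row order.
#'
#' @param reference Data frame with the six soil properties, no missing
#'   values, at least `k` rows. Extra columns (e.g. coordinates) are
#'   ignored.
#' @param k Number of neighbours (default 5).
#' @return An object of class `soil_imputer`.
#' @seealso [impute_soils()], [write_soil_imputer()]
#' @export
fit_soil_imputer <- function(reference, k = 5) {
  reference <- tibble::as_tibble(reference)
  missing <- setdiff(.soil_properties, names(reference))
  if (length(missing)) {
    stop("reference table is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- as.matrix(reference[, .soil_properties])
  if (anyNA(ref)) stop("reference table must be complete", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k > nrow(ref)) {
    stop("`k` (", k, ") exceeds the number of reference rows (", nrow(ref),
         ")", call. = FALSE)
  }
  bounds <- tibble::tibble(
    property = .soil_properties,
    min = apply(ref, 2, min),
    max = apply(ref, 2, max)
  )
  span <- pmax(bounds$max - bounds$min, .Machine$double.eps)
  scaled <- sweep(sweep(ref, 2, bounds$min), 2, span, "/")
  structure(
    list(reference = ref, scaled = scaled, bounds = bounds, span = span,
         k = as.integer(k)),
    class = "soil_imputer"
  )
}

#' Impute missing soil properties
#'
#' Fills every missing model soil property in `soils` using the fitted
#' imputer and records which fields were filled in an `imputed_fields`
#' list-column. Sand/silt/clay are renormalized to sum to 100 for rows
#' where any texture fraction was imputed. Rows with all six properties
#' missing cannot be placed in property space; they are returned
#' unfilled with `imputable = FALSE` and a warning.
#'
#' @param imputer A fitted [fit_soil_imputer()] object.
#' @param soils Data frame with (possibly incomplete) soil property
#'   columns.
#' @return `soils` with missing properties filled, plus `imputed_fields`
#'   (character list-column) and `imputable` (logical).
#' @export
impute_soils <- function(imputer, soils) {
  stopifnot(inherits(imputer, "soil_imputer"))
  soils <- tibble::as_tibble(soils)
  for (p in .soil_properties) if (!p %in% names(soils)) soils[[p]] <- NA_real_
  x <- as.matrix(soils[, .soil_properties])
  p <- length(.soil_properties)
  imputed_fields <- vector("list", nrow(soils))
  imputable <- rep(TRUE, nrow(soils))

  for (i in seq_len(nrow(x))) {
    obs <- !is.na(x[i, ])
    if (!any(obs)) {
      imputable[i] <- FALSE
      imputed_fields[[i]] <- character(0)
      next
    }
    if (all(obs)) {
      imputed_fields[[i]] <- character(0)
      next
    }
    nn <- nearest_reference_rows(imputer, x[i, ], obs)
    fill <- which(!obs)
    x[i, fill] <- colMeans(imputer$reference[nn, fill, drop = FALSE])
    imputed_fields[[i]] <- .soil_properties[fill]
    tex <- c("sand", "silt", "clay")
    if (any(tex %in% imputed_fields[[i]])) {
      ti <- match(tex, .soil_properties)
      x[i, ti] <- x[i, ti] * 100 / sum(x[i, ti])
    }
  }
  if (any(!imputable)) {
    warning(sum(!imputable), " soil(s) had all properties missing and were ",
            "left unfilled", call. = FALSE)
  }
  soils[, .soil_properties] <- as.data.frame(x)
  soils$imputed_fields <- imputed_fields
  soils$imputable <- imputable
  soils
}

# nan-aware scaled Euclidean distance; returns indices of the k nearest
# reference rows (stable ties by row order).
nearest_reference_rows <- function(imputer, row, obs) {
  q <- (row - imputer$bounds$min) / imputer$span
  d2 <- colSums((t(imputer$scaled[, obs, drop = FALSE]) - q[obs])^2)
  p <- length(obs)
  d <- sqrt(d2 * p / sum(obs))
  order(d)[seq_len(imputer$k)]
}

#' @export
print.soil_imputer <- function(x, ...) {
  cat("<soil_imputer> k =", x$k, "on", nrow(x$reference),
      "reference soils\n")
  print(x$bounds)
  invisible(x)
}

#' Serialize a soil imputer to a JSON bundle
#'
#' The bundle stores k, the per-property scaling bounds, and the raw
#' reference matrix, so a saved imputer reloads bit-identically.
#'
#' @param imputer A fitted [fit_soil_imputer()] object.
#' @param path Output JSON path.
#' @export
write_soil_imputer <- function(imputer, path) {
  stopifnot(inherits(imputer, "soil_imputer"))
  jsonlite::write_json(
    list(k = imputer$k,
         properties = .soil_properties,
         bounds = imputer$bounds,
         reference = as.data.frame(imputer$reference)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_soil_imputer
#' @export
read_soil_imputer <- function(path) {
  b <- jsonlite::fromJSON(path)
  fit_soil_imputer(tibble::as_tibble(b$reference), k = b$k)
}
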