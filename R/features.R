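#' The canonical model feature set
#'
#' The nine predictors, in fixed order: three compound descriptors
#' (`mw_effective`, `log_kow`, `charge_density`) and six soil properties
#' (`ph`, `cec`, `corg`, `sand`, `silt`, `clay`).
#'
#' @return Character vector of feature names.
#' @export
pssm_features <- function() {
  c("mw_effective", "log_kow", "charge_density",
    "ph", "cec", "corg", "sand", "silt", "clay")
}

#' Assemble model features for sorption entries
#'
#' For each entry, speciates its compound at the entry's soil pH and
#' fills the pH-dependent descriptors (effective molecular weight,
#' charge density) alongside log Kow and the six soil properties. The
#' modeling target `log_kd` is carried through when `kd`/`log_kd` is
#' present. Soils must be complete (run [impute_soils()] first).
#'
#' @param entries Data frame with `compound_id`, the six soil properties
#'   and optionally `kd` or `log_kd`.
#' @param registry Compound registry.
#' @return A tibble with the entry identifier columns, the nine features
#'   of [pssm_features()], and `log_kd` when available.
#' @export
assemble_features <- function(entries, registry = pfas_registry()) {
  entries <- tibble::as_tibble(entries)
  stopifnot("compound_id" %in% names(entries))
  missing_soil <- setdiff(.soil_properties, names(entries))
  if (length(missing_soil)) {
    stop("entries are missing soil column(s): ",
         paste(missing_soil, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(entries$compound_id), registry$id)
  if (length(unknown)) {
    stop("compound(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  soil <- entries[, .soil_properties]
  if (anyNA(soil) || anyNA(entries$ph)) {
    stop("soil properties must be complete; impute first", call. = FALSE)
  }
  ridx <- match(entries$compound_id, registry$id)

  # speciation depends only on (compound, ph): compute unique pairs once
  key <- paste(entries$compound_id, signif(entries$ph, 12))
  uniq <- !duplicated(key)
  spec <- purrr::map2(ridx[uniq], entries$ph[uniq], function(ri, ph) {
    st <- speciate(registry[ri, ], ph, registry)
    c(mw_effective = attr(st, "mw_effective"),
      charge_density = attr(st, "charge_density"))
  })
  spec <- do.call(rbind, spec)[match(key, key[uniq]), , drop = FALSE]

  out <- entries
  out$mw_effective <- spec[, "mw_effective"]
  out$charge_density <- spec[, "charge_density"]
  out$log_kow <- registry$log_kow[ridx]
  if (!"log_kd" %in% names(out) && "kd" %in% names(out)) {
    out$log_kd <- log10(out$kd)
  }
  keep <- c(intersect(c("entry_id", "compound_id", "study_id"), names(out)),
            pssm_features(),
            intersect("log_kd", names(out)))
  out[, keep]
}
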