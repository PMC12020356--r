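#' Convert an organic-carbon-normalized coefficient to Kd
#'
#' `Kd = Koc * foc` with `foc = corg / 100`. Entries with zero or missing
#' organic carbon cannot be converted and raise an error.
#'
#' @param koc Organic-carbon-normalized sorption coefficient (L kg^-1 OC).
#' @param corg Soil organic carbon content (% mass).
#' @return Kd in L kg^-1.
#' @examples
#' kd_from_koc(100, corg = 1)  # 1 L/kg
#' @export
kd_from_koc <- function(koc, corg) {
  stopifnot(is.numeric(koc), is.numeric(corg))
  if (any(!is.finite(koc) | koc <= 0)) {
    stop("`koc` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(corg) | corg <= 0)) {
    stop("cannot convert Koc to Kd without organic carbon (corg must be > 0)",
         call. = FALSE)
  }
  koc * corg / 100
}

#' Back-compute Koc from a Kd entry
#'
#' Exact inverse of [kd_from_koc()]: `Koc = Kd / (corg/100)`.
#'
#' @param kd Distribution coefficient (L kg^-1).
#' @param corg Soil organic carbon content (% mass).
#' @return Koc in L kg^-1 OC.
#' @export
koc_of <- function(kd, corg) {
  stopifnot(is.numeric(kd), is.numeric(corg))
  if (any(!is.finite(corg) | corg <= 0)) {
    stop("Koc is undefined for corg <= 0", call. = FALSE)
  }
  kd / (corg / 100)
}

#' Derive Kd from isotherm fit parameters
#'
#' Evaluates the distribution coefficient `Kd = Cs/Cw` at an aqueous
#' concentration of 10% of the compound's water solubility. For a
#' Freundlich isotherm `Cs = Kf * Cw^n` this gives
#' `Kd = Kf * (0.1 S)^(n-1)` (so a linear isotherm, `n = 1`, returns
#' `Kf`); for a Langmuir isotherm `Cs = Qmax * Kl * Cw / (1 + Kl * Cw)`
#' it gives `Kd = Qmax * Kl / (1 + 0.1 S Kl)`.
#'
#' @param model `"freundlich"` or `"langmuir"`.
#' @param p1 Freundlich `Kf` or Langmuir `Qmax`.
#' @param p2 Freundlich exponent `n` (> 0) or Langmuir `Kl`.
#' @param solubility Water solubility S (mg L^-1), must be positive.
#' @return Kd in L kg^-1.
#' @examples
#' kd_from_isotherm("freundlich", p1 = 10, p2 = 0.8, solubility = 100)
#' @export
kd_from_isotherm <- function(model, p1, p2, solubility) {
  model <- match.arg(tolower(model), c("freundlich", "langmuir"))
  if (!is.numeric(solubility) || any(!is.finite(solubility) | solubility <= 0)) {
    stop("missing or non-positive solubility: cannot evaluate the isotherm ",
         "at 10% of solubility", call. = FALSE)
  }
  if (any(!is.finite(p1) | p1 <= 0) || any(!is.finite(p2) | p2 <= 0)) {
    stop("isotherm parameters must be positive", call. = FALSE)
  }
  cw <- 0.1 * solubility
  switch(model,
    freundlich = p1 * cw^(p2 - 1),
    langmuir = p1 * p2 / (1 + p2 * cw)
  )
}

#' Harmonize a raw sorption dataset
#'
#' Turns heterogeneous literature-style sorption records into a clean,
#' unit-consistent Kd table. For each row the Kd source is resolved by
#' preference: a directly reported `kd` first, then conversion from a
#' reported `koc` (requires `corg > 0`), then derivation from isotherm
#' fit parameters at 10% of the registry solubility. Rows where no route
#' applies, or whose soil fields violate their physical ranges, are kept
#' with `accepted = FALSE` and a machine-readable `reject_reason`.
#' Reported sand/silt/clay triplets are accepted when they close to
#' 100 +- `texture_tol` % and are renormalized to exactly 100.
#'
#' @param raw A data frame in the documented CSV schema (see
#'   [read_sorption_csv()]): `entry_id`, `compound_id`, `study_id`, `ph`,
#'   `cec`, `corg`, `sand`, `silt`, `clay`, `fe`, `al`, `kd`, `koc`,
#'   `isotherm_model`, `isotherm_p1`, `isotherm_p2`. Missing values as NA.
#' @param registry Compound registry (solubility lookup for isotherm
#'   conversion; unknown compounds are rejected).
#' @param texture_tol Closure tolerance for reported textures (%).
#' @return The input tibble with resolved `kd`, `log_kd` (base 10),
#'   `source` (`direct`, `from_koc`, `from_isotherm`), `accepted`,
#'   `reject_reason` columns.
#' @examples
#' raw <- tibble::tibble(entry_id = "e1", compound_id = "pfoa",
#'                       study_id = "s1", ph = 6, cec = 10, corg = 2,
#'                       sand = 40, silt = 40, clay = 20, kd = 3.2)
#' harmonize_sorption(raw)
#' @export
harmonize_sorption <- function(raw, registry = pfas_registry(),
                               texture_tol = 2) {
  raw <- tibble::as_tibble(raw)
  for (col in c("kd", "koc", "isotherm_model", "isotherm_p1", "isotherm_p2",
                "ph", "cec", "corg", "sand", "silt", "clay")) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  n <- nrow(raw)
  kd <- rep(NA_real_, n)
  source <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  known <- raw$compound_id %in% registry$id
  sol <- registry$solubility[match(raw$compound_id, registry$id)]

  for (i in seq_len(n)) {
    if (!known[i]) { reason[i] <- "unknown_compound"; next }
    r <- raw[i, ]
    # soil plausibility screens (missing values pass; the imputer fills them)
    if (!is.na(r$ph) && (r$ph < 0 || r$ph > 14)) { reason[i] <- "ph_out_of_range"; next }
    if (!is.na(r$cec) && r$cec < 0) { reason[i] <- "negative_cec"; next }
    pc <- c(r$corg, r$sand, r$silt, r$clay)
    if (any(!is.na(pc) & (pc < 0 | pc > 100))) { reason[i] <- "percentage_out_of_range"; next }
    tex <- c(r$sand, r$silt, r$clay)
    if (all(!is.na(tex)) && abs(sum(tex) - 100) > texture_tol) {
      reason[i] <- "texture_sum"; next
    }
    if (!is.na(r$kd)) {
      if (r$kd <= 0) { reason[i] <- "nonpositive_kd"; next }
      kd[i] <- r$kd; source[i] <- "direct"
    } else if (!is.na(r$koc)) {
      if (is.na(r$corg) || r$corg <= 0) { reason[i] <- "koc_without_corg"; next }
      kd[i] <- kd_from_koc(r$koc, r$corg); source[i] <- "from_koc"
    } else if (!is.na(r$isotherm_model)) {
      if (is.na(sol[i]) || sol[i] <= 0) { reason[i] <- "isotherm_without_solubility"; next }
      ok <- tryCatch({
        kd[i] <- kd_from_isotherm(r$isotherm_model, r$isotherm_p1,
                                  r$isotherm_p2, sol[i])
        TRUE
      }, error = function(e) FALSE)
      if (!ok) { reason[i] <- "invalid_isotherm"; next }
      source[i] <- "from_isotherm"
    } else {
      reason[i] <- "no_kd_source"
    }
  }

  out <- raw
  out$kd <- kd
  out$log_kd <- log10(kd)
  out$source <- source
  out$accepted <- is.na(reason)
  out$reject_reason <- reason
  # renormalize accepted complete textures to exactly 100
  full <- out$accepted & !is.na(out$sand) & !is.na(out$silt) & !is.na(out$clay)
  s <- out$sand[full] + out$silt[full] + out$clay[full]
  out$sand[full] <- out$sand[full] * 100 / s
  out$silt[full] <- out$silt[full] * 100 / s
  out$clay[full] <- out$clay[full] * 100 / s
  out
}

#' Flag outlying compounds and entries against the log Koc - log Kow trend
#'
#' Two advisory screens, mirroring the dataset-curation practice of
#' inspecting organic-carbon-normalized sorption against hydrophobicity:
#'
#' 1. *Compound level*: per-compound mean log Koc is regressed (OLS) on
#'    log Kow; compounds whose absolute residual exceeds
#'    `compound_mult` times the residual RMSE of that fit are flagged.
#'    A single gross outlier inflates the RMSE, so this screen isolates
#'    compounds far off the trend rather than tail noise; several
#'    outliers of similar magnitude can partially mask one another,
#'    which is why flags are advisory and carried with diagnostics.
#' 2. *Entry level*: entries whose log Koc deviates from their compound's
#'    median log Koc by more than `entry_threshold` log units are flagged.
#'
#' Only entries with `corg > 0` enter the screens (Koc is undefined
#' otherwise). Flags are advisory: nothing is dropped, and each flag
#' carries a reason.
#'
#' @param dataset A harmonized dataset (accepted rows of
#'   [harmonize_sorption()]) with `compound_id`, `kd`, `corg`.
#' @param registry Compound registry providing `log_kow`.
#' @param compound_mult Residual threshold in multiples of the RMSE.
#' @param entry_threshold Within-compound deviation threshold (log units).
#' @return `dataset` with `outlier` and `outlier_reason` columns and an
#'   `outlier_diagnostics` attribute (per-compound table, fit
#'   coefficients, RMSE and threshold).
#' @export
flag_outliers <- function(dataset, registry = pfas_registry(),
                          compound_mult = 2, entry_threshold = 1.5) {
  dataset <- tibble::as_tibble(dataset)
  stopifnot(all(c("compound_id", "kd", "corg") %in% names(dataset)))
  usable <- !is.na(dataset$corg) & dataset$corg > 0 & !is.na(dataset$kd)
  log_koc <- rep(NA_real_, nrow(dataset))
  log_koc[usable] <- log10(koc_of(dataset$kd[usable], dataset$corg[usable]))

  per_compound <- tibble::tibble(compound_id = dataset$compound_id,
                                 log_koc = log_koc)[usable, ]
  per_compound <- dplyr::summarise(
    dplyr::group_by(per_compound, .data$compound_id),
    mean_log_koc = mean(.data$log_koc),
    median_log_koc = stats::median(.data$log_koc),
    n = dplyr::n(), .groups = "drop"
  )
  per_compound$log_kow <-
    registry$log_kow[match(per_compound$compound_id, registry$id)]
  per_compound <- per_compound[!is.na(per_compound$log_kow), ]
  per_compound <- per_compound[order(per_compound$compound_id), ]
  if (nrow(per_compound) < 3) {
    stop("need at least 3 compounds with usable Koc to fit the ",
         "log Koc - log Kow screen", call. = FALSE)
  }

  fit <- stats::lm(mean_log_koc ~ log_kow, data = per_compound)
  diag_res <- stats::resid(fit)
  diag_rmse <- sqrt(mean(diag_res^2))
  # floor keeps float noise on an exactly collinear set from flagging
  flagged <- abs(diag_res) > pmax(compound_mult * diag_rmse, 1e-8)
  per_compound$residual <- unname(diag_res)
  per_compound$flagged <- unname(flagged)

  flagged_compounds <- per_compound$compound_id[flagged]
  out <- dataset
  out$outlier <- FALSE
  out$outlier_reason <- NA_character_
  is_cmp <- out$compound_id %in% flagged_compounds
  out$outlier[is_cmp] <- TRUE
  out$outlier_reason[is_cmp] <- "compound_trend"

  med <- per_compound$median_log_koc[match(out$compound_id,
                                           per_compound$compound_id)]
  dev <- abs(log_koc - med)
  is_ent <- !is.na(dev) & dev > entry_threshold & !out$outlier
  out$outlier[is_ent] <- TRUE
  out$outlier_reason[is_ent] <- "entry_deviation"

  attr(out, "outlier_diagnostics") <- list(
    per_compound = per_compound,
    coefficients = stats::coef(fit),
    rmse = diag_rmse,
    compound_threshold = compound_mult * diag_rmse,
    entry_threshold = entry_threshold
  )
  out
}

.sorption_cols <- c("entry_id", "compound_id", "study_id", "ph", "cec",
                    "corg", "sand", "silt", "clay", "fe", "al", "kd", "koc",
                    "isotherm_model", "isotherm_p1", "isotherm_p2",
                    "source", "outlier")

#' Read or write a sorption dataset CSV
#'
#' The documented schema has columns `entry_id`, `compound_id`,
#' `study_id`, `ph`, `cec`, `corg`, `sand`, `silt`, `clay`, `fe`, `al`,
#' `kd`, `koc`, `isotherm_model`, `isotherm_p1`, `isotherm_p2`, `source`,
#' `outlier`; missing values are empty fields. Extra columns are carried
#' through.
#'
#' @param path CSV path.
#' @return `read_sorption_csv()` returns a tibble.
#' @export
read_sorption_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  header <- gsub("\"", "", header)
  types <- list(
    entry_id = "c", compound_id = "c", study_id = "c",
    isotherm_model = "c", source = "c", outlier = "l"
  )
  spec <- do.call(readr::cols,
                  c(types[intersect(names(types), header)],
                    .default = readr::col_double()))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = spec)
}

#' @rdname read_sorption_csv
#' @param dataset Tibble to write.
#' @export
write_sorption_csv <- function(dataset, path) {
  readr::write_csv(dataset, path, na = "")
  invisible(path)
}
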