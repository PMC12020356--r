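#' Generate a synthetic reference soil table
#'
#' Draws soils with the distributional structure of a worldwide topsoil
#' repository sample: organic carbon log-normal and skewed low (median
#' below 2%), truncated to [0.03, 54]%; pH from a truncated normal on
#' [2.8, 9.0] whose centre drops with log Corg (organic topsoils run
#' acidic), overall mean near 6.2; sand/silt/clay from a Dirichlet
#' scaled to 100% with clay capped at 69% (rejection); CEC correlated
#' with organic carbon plus a clay term, truncated to
#' [0.1, 140] cmol+ kg^-1. The cross-property correlations are what make
#' K-nearest-neighbour imputation of a missing property informative.
#' Seed-reproducible; suitable for training the KNN imputer offline.
#'
#' @param n Number of soils (>= 10).
#' @param seed Integer seed.
#' @return A complete soil tibble (`ph`, `cec`, `corg`, `sand`, `silt`,
#'   `clay`).
#' @export
gen_reference_soils <- function(n, seed = 1) {
  if (!is.numeric(n) || n < 10) stop("need n >= 10", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  corg <- rtrunc_lnorm(n, meanlog = 0, sdlog = 1.2, lower = 0.03, upper = 54)
  # organic topsoils run acidic: pH centred lower at high Corg
  ph <- vapply(6.2 - 1.0 * log10(corg), function(m) {
    rtrunc_norm(1, mean = m, sd = 0.95, lower = 2.8, upper = 9.0)
  }, numeric(1))
  tex <- matrix(NA_real_, n, 3)
  need <- rep(TRUE, n)
  while (any(need)) {
    m <- sum(need)
    g <- cbind(stats::rgamma(m, 2.2), stats::rgamma(m, 2.0),
               stats::rgamma(m, 1.2))
    t100 <- 100 * g / rowSums(g)
    ok <- t100[, 3] <= 69
    idx <- which(need)[ok]
    tex[idx, ] <- t100[ok, , drop = FALSE]
    need[idx] <- FALSE
  }
  cec <- pmin(pmax(2 + 2.2 * corg + 0.15 * tex[, 3] +
                     stats::rnorm(n, 0, 3), 0.1), 140)
  tibble::tibble(ph = ph, cec = cec, corg = corg,
                 sand = tex[, 1], silt = tex[, 2], clay = tex[, 3])
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  u <- stats::runif(n, stats::plnorm(lower, meanlog, sdlog),
                    stats::plnorm(upper, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

#' Ground-truth rule for the synthetic sorption generator
#'
#' Defines the latent linear rule
#' `log Kd = b0 + b_kow * log Kow + b_corg * log10(Corg) +
#'  b_cd * charge_density + b_ph * pH + eps`, `eps ~ N(0, sigma^2)`.
#' The default coefficients reproduce the directions seen in field
#' data (sorption rising with hydrophobicity and organic carbon,
#' falling with pH, with a minor electrostatic term) and a log Kd span
#' of roughly five orders of magnitude.
#'
#' @param b0,b_kow,b_corg,b_cd,b_ph Coefficients of the latent rule.
#' @param sigma Residual noise SD (log Kd units).
#' @return A named list of class `pssm_effect_spec`.
#' @export
effect_spec <- function(b0 = 0.2, b_kow = 0.45, b_corg = 0.6,
                        b_cd = 5e-4, b_ph = -0.15, sigma = 0.3) {
  vals <- c(b0, b_kow, b_corg, b_cd, b_ph, sigma)
  if (!is.numeric(vals) || length(vals) != 6 || any(!is.finite(vals)) ||
      sigma < 0) {
    stop("invalid effect specification", call. = FALSE)
  }
  structure(list(b0 = b0, b_kow = b_kow, b_corg = b_corg, b_cd = b_cd,
                 b_ph = b_ph, sigma = sigma),
            class = "pssm_effect_spec")
}

#' Generate a synthetic sorption dataset with known ground truth
#'
#' Samples compounds from the registry and soils from
#' [gen_reference_soils()], computes the speciation-derived descriptors
#' at each soil's pH, and emits sorption entries whose log Kd follows
#' the latent rule of an [effect_spec()] plus Gaussian noise. The
#' noiseless latent target is returned in `.latent` for
#' parameter-recovery tests. Optionally, whole compounds can be planted
#' as outliers by displacing all their entries by a fixed offset, which
#' moves them off the log Koc - log Kow trend by that amount.
#'
#' @param n_entries Number of sorption entries.
#' @param seed Integer seed.
#' @param effect An [effect_spec()].
#' @param registry Compound registry to sample from.
#' @param compounds Compound ids to draw from (default: all non-neutral
#'   and neutral compounds with finite log Kow).
#' @param outlier_compounds Number of compounds to displace.
#' @param outlier_offset Displacement in log Kd units.
#' @return A tibble in the harmonized-entry layout (`entry_id`,
#'   `compound_id`, `study_id`, soil columns, `kd`, `log_kd`, `source`)
#'   plus `.latent` and `.outlier_truth`.
#' @export
gen_sorption_dataset <- function(n_entries, seed = 1,
                                 effect = effect_spec(),
                                 registry = pfas_registry(),
                                 compounds = NULL,
                                 outlier_compounds = 0,
                                 outlier_offset = 3) {
  stopifnot(inherits(effect, "pssm_effect_spec"))
  if (is.null(compounds)) {
    compounds <- registry$id[is.finite(registry$log_kow)]
  }
  soils <- gen_reference_soils(n_entries, seed = seed)
  set.seed(seed + 1L)
  entries <- soils
  entries$entry_id <- sprintf("syn%05d", seq_len(n_entries))
  entries$compound_id <- sample(compounds, n_entries, replace = TRUE)
  entries$study_id <- sprintf("study%02d",
                              sample.int(20, n_entries, replace = TRUE))
  feats <- assemble_features(entries, registry)
  latent <- effect$b0 +
    effect$b_kow * feats$log_kow +
    effect$b_corg * log10(feats$corg) +
    effect$b_cd * feats$charge_density +
    effect$b_ph * feats$ph
  out_truth <- rep(FALSE, n_entries)
  if (outlier_compounds > 0) {
    planted <- sample(unique(entries$compound_id),
                      min(outlier_compounds,
                          length(unique(entries$compound_id))))
    hit <- entries$compound_id %in% planted
    latent[hit] <- latent[hit] + outlier_offset
    out_truth[hit] <- TRUE
  }
  log_kd <- latent + stats::rnorm(n_entries, 0, effect$sigma)
  out <- entries[, c("entry_id", "compound_id", "study_id", "ph", "cec",
                     "corg", "sand", "silt", "clay")]
  out$kd <- 10^log_kd
  out$log_kd <- log_kd
  out$source <- "direct"
  out$.latent <- latent
  out$.outlier_truth <- out_truth
  out
}
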