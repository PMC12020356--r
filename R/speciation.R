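#' pH-dependent speciation of a PFAS compound
#'
#' Computes the relative abundance of each ionic species of a compound at
#' a given pH from its acid dissociation constants, following the
#' Henderson-Hasselbalch closed forms. For a monoprotic acid the
#' protonated fraction is \eqn{1/(1+10^{pH-pKa})}; for a diprotic acid
#' the three fractions follow the standard alpha formulas in
#' \eqn{10^{pH-pKa_1}} and \eqn{10^{2pH-pKa_1-pKa_2}}; a compound with no
#' ionizable group has a single species with abundance 1.
#'
#' @param compound A one-row registry tibble, or a character key resolved
#'   through `registry` via [registry_lookup()].
#' @param ph Soil/solution pH (finite scalar).
#' @param registry Registry used to resolve character `compound` keys.
#' @return A tibble of class `pfas_speciation` with one row per species
#'   (`species`, `protonation_level`, `z`, `mw`, `abundance`) and
#'   attributes `ph`, `compound_id`, `net_charge`, `mw_effective`,
#'   `charge_density`.
#' @seealso [mw_effective()], [net_charge()], [charge_density()],
#'   [speciation_profile()]
#' @examples
#' speciate("TFA", ph = 7)
#' charge_density(speciate("TFA", ph = 7))
#' @export
speciate <- function(compound, ph, registry = pfas_registry()) {
  if (is.character(compound)) compound <- registry_lookup(registry, compound)
  stopifnot(is.data.frame(compound), nrow(compound) == 1L)
  if (!is.numeric(ph) || length(ph) != 1L || !is.finite(ph)) {
    stop("`ph` must be a finite numeric scalar", call. = FALSE)
  }
  sp <- compound$species[[1]]
  if (!is.data.frame(sp) || nrow(sp) < 1L) {
    stop("compound '", compound$id, "' has a malformed species list",
         call. = FALSE)
  }
  pka <- c(compound$pka1, compound$pka2)
  pka <- pka[!is.na(pka)]
  ab <- alpha_fractions(ph, pka)
  if (length(ab) != nrow(sp)) {
    stop("compound '", compound$id, "': species/pKa count mismatch",
         call. = FALSE)
  }
  out <- sp
  out$abundance <- ab
  out <- tibble::as_tibble(out)
  class(out) <- c("pfas_speciation", class(out))
  attr(out, "ph") <- ph
  attr(out, "compound_id") <- compound$id
  attr(out, "net_charge") <- sum(ab * sp$z)
  attr(out, "mw_effective") <- sum(ab * sp$mw)
  attr(out, "charge_density") <- .faraday * sum(ab * sp$z) / sum(ab * sp$mw)
  out
}

# Closed-form Henderson-Hasselbalch alpha fractions, ordered from fully
# protonated to fully deprotonated. Numerically stable: terms are computed
# in log10 space and shifted by their maximum before exponentiation.
alpha_fractions <- function(ph, pka) {
  n <- length(pka)
  if (n == 0) return(1)
  log_terms <- switch(as.character(n),
    "1" = c(0, ph - pka[1]),
    "2" = c(0, ph - pka[1], 2 * ph - pka[1] - pka[2]),
    stop("at most two pKa values are supported", call. = FALSE)
  )
  t <- 10^(log_terms - max(log_terms))
  t / sum(t)
}

#' Abundance-weighted effective molecular weight
#'
#' The effective molecular weight at a given pH is the abundance-weighted
#' mean of the species molecular weights, reflecting the protonated and
#' deprotonated forms actually present.
#'
#' @param state A `pfas_speciation` tibble from [speciate()].
#' @return Effective molecular weight in g mol^-1.
#' @export
mw_effective <- function(state) {
  check_speciation(state)
  sum(state$abundance * state$mw)
}

#' Abundance-weighted net molar charge
#'
#' @param state A `pfas_speciation` tibble from [speciate()].
#' @return Dimensionless net charge \eqn{\sum_i A_i z_i}.
#' @export
net_charge <- function(state) {
  check_speciation(state)
  sum(state$abundance * state$z)
}

#' Charge density descriptor
#'
#' The charge density is the Faraday constant (96485 C mol^-1) times the
#' abundance-weighted net molar charge, divided by the effective
#' molecular weight: positive for net-cationic, about zero for neutral or
#' zwitterionic, and negative for net-anionic speciation. It summarizes
#' the electrostatic character of a compound at a given soil pH in one
#' number (fully deprotonated trifluoroacetate, for example, sits near
#' -854 C g^-1).
#'
#' @param state A `pfas_speciation` tibble from [speciate()].
#' @return Charge density in C g^-1.
#' @examples
#' charge_density(speciate("TFA", ph = 7))
#' @export
charge_density <- function(state) {
  check_speciation(state)
  mw <- mw_effective(state)
  if (!is.finite(mw) || mw <= 0) {
    stop("effective molecular weight must be positive", call. = FALSE)
  }
  .faraday * net_charge(state) / mw
}

check_speciation <- function(state) {
  if (!inherits(state, "pfas_speciation")) {
    stop("`state` must come from speciate()", call. = FALSE)
  }
  if (length(state$abundance) != length(state$mw)) {
    stop("species/abundance length mismatch", call. = FALSE)
  }
  invisible(state)
}

#' Speciation profile over a pH range
#'
#' Evaluates [speciate()] over a vector of pH values and returns a long
#' table of per-species abundances together with the pH-wise net charge,
#' effective molecular weight and charge density.
#'
#' @inheritParams speciate
#' @param ph Numeric vector of pH values.
#' @return A tibble of class `pfas_speciation_profile` with columns
#'   `compound_id`, `ph`, `species`, `z`, `mw`, `abundance`,
#'   `net_charge`, `mw_effective`, `charge_density`.
#' @examples
#' prof <- speciation_profile("PFOSA", ph = seq(2, 12, by = 0.25))
#' @export
speciation_profile <- function(compound, ph = seq(0, 14, by = 0.1),
                               registry = pfas_registry()) {
  if (is.character(compound)) compound <- registry_lookup(registry, compound)
  out <- purrr::map_dfr(ph, function(p) {
    st <- speciate(compound, p, registry)
    tibble::tibble(
      compound_id = attr(st, "compound_id"),
      ph = p,
      species = st$species,
      z = st$z,
      mw = st$mw,
      abundance = st$abundance,
      net_charge = attr(st, "net_charge"),
      mw_effective = attr(st, "mw_effective"),
      charge_density = attr(st, "charge_density")
    )
  })
  class(out) <- c("pfas_speciation_profile", class(out))
  out
}

#' @export
autoplot.pfas_speciation_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ph, y = .data$abundance,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = "relative abundance",
                  title = unique(object$compound_id)) +
    ggplot2::theme_minimal()
}

#' @export
print.pfas_speciation <- function(x, ...) {
  cat("<pfas_speciation> ", attr(x, "compound_id"),
      " at pH ", format(attr(x, "ph")), "\n", sep = "")
  cat("  net charge: ", format(attr(x, "net_charge"), digits = 4),
      "  effective MW: ", format(attr(x, "mw_effective"), digits = 6),
      " g/mol\n  charge density: ",
      format(attr(x, "charge_density"), digits = 5), " C/g\n", sep = "")
  print(tibble::as_tibble(unclass(x)[c("species", "z", "mw", "abundance")]))
  invisible(x)
}
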