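# Standard atomic weights (IUPAC 2021, 3 decimals) for elements found in
# PFAS empirical formulas.
.atomic_weights <- c(
  C = 12.011, H = 1.008, F = 18.998, O = 15.999, N = 14.007,
  S = 32.06, P = 30.974, Cl = 35.45, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098
)

parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula) {
    stop("malformed empirical formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  unknown <- setdiff(el, names(.atomic_weights))
  if (length(unknown)) {
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(n, el, sum)
  counts[unique(el)]
}

#' Molar mass from an empirical formula
#'
#' Computes the molar mass of an empirical formula string such as
#' `"C8HF15O2"` using standard atomic weights to three decimals. Used to
#' validate the molecular weights stored in the PFAS registry.
#'
#' @param formula Character vector of empirical formulas.
#' @return Numeric vector of molar masses in g mol^-1.
#' @examples
#' formula_mw("C2HF3O2")  # trifluoroacetic acid, ~114.02
#' @export
formula_mw <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    sum(.atomic_weights[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Fluorine mass fraction of an empirical formula
#'
#' @param formula Character vector of empirical formulas.
#' @return Fluorine mass fraction (percent w/w).
#' @examples
#' fluorine_fraction("C8HF15O2")  # PFOA, ~69% w/w
#' @export
fluorine_fraction <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    nf <- if ("F" %in% names(counts)) counts[["F"]] else 0
    100 * nf * .atomic_weights[["F"]] / sum(.atomic_weights[names(counts)] * counts)
  }, numeric(1), USE.NAMES = FALSE)
}
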