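# Shared fixtures: tiny registries and datasets built in code.

# A minimal registry: one monoprotic acid, one diprotic acid, one neutral
# compound. Values chosen for hand-checkable arithmetic.
toy_registry <- function() {
  raw <- tibble::tibble(
    id = c("monoacid", "diacid", "neutral"),
    name = c("Mono acid", "Di acid", "Neutral compound"),
    abbreviation = c("MA", "DA", "NEU"),
    cas = NA_character_,
    formula = c("C2HF3O2", "C6H2F13O3P", "C8H5F13O"),
    mw_neutral = c(114.02, 400.03, 364.1),
    log_kow = c(1.0, 3.0, 5.0),
    solubility = c(1e5, 1e3, 100),
    pka1 = c(5, 3, NA),
    pka2 = c(NA, 6, NA),
    species_charges = c("0;-1", "0;-1;-2", "0"),
    subfamily = c("PFCA", "PFPA", "FTOH"),
    n_fluorinated_carbons = c(1L, 6L, 6L),
    provisional = TRUE
  )
  pfasorption:::build_species(raw)
}

# Complete soil table small enough for exhaustive-oracle checks.
tiny_soils <- function(n = 12, seed = 1) {
  gen_reference_soils(max(n, 10), seed = seed)[seq_len(n), ]
}

# Entry table on an exact Koc-Kow line: log Koc = slope*logKow + icpt,
# one entry per compound, corg fixed so Kd is recoverable exactly.
line_dataset <- function(log_kows, slope = 0.6, icpt = 0.5, corg = 2) {
  n <- length(log_kows)
  log_koc <- slope * log_kows + icpt
  tibble::tibble(
    entry_id = paste0("e", seq_len(n)),
    compound_id = paste0("c", seq_len(n)),
    study_id = "s1",
    ph = 6, cec = 10, corg = corg, sand = 40, silt = 40, clay = 20,
    kd = 10^log_koc * corg / 100,
    log_kd = log_koc + log10(corg / 100)
  )
}

line_registry <- function(log_kows) {
  n <- length(log_kows)
  raw <- tibble::tibble(
    id = paste0("c", seq_len(n)),
    name = paste0("Compound ", seq_len(n)),
    abbreviation = paste0("C", seq_len(n)),
    cas = NA_character_,
    formula = "C2HF3O2",
    mw_neutral = 114.02 + 50 * seq_len(n),
    log_kow = log_kows,
    solubility = 1e4,
    pka1 = 0.5, pka2 = NA_real_,
    species_charges = "0;-1",
    subfamily = "PFCA",
    n_fluorinated_carbons = seq_len(n),
    provisional = TRUE
  )
  pfasorption:::build_species(raw)
}

# Small stacking config for plumbing tests (full defaults are exercised
# in the acceptance suite).
fast_config <- function() {
  pssm_config(n_trees = 100L, gb_rounds = 100L, mlp_maxit = 500L,
              cv_folds = 3L)
}
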