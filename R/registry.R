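# Faraday constant [C mol^-1], CODATA rounded.
.faraday <- 96485

#' The bundled PFAS compound registry
#'
#' Returns the compound registry shipped with the package: identities
#' (name, abbreviation, CAS number), physicochemical properties (empirical
#' formula, neutral molecular weight, log Kow, water solubility, up to two
#' pKa values), the per-species net charges from fully protonated to fully
#' deprotonated, subfamily membership and the number of fluorinated
#' carbons. The table covers the C2-C14 perfluorocarboxylic acids,
#' C4-C10 perfluorosulfonic acids, perfluorophosphonic and phosphinic
#' acids, perfluoroalkane sulfonamides and sulfonamidoacetic acids,
#' perfluoroether carboxylates and sulfonates, fluorotelomer alcohols and
#' sulfonates, and cationic/zwitterionic (betaine- and amine-type)
#' compounds commonly studied in soil sorption work.
#'
#' Entries with `provisional = TRUE` carry curated literature-typical
#' property values (and, for cationic/zwitterionic compounds, assumed
#' speciation diagrams: betaines as permanent zwitterions, quaternary
#' ammonium compounds as permanent cations). They are stand-ins suitable
#' for method development and synthetic studies; replace them with
#' measured values via [read_pfas_registry()] for compound-critical work.
#'
#' @return A tibble with one row per compound and a `species` list-column
#'   (one tibble per compound: `species`, `protonation_level`, `z`, `mw`).
#' @seealso [speciate()], [read_pfas_registry()], [registry_lookup()]
#' @examples
#' reg <- pfas_registry()
#' dplyr::filter(reg, subfamily == "PFCA")
#' @export
pfas_registry <- function() {
  path <- system.file("extdata", "pfas_registry.csv", package = "pfasorption",
                      mustWork = TRUE)
  read_pfas_registry(path)
}

#' Read a PFAS compound registry from CSV or JSON
#'
#' The CSV dialect has one row per compound with columns `id`, `name`,
#' `abbreviation`, `cas`, `formula`, `mw_neutral`, `log_kow`,
#' `solubility`, `pka1`, `pka2`, `species_charges` (semicolon-separated
#' net charges ordered from fully protonated to fully deprotonated),
#' `subfamily`, `n_fluorinated_carbons`, `provisional`. The JSON dialect
#' is an array of objects with the same field names (`pka` may be given
#' as an array instead of `pka1`/`pka2`). CAS numbers, when present, are
#' validated by their checksum digit.
#'
#' @param path Path to a `.csv` or `.json` registry file.
#' @return A validated registry tibble (see [pfas_registry()]).
#' @export
read_pfas_registry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    raw <- tibble::as_tibble(raw)
    if ("pka" %in% names(raw) && !"pka1" %in% names(raw)) {
      pk <- lapply(raw$pka, function(p) c(as.numeric(p), NA_real_, NA_real_)[1:2])
      raw$pka1 <- vapply(pk, `[`, numeric(1), 1)
      raw$pka2 <- vapply(pk, `[`, numeric(1), 2)
      raw$pka <- NULL
    }
  } else {
    raw <- readr::read_csv(
      path, show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(
        id = "c", name = "c", abbreviation = "c", cas = "c", formula = "c",
        mw_neutral = "d", log_kow = "d", solubility = "d",
        pka1 = "d", pka2 = "d", species_charges = "c", subfamily = "c",
        n_fluorinated_carbons = "i", provisional = "l"
      )
    )
  }
  validate_registry(build_species(raw))
}

build_species <- function(reg) {
  reg$species <- purrr::pmap(
    list(reg$id, reg$mw_neutral, reg$pka1, reg$pka2, reg$species_charges),
    function(id, mw0, pka1, pka2, charges) {
      z <- as.integer(strsplit(charges, ";", fixed = TRUE)[[1]])
      n_pka <- sum(!is.na(c(pka1, pka2)))
      if (length(z) != n_pka + 1L) {
        stop("registry entry '", id, "': ", length(z), " species but ",
             n_pka, " pKa value(s)", call. = FALSE)
      }
      # protonation levels run from fully protonated (n_pka) down to 0;
      # species MW is anchored at the neutral (z == 0) species when one
      # exists, else at the single permanently charged species.
      p <- seq(n_pka, 0L)
      anchor <- if (any(z == 0L)) which(z == 0L)[1] else 1L
      mw <- mw0 + 1.008 * (p - p[anchor])
      tibble::tibble(
        species = paste0(id, "_", ifelse(z > 0, paste0("+", z), z)),
        protonation_level = p, z = z, mw = mw
      )
    }
  )
  reg
}

#' Validate a PFAS registry
#'
#' Checks the registry invariants: positive molecular weights, at most two
#' pKa values sorted ascending, one more ionic species than pKa values,
#' adjacent species differing by one proton mass, non-increasing species
#' charge with deprotonation, and CAS checksum validity.
#'
#' @param registry A registry tibble with a `species` list-column.
#' @return The registry, invisibly classed, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  req <- c("id", "mw_neutral", "log_kow", "species_charges", "subfamily",
           "n_fluorinated_carbons", "species")
  missing <- setdiff(req, names(registry))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(registry$id)) stop("duplicate compound ids", call. = FALSE)
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    sp <- r$species[[1]]
    if (!is.na(r$mw_neutral) && r$mw_neutral <= 0) {
      stop("compound '", r$id, "': mw_neutral must be > 0", call. = FALSE)
    }
    pka <- c(r$pka1, r$pka2)
    pka <- pka[!is.na(pka)]
    if (length(pka) == 2 && diff(pka) < 0) {
      stop("compound '", r$id, "': pKa values must be sorted ascending",
           call. = FALSE)
    }
    if (nrow(sp) != length(pka) + 1L) {
      stop("compound '", r$id, "': species/pKa count mismatch", call. = FALSE)
    }
    if (any(sp$mw <= 0)) stop("compound '", r$id, "': species mw <= 0", call. = FALSE)
    if (nrow(sp) > 1) {
      if (any(abs(diff(sp$mw) + 1.008) > 1e-9)) {
        stop("compound '", r$id,
             "': adjacent species must differ by one proton mass", call. = FALSE)
      }
      if (any(diff(sp$z) != -1L)) {
        stop("compound '", r$id,
             "': each deprotonation must lower the charge by one", call. = FALSE)
      }
    }
    if (!is.na(r$cas) && nzchar(r$cas) && !cas_is_valid(r$cas)) {
      stop("compound '", r$id, "': CAS checksum invalid (", r$cas, ")",
           call. = FALSE)
    }
  }
  registry
}

#' Validate a CAS registry number by its checksum digit
#'
#' @param cas Character vector of CAS numbers (`"NNNNN-NN-N"`).
#' @return Logical vector.
#' @examples
#' cas_is_valid("335-67-1")  # PFOA
#' @export
cas_is_valid <- function(cas) {
  vapply(cas, function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    d <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    check <- d[length(d)]
    rest <- rev(d[-length(d)])
    sum(rest * seq_along(rest)) %% 10 == check
  }, logical(1), USE.NAMES = FALSE)
}

#' Look up a compound in a registry
#'
#' Matches `key` against compound id, abbreviation, CAS number, or full
#' name (case-insensitively, in that order).
#'
#' @param registry A registry tibble.
#' @param key Character scalar identifying the compound.
#' @return The matching one-row registry tibble.
#' @examples
#' registry_lookup(pfas_registry(), "PFOA")
#' @export
registry_lookup <- function(registry, key) {
  stopifnot(is.character(key), length(key) == 1L)
  k <- tolower(key)
  for (col in c("id", "abbreviation", "cas", "name")) {
    hit <- which(tolower(registry[[col]]) == k)
    if (length(hit)) return(registry[hit[1], ])
  }
  stop("compound '", key, "' not found in registry", call. = FALSE)
}
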