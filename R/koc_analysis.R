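.functional_groups <- c(
  PFCA = "carboxylate", PFSA = "sulfonate", FTS = "telomer sulfonate",
  FOSA = "sulfonamide", FTOH = "telomer alcohol", PFPA = "phosphonate",
  PFPiA = "phosphinate", PFECA = "ether carboxylate",
  PFAES = "ether sulfonate", FOSAA = "sulfonamidoacetate",
  cationic_zwitterionic = "cationic/zwitterionic"
)

#' Grouped log Koc summaries
#'
#' Converts each entry's Kd to the organic-carbon-normalized coefficient
#' (`Koc = Kd / (corg/100)`; entries with `corg <= 0` are dropped) and
#' summarizes log10 Koc by compound subfamily, number of fluorinated
#' carbons, or head-group functional group. Single-entry groups report a
#' missing SD. Groups are ordered by chain length.
#'
#' @param dataset Harmonized dataset with `compound_id`, `kd`, `corg`.
#' @param registry Compound registry.
#' @param group_by `"subfamily"`, `"n_fluorinated_carbons"`, or
#'   `"functional_group"`.
#' @return Tibble with `group`, `n`, `mean_log_koc`, `sd_log_koc`,
#'   `n_fluorinated_carbons` (group mean, used for ordering).
#' @export
koc_summary <- function(dataset, registry = pfas_registry(),
                        group_by = c("subfamily", "n_fluorinated_carbons",
                                     "functional_group")) {
  group_by <- match.arg(group_by)
  dataset <- tibble::as_tibble(dataset)
  idx <- match(dataset$compound_id, registry$id)
  if (anyNA(idx)) {
    stop("compound(s) not in registry: ",
         paste(unique(dataset$compound_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  usable <- !is.na(dataset$corg) & dataset$corg > 0 & !is.na(dataset$kd)
  if (!all(usable)) {
    message("dropping ", sum(!usable), " entries without usable corg/kd")
  }
  d <- dataset[usable, ]
  idx <- idx[usable]
  d$log_koc <- log10(koc_of(d$kd, d$corg))
  d$n_fluorinated_carbons <- registry$n_fluorinated_carbons[idx]
  d$group <- switch(group_by,
    subfamily = registry$subfamily[idx],
    n_fluorinated_carbons = as.character(registry$n_fluorinated_carbons[idx]),
    functional_group = unname(.functional_groups[registry$subfamily[idx]])
  )
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$group),
    n = dplyr::n(),
    mean_log_koc = mean(.data$log_koc),
    sd_log_koc = if (dplyr::n() > 1) stats::sd(.data$log_koc) else NA_real_,
    n_fluorinated_carbons = mean(.data$n_fluorinated_carbons),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$n_fluorinated_carbons)
}

#' Group populations into homogeneous subsets
#'
#' Tests whether groups share a common mean using Welch's ANOVA
#' (heteroscedasticity-robust) followed by Games-Howell pairwise
#' comparisons (studentized-range reference distribution with
#' Welch-Satterthwaite degrees of freedom, which controls the
#' family-wise error rate). Groups that are never significantly
#' different share a letter in the compact letter display.
#'
#' @param data Data frame with a numeric value column and a grouping
#'   column.
#' @param value,group Column names (character) of the value and group.
#' @param alpha Significance level for the pairwise tests.
#' @return A list of class `pssm_group_comparison`: `groups` (per-group
#'   n/mean/sd plus a `letters` column), `pairwise` (Games-Howell
#'   table), and `welch` (the overall Welch ANOVA htest).
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  stopifnot(value %in% names(data), group %in% names(data))
  y <- data[[value]]
  g <- as.character(data[[group]])
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  stats_tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(y = y, g = g), .data$g),
    n = dplyr::n(), mean = mean(.data$y),
    sd = if (dplyr::n() > 1) stats::sd(.data$y) else NA_real_,
    .groups = "drop"
  )
  if (nrow(stats_tab) < 2) stop("need at least two groups", call. = FALSE)
  if (all(stats_tab$n < 2)) {
    stop("all groups have a single observation; nothing to test",
         call. = FALSE)
  }
  usable <- stats_tab$n >= 2
  if (any(!usable)) {
    message("dropping group(s) with n < 2: ",
            paste(stats_tab$g[!usable], collapse = ", "))
    stats_tab <- stats_tab[usable, ]
    keep2 <- g %in% stats_tab$g
    y <- y[keep2]; g <- g[keep2]
  }
  k <- nrow(stats_tab)
  welch <- stats::oneway.test(y ~ g, var.equal = FALSE)

  pairs <- utils::combn(seq_len(k), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    v1 <- stats_tab$sd[i1]^2 / stats_tab$n[i1]
    v2 <- stats_tab$sd[i2]^2 / stats_tab$n[i2]
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (stats_tab$n[i1] - 1) +
                         v2^2 / (stats_tab$n[i2] - 1))
    diff <- stats_tab$mean[i1] - stats_tab$mean[i2]
    tstat <- if (se > 0) abs(diff) / se else Inf
    p <- stats::ptukey(tstat * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    tibble::tibble(group1 = stats_tab$g[i1], group2 = stats_tab$g[i2],
                   diff = diff, se = se, df = df, statistic = tstat,
                   p_adj = p, significant = p < alpha)
  })

  ord <- order(stats_tab$mean)
  letters_col <- letter_display(stats_tab$g[ord], pairwise)
  stats_tab$letters <- letters_col[match(stats_tab$g, stats_tab$g[ord])]

  structure(list(groups = stats_tab, pairwise = pairwise, welch = welch,
                 alpha = alpha),
            class = "pssm_group_comparison")
}

# compact letter display (insert-and-absorb) for groups ordered by mean
letter_display <- function(groups, pairwise) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (j in seq_len(nrow(pairwise))) {
    if (pairwise$significant[j]) {
      g1 <- pairwise$group1[j]; g2 <- pairwise$group2[j]
      sig[g1, g2] <- sig[g2, g1] <- TRUE
    }
  }
  cols <- list(rep(TRUE, k))  # columns of group membership
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      if (!sig[a, b]) next
      split_cols <- list()
      for (col in cols) {
        if (col[a] && col[b]) {
          c1 <- col; c1[a] <- FALSE
          c2 <- col; c2[b] <- FALSE
          split_cols <- c(split_cols, list(c1, c2))
        } else {
          split_cols <- c(split_cols, list(col))
        }
      }
      # absorb: drop any column whose members are a subset of another's
      keep <- rep(TRUE, length(split_cols))
      for (i in seq_along(split_cols)) {
        for (j in seq_along(split_cols)) {
          if (i == j || !keep[i] || !keep[j]) next
          subset_ij <- all(split_cols[[j]] | !split_cols[[i]])
          if (subset_ij &&
              (!identical(split_cols[[i]], split_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- split_cols[keep]
    }
  }
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}

#' @export
print.pssm_group_comparison <- function(x, ...) {
  cat("<pssm_group_comparison> Welch ANOVA F =",
      format(unname(x$welch$statistic), digits = 4),
      " p =", format(x$welch$p.value, digits = 3), "\n")
  print(x$groups)
  invisible(x)
}

#' @export
tidy.pssm_group_comparison <- function(x, ...) x$groups

#' Regression of per-compound mean log Koc on log Kow
#'
#' Averages log Koc within each compound, joins the registry log Kow,
#' and fits the OLS line summarizing the hydrophobicity trend. Outlier
#' entries (flagged by [flag_outliers()] or in an `outlier` column) can
#' be excluded first.
#'
#' @param dataset Harmonized dataset with `compound_id`, `kd`, `corg`
#'   and optionally `outlier`.
#' @param registry Compound registry.
#' @param exclude_outliers Drop rows with `outlier == TRUE` first.
#' @return One-row tibble `slope`, `intercept`, `r2`, `n` (compounds),
#'   with the per-compound table as attribute `compounds`.
#' @export
koc_kow_regression <- function(dataset, registry = pfas_registry(),
                               exclude_outliers = TRUE) {
  dataset <- tibble::as_tibble(dataset)
  if (exclude_outliers && "outlier" %in% names(dataset)) {
    dataset <- dataset[!isTRUE_vec(dataset$outlier), ]
  }
  usable <- !is.na(dataset$corg) & dataset$corg > 0 & !is.na(dataset$kd)
  d <- dataset[usable, ]
  d$log_koc <- log10(koc_of(d$kd, d$corg))
  per <- dplyr::summarise(dplyr::group_by(d, .data$compound_id),
                          mean_log_koc = mean(.data$log_koc),
                          n_entries = dplyr::n(), .groups = "drop")
  per$log_kow <- registry$log_kow[match(per$compound_id, registry$id)]
  per <- per[!is.na(per$log_kow), ]
  per <- per[order(per$compound_id), ]
  if (nrow(per) < 3) stop("need at least 3 compounds", call. = FALSE)
  if (stats::var(per$log_kow) == 0) {
    stop("log Kow has no variance across compounds", call. = FALSE)
  }
  fit <- stats::lm(mean_log_koc ~ log_kow, data = per)
  out <- tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = stats::cor(per$log_kow, per$mean_log_koc)^2,
    n = nrow(per)
  )
  attr(out, "compounds") <- per
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
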