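test_that("Koc and isotherm conversions match hand-computed values", {
  expect_equal(kd_from_koc(100, corg = 1), 1)
  expect_equal(kd_from_koc(10^3.5, corg = 10), 316.2278, tolerance = 1e-6)
  expect_error(kd_from_koc(100, corg = 0), "corg")

  # Freundlich: linear isotherm returns Kf for any solubility
  expect_equal(kd_from_isotherm("freundlich", 7.3, 1, solubility = 55), 7.3)
  expect_equal(kd_from_isotherm("freundlich", 10, 0.8, solubility = 100),
               10 * 10^(-0.2), tolerance = 1e-9)
  # Langmuir at Cw = 0.1 S
  expect_equal(kd_from_isotherm("langmuir", 100, 0.05, solubility = 100),
               10 / 3, tolerance = 1e-9)
  expect_error(kd_from_isotherm("freundlich", 10, 0.8, solubility = NA),
               "solubility")
})

test_that("Freundlich Kd is continuous in the exponent around n = 1", {
  n_grid <- seq(0.9, 1.1, by = 0.01)
  kd <- vapply(n_grid,
               function(n) kd_from_isotherm("freundlich", 5, n, 200),
               numeric(1))
  expect_true(all(abs(diff(kd)) < 0.5))
  expect_equal(kd[n_grid == 1], 5)
})

test_that("koc_of and kd_from_koc are exact inverses", {
  set.seed(4)
  kd <- 10^runif(50, -1.4, 3.95)
  corg <- runif(50, 0.03, 54)
  expect_equal(kd_from_koc(koc_of(kd, corg), corg), kd, tolerance = 1e-12)
  expect_equal(koc_of(1, corg = 1), 100)
  expect_error(koc_of(1, corg = 0), "undefined")
})

test_that("harmonization resolves Kd by source preference with reasons", {
  reg <- pfas_registry()
  raw <- tibble::tibble(
    entry_id = paste0("e", 1:7),
    compound_id = c("pfoa", "pfoa", "pfoa", "pfoa", "nope", "pfoa", "pfoa"),
    study_id = "s",
    ph = c(6, 6, 6, 6, 6, 20, 6),
    cec = 10, corg = c(2, 2, 0, 2, 2, 2, 2),
    sand = c(40, 40, 40, 40, 40, 40, 60),
    silt = c(40, 40, 40, 40, 40, 40, 50),
    clay = c(20, 20, 20, 20, 20, 20, 20),
    kd = c(3.2, NA, NA, NA, 1, 1, 1),
    koc = c(500, 160, 160, NA, NA, NA, NA),
    isotherm_model = c(NA, NA, NA, "freundlich", NA, NA, NA),
    isotherm_p1 = c(NA, NA, NA, 10, NA, NA, NA),
    isotherm_p2 = c(NA, NA, NA, 1, NA, NA, NA)
  )
  out <- harmonize_sorption(raw, reg)
  expect_equal(out$source[1], "direct")       # direct beats reported koc
  expect_equal(out$kd[1], 3.2)
  expect_equal(out$source[2], "from_koc")
  expect_equal(out$kd[2], 160 * 0.02)
  expect_false(out$accepted[3])               # koc without corg
  expect_equal(out$reject_reason[3], "koc_without_corg")
  expect_equal(out$source[4], "from_isotherm")
  expect_equal(out$kd[4], 10)                 # linear Freundlich
  expect_equal(out$reject_reason[5], "unknown_compound")
  expect_equal(out$reject_reason[6], "ph_out_of_range")
  expect_equal(out$reject_reason[7], "texture_sum")  # 130 > 100 + 2
  expect_equal(out$log_kd[out$accepted], log10(out$kd[out$accepted]))
})

test_that("textures within tolerance renormalize to exactly 100", {
  raw <- tibble::tibble(
    entry_id = "e1", compound_id = "pfoa", study_id = "s",
    ph = 6, cec = 10, corg = 2, sand = 40.5, silt = 40.5, clay = 20.5,
    kd = 1
  )
  out <- harmonize_sorption(raw)
  expect_true(out$accepted)
  expect_equal(out$sand + out$silt + out$clay, 100, tolerance = 1e-12)
})

test_that("sorption CSV round-trips through the documented schema", {
  d <- gen_sorption_dataset(20, seed = 3)
  d$.latent <- NULL; d$.outlier_truth <- NULL
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_sorption_csv(d, tmp)
  back <- read_sorption_csv(tmp)
  expect_equal(back$kd, d$kd, tolerance = 1e-12)
  expect_equal(back$compound_id, d$compound_id)
})

test_that("collinear compounds produce zero outlier flags", {
  reg <- line_registry(seq(1, 5.5, by = 0.5))
  d <- line_dataset(seq(1, 5.5, by = 0.5))
  out <- flag_outliers(d, reg)
  expect_false(any(out$outlier))
  diag <- attr(out, "outlier_diagnostics")
  expect_equal(diag$per_compound$residual, rep(0, 10), tolerance = 1e-10)
})

test_that("a compound displaced three log units is the unique flag", {
  kows <- seq(1, 6, by = 0.5)
  reg <- line_registry(kows)
  d <- line_dataset(kows)
  d$kd[4] <- d$kd[4] * 1e3  # displace compound c4 by +3 log units
  out <- flag_outliers(d, reg)
  flagged <- unique(out$compound_id[out$outlier])
  expect_equal(flagged, "c4")
  expect_equal(unique(out$outlier_reason[out$outlier]), "compound_trend")
})

test_that("flags are invariant to entry order and need three compounds", {
  kows <- seq(1, 6, by = 0.5)
  reg <- line_registry(kows)
  d <- line_dataset(kows)
  d$kd[4] <- d$kd[4] * 1e3
  out1 <- flag_outliers(d, reg)
  perm <- sample(nrow(d))
  out2 <- flag_outliers(d[perm, ], reg)
  expect_equal(out2$outlier[order(perm)], out1$outlier)
  expect_error(flag_outliers(d[1:2, ], reg), "at least 3 compounds")
})

test_that("within-compound deviations get entry-level flags", {
  reg <- line_registry(c(1, 2, 3))
  d <- line_dataset(c(1, 2, 3))
  d <- dplyr::bind_rows(d, d, d)  # three entries per compound
  d$entry_id <- paste0("e", seq_len(nrow(d)))
  d$kd[1] <- d$kd[1] * 10^2.5     # 2.5 log units above its compound median
  out <- flag_outliers(d, reg)
  expect_true(out$outlier[1])
  expect_equal(out$outlier_reason[1], "entry_deviation")
  expect_equal(sum(out$outlier), 1)
})
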