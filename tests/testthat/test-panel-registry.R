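test_that("default registry reproduces the published panel structure", {
  reg <- default_registry()
  fc <- feature_counts(reg)
  expect_identical(unname(fc["individual"]), 50L)
  expect_identical(unname(fc["sum"]), 13L)
  expect_identical(unname(fc["sg_ratio"]), 9L)
  expect_identical(unname(fc["enzyme_ratio"]), 17L)
  expect_identical(sum(fc), 89L)
})

test_that("panel annotations are coherent", {
  reg <- default_registry()
  met <- reg$metabolites
  expect_false(any(duplicated(met$id)))
  expect_true(all(met$molar_mass > 0))
  expect_true(all(met$lod >= 1 & met$lod <= 200))
  expect_false(any(is.na(met$conjugation)))
  expect_identical(met$conjugation, conjugation_from_id(met$id))
  # family follows the hormone-group prefix
  expect_equal(met$family[met$id == "PD-G"], "progestogen")
  expect_equal(met$family[met$id == "DHEA-S"], "androgen")
  expect_equal(met$family[met$id == "F-S"], "corticosteroid")
  expect_equal(met$family[met$id == "E3-G"], "estrogen")
  # every derived definition resolves, ratios have disjoint sides
  for (i in seq_len(nrow(reg$derived))) {
    num <- reg$derived$numerator_ids[[i]]
    den <- reg$derived$denominator_ids[[i]]
    expect_true(all(c(num, den) %in% met$id))
    expect_length(intersect(num, den), 0)
  }
})

test_that("registry validation catches broken definitions", {
  reg <- toy_registry()
  # unknown metabolite reference, named in the error
  bad <- reg
  bad$derived$numerator_ids[[1]] <- c("X-G", "Z-G")
  expect_error(steromap:::validate_registry(bad), "Z-G")
  # duplicate metabolite id
  bad <- reg
  bad$metabolites <- dplyr::bind_rows(bad$metabolites, bad$metabolites[1, ])
  expect_error(steromap:::validate_registry(bad), "duplicate")
  # sum with a denominator
  bad <- reg
  bad$derived$denominator_ids[[1]] <- "X-S"
  expect_error(steromap:::validate_registry(bad), "denominator")
  # overlapping ratio sides
  bad <- reg
  bad$derived$numerator_ids[[2]] <- c("X-S", "X-G")
  expect_error(steromap:::validate_registry(bad), "overlap")
  # minimal registry: one metabolite, no derived features
  mini <- list(
    metabolites = reg$metabolites[1, ],
    derived = reg$derived[0, ], version = "mini"
  )
  class(mini) <- "sh_registry"
  expect_silent(steromap:::validate_registry(mini))
  expect_identical(sum(feature_counts(mini)), 1L)
})

test_that("registries survive a JSON round trip", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_equal(back$metabolites, reg$metabolites)
  expect_equal(back$derived$numerator_ids, reg$derived$numerator_ids)
  expect_identical(feature_counts(back), feature_counts(reg))
  expect_null(load_registry(NULL)$missing) # NULL path -> default registry
  expect_identical(feature_counts(load_registry(NULL)), feature_counts(reg))
})

test_that("derive_features computes sums and ratios as molar arithmetic", {
  reg <- toy_registry()
  conc <- toy_cohort(tibble::tibble(`X-G` = c(3, 2), `X-S` = c(3, 0), `Y-S` = c(1, 1)))
  f <- derive_features(conc, reg)
  expect_equal(f$total_x, c(6, 2)) # sum of group members
  expect_equal(f$sg_x, c(1, 0)) # sulfate 3 / glucuronide 3 = 1
  expect_equal(f$enz_y_from_x, c(1 / 6, 0.5)) # product over precursor
  cls <- feature_classes(f)
  expect_identical(unname(cls[c("X-G", "total_x", "sg_x", "enz_y_from_x")]),
    c("individual", "sum", "sg_ratio", "enzyme_ratio"))
  # single metabolite at 2.5 in a one-member sum
  reg1 <- toy_registry()
  reg1$derived <- reg1$derived[1, ]
  reg1$derived$numerator_ids[[1]] <- "X-G"
  conc1 <- toy_cohort(tibble::tibble(`X-G` = 2.5, `X-S` = 1, `Y-S` = 1))
  expect_equal(derive_features(conc1, reg1)$total_x, 2.5)
})

test_that("zero denominators become missing, never infinite", {
  reg <- toy_registry()
  conc <- toy_cohort(tibble::tibble(`X-G` = c(0, 1), `X-S` = c(2, 2), `Y-S` = c(1, 1)))
  f <- derive_features(conc, reg)
  expect_true(is.na(f$sg_x[1]))
  expect_false(any(is.infinite(as.matrix(f[-1]))))
})

test_that("derive_features refuses non-molar input and yields 89 columns by default", {
  reg <- toy_registry()
  conc_ng <- toy_cohort(tibble::tibble(`X-G` = 1, `X-S` = 1, `Y-S` = 1), unit = "ng_ml")
  expect_error(derive_features(conc_ng, reg), "umol/L")

  fx <- small_prepared()
  expect_identical(ncol(fx$feats) - 1L, 89L)
  expect_identical(
    as.integer(table(feature_classes(fx$feats))[c("individual", "sum", "sg_ratio", "enzyme_ratio")]),
    c(50L, 13L, 9L, 17L)
  )
})

test_that("sums scale with the subject while ratios are scale-invariant", {
  reg <- toy_registry()
  base <- tibble::tibble(`X-G` = c(1.2, 3), `X-S` = c(0.4, 1), `Y-S` = c(2, 0.5))
  f1 <- derive_features(toy_cohort(base), reg)
  f2 <- derive_features(toy_cohort(base * 3.7), reg) # c > 0 per-subject scaling
  expect_equal(f2$total_x, 3.7 * f1$total_x)
  expect_equal(f2$sg_x, f1$sg_x)
  expect_equal(f2$enz_y_from_x, f1$enz_y_from_x)
})

test_that("ratio features ignore a per-subject multiplicative dilution factor", {
  fx <- small_prepared()
  pp <- fx$prep
  reg <- fx$spec$registry
  raw <- pp$conc_molar_raw
  # a per-subject multiplicative correction cancels exactly in every ratio
  d <- (raw$specific_gravity - 1) / (stats::median(raw$specific_gravity) - 1)
  corr <- raw
  for (j in steromap:::metabolite_cols(raw, reg)) corr[[j]] <- corr[[j]] / d
  f_raw <- derive_features(raw, reg, conc_raw = raw)
  f_corr <- derive_features(corr, reg, conc_raw = corr)
  cls <- feature_classes(f_raw)
  ratio_cols <- names(cls)[cls %in% c("sg_ratio", "enzyme_ratio")]
  for (j in ratio_cols) {
    expect_equal(f_corr[[j]], f_raw[[j]], tolerance = 1e-12)
  }
})
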