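test_that("RSD filter applies the reproducibility rule", {
  qc <- cbind(flat = c(1, 1, 1, 1), noisy = c(1, 1, 1, 2))
  res <- rsd_filter(qc)
  expect_equal(unname(res$rsd["flat"]), 0)
  expect_equal(unname(res$rsd["noisy"]), 0.4) # sd 0.5 / mean 1.25
  expect_identical(unname(res$retained), c(TRUE, FALSE))
  # non-positive mean: excluded with undefined-high RSD
  res2 <- rsd_filter(cbind(zeroed = c(-1, 1, 0, 0)))
  expect_false(res2$retained[1])
  expect_identical(unname(res2$rsd[1]), Inf)
  expect_error(rsd_filter(matrix(1, 1, 3)), "replicates")
})

test_that("LOD imputation fills only censored cells, below the LOD", {
  x <- c(1.2, 2.5, NA, 0.8, NA, 3.1)
  out <- impute_below_lod(x, lod = 0.5, seed = 4)
  expect_identical(out[!is.na(x)], x[!is.na(x)])
  expect_true(all(out[is.na(x)] < 0.5 & out[is.na(x)] > 0))
  expect_identical(out, impute_below_lod(x, lod = 0.5, seed = 4))
  expect_false(identical(out, impute_below_lod(x, lod = 0.5, seed = 5)))
  # untouched when nothing is censored
  expect_identical(impute_below_lod(x[!is.na(x)], lod = 0.5, seed = 1), x[!is.na(x)])
  # all censored: constant fallback with a warning
  expect_warning(out2 <- impute_below_lod(c(NA_real_, NA_real_), lod = 2, seed = 1), "lod")
  expect_equal(out2, rep(2 / sqrt(2), 2))
})

test_that("imputed values follow the truncated left tail", {
  withr::with_seed(99, {
    true <- stats::rlnorm(10000, 0, 1)
  })
  lod <- stats::qlnorm(0.2, 0, 1)
  x <- ifelse(true < lod, NA, true)
  out <- impute_below_lod(x, lod, seed = 12)
  imp <- out[is.na(x)]
  ks <- stats::ks.test(imp, function(q) stats::plnorm(q, 0, 1) / stats::plnorm(lod, 0, 1))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(imp < lod))
})

test_that("molar conversion is ng/mL over g/mol", {
  expect_equal(convert_to_molar(288.4, 288.4), 1)
  expect_equal(convert_to_molar(0, 123), 0)
  expect_equal(convert_to_molar(100, 400), 0.25)
  expect_error(convert_to_molar(-1, 100), "negative")
})

test_that("SG correction recovers pure dilution and removes the SG trend", {
  # pure-dilution fixture with typical assay noise: the fitted exponent
  # pins down the generative b = 1
  n <- 500
  withr::with_seed(31, {
    sg <- stats::runif(n, 1.005, 1.035)
    d <- (sg - 1) / (stats::median(sg) - 1)
    vals <- tibble::tibble(
      m1 = stats::rlnorm(n, log(2), 0.15) * d,
      m2 = stats::rlnorm(n, log(0.5), 0.15) * d,
      m3 = stats::rlnorm(n, log(10), 0.15) * d
    )
  })
  conc <- sh_cohort(
    tibble::tibble(
      subject_id = sprintf("S%03d", 1:n), specific_gravity = sg,
      gestational_age_weeks = 34, vals
    ),
    unit = "umol_l", correction = "raw"
  )
  model <- fit_sg_correction(conc)
  expect_true(all(abs(model$slope - 1) < 0.05))
  # on the full generator (metabolites with much larger biological spread)
  # the exponents are unbiased and the corrected data lose their SG trend
  spec <- cohort_spec(n_subjects = 500, missing_rate = 0, seed = 31)
  g <- generate_cohort(spec)
  pp <- suppressWarnings(preprocess_cohort(g$cohort, spec$registry, seed = 1))
  expect_lt(abs(mean(pp$sg_model$slope) - 1), 0.05)
  sgc <- pp$conc_molar$specific_gravity
  r <- vapply(
    steromap:::metabolite_cols(pp$conc_molar, spec$registry),
    function(j) stats::cor(log(pp$conc_molar[[j]]), sgc), numeric(1)
  )
  expect_lt(max(abs(r)), 0.05)
})

test_that("SG correction is the identity at the reference gravity and idempotent", {
  reg <- toy_registry()
  n <- 40
  withr::with_seed(8, {
    vals <- tibble::tibble(
      `X-G` = stats::rlnorm(n), `X-S` = stats::rlnorm(n), `Y-S` = stats::rlnorm(n)
    )
  })
  conc <- toy_cohort(vals) # all subjects at SG 1.02
  model <- fit_sg_correction(conc, sg_ref = 1.02)
  corrected <- apply_sg_correction(conc, model)
  expect_equal(corrected[["X-G"]], conc[["X-G"]])
  # re-applying the fitted model at the reference changes nothing
  again <- apply_sg_correction(corrected, model)
  expect_equal(again[["X-S"]], corrected[["X-S"]])
  bad <- conc
  bad$specific_gravity[3] <- 1.000
  expect_error(fit_sg_correction(bad), "S03")
})

test_that("MoM is one on the median curve and per-bin centered", {
  n <- 1000
  withr::with_seed(21, {
    ga <- stats::rnorm(n, 34.7, 1.5)
    m <- cbind(
      const = rep(2, n), # constant in gestational age
      trend = exp(0.4 + 0.08 * ga + stats::rnorm(n, 0, 0.3))
    )
  })
  model <- fit_mom_model(m, ga)
  mom <- mom_normalize(m, ga, model)
  expect_equal(unname(mom[, "const"]), rep(1, n), tolerance = 1e-6)
  bins <- cut(ga, stats::quantile(ga, seq(0, 1, 0.2)), include.lowest = TRUE)
  bin_med <- tapply(mom[, "trend"], bins, stats::median)
  expect_true(all(bin_med > 0.95 & bin_med < 1.05))
  # a subject lying exactly on the fitted median curve maps to MoM = 1
  on_curve <- exp(model$intercept["trend"] + model$slope["trend"] * 35)
  expect_equal(
    unname(mom_normalize(cbind(trend = on_curve), 35, model)[, "trend"]), 1,
    tolerance = 1e-10
  )
  expect_message(mom_normalize(cbind(trend = 1, const = 1), 60, model), "extrapolat")
})

test_that("log2 transform is exact and guards its domain", {
  reg <- toy_registry()
  f <- derive_features(toy_cohort(tibble::tibble(`X-G` = c(1, 8), `X-S` = c(2, 2), `Y-S` = c(4, 4))), reg)
  lf <- log2_features(f)
  expect_equal(lf[["X-G"]], c(0, 3))
  expect_equal(lf[["Y-S"]], c(2, 2))
  f$`X-G`[1] <- 0
  expect_error(log2_features(f), "X-G")
})

test_that("the preprocessing pipeline output is ordered and complete", {
  fx <- small_prepared()
  pp <- fx$prep
  expect_identical(steromap:::cohort_correction(pp$conc_molar), "sg")
  expect_identical(steromap:::cohort_correction(pp$conc_molar_raw), "raw")
  expect_true(isTRUE(attr(pp$features, "log2")))
  expect_true(isTRUE(attr(pp$features, "mom")))
  expect_identical(ncol(pp$features), 90L)
  expect_false(any(is.na(steromap:::feature_matrix(pp$features))))
})
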