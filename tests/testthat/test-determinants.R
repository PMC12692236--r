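make_det <- function(data, types = NULL, forced = NULL) {
  ids <- setdiff(names(data), "subject_id")
  if (is.null(types)) {
    types <- ifelse(vapply(data[ids], is.numeric, logical(1)), "continuous", "categorical")
  }
  schema <- tibble::tibble(
    id = ids, type = types,
    family = "clinical", forced = if (is.null(forced)) FALSE else forced,
    levels = rep(list(NULL), length(ids)), reference = NA_character_
  )
  sh_determinants(data, schema)
}

test_that("missingness filtering removes rows before columns", {
  withr::with_seed(1, {
    d <- tibble::tibble(
      subject_id = sprintf("S%02d", 1:10),
      a = stats::rnorm(10), b = stats::rnorm(10), c = stats::rnorm(10),
      d = stats::rnorm(10), e = stats::rnorm(10)
    )
  })
  det <- make_det(d)
  out <- filter_missingness(det)
  expect_identical(out$determinants$data, det$data) # complete table unchanged
  # one subject with 60% missing goes
  d2 <- d
  d2[3, c("a", "b", "c")] <- NA
  out2 <- filter_missingness(make_det(d2))
  expect_identical(out2$report$rows_removed, "S03")
  expect_identical(nrow(out2$determinants$data), 9L)
  # a column 70% missing goes (after row filtering)
  d3 <- d
  d3$b[1:7] <- NA
  out3 <- filter_missingness(make_det(d3))
  expect_identical(out3$report$cols_removed, "b")
  expect_identical(nrow(out3$determinants$schema), 4L)
  # everything missing -> error
  d4 <- d
  d4[, c("a", "b", "c", "d", "e")] <- NA_real_
  expect_error(filter_missingness(make_det(d4)), "all subjects")
})

test_that("correlation pruning drops the more redundant member", {
  n <- 1000
  withr::with_seed(5, {
    z <- stats::rnorm(n)
    a <- z + 0.3 * stats::rnorm(n) # r(a, b) ~ 0.92
    b <- z + 0.3 * stats::rnorm(n)
    cc <- a + 0.5 * stats::rnorm(n) # child of a: r(a, c) > r(b, c)
    ind <- stats::rnorm(n)
  })
  det <- make_det(tibble::tibble(subject_id = as.character(1:n), a = a, b = b, c = cc, ind = ind))
  out <- prune_correlated(det)
  # a and b are near-duplicates; a is also the parent of c, so a goes
  expect_identical(out$report$cols_removed, "a")
  expect_true(all(c("b", "c", "ind") %in% out$determinants$schema$id))
  # an exact duplicate loses exactly one member
  det2 <- make_det(tibble::tibble(subject_id = as.character(1:n), x = a, y = a, ind = ind))
  out2 <- prune_correlated(det2)
  expect_length(out2$report$cols_removed, 1)
  # independent columns are untouched
  det3 <- make_det(tibble::tibble(
    subject_id = as.character(1:n),
    p = stats::rnorm(n), q = stats::rnorm(n)
  ))
  expect_length(prune_correlated(det3)$report$cols_removed, 0)
})

test_that("iterative imputation beats marginal imputation on correlated data", {
  n <- 300
  withr::with_seed(11, {
    z <- stats::rnorm(n)
    truth <- tibble::tibble(
      subject_id = as.character(1:n),
      x1 = z + 0.3 * stats::rnorm(n),
      x2 = z + 0.3 * stats::rnorm(n),
      x3 = z + 0.3 * stats::rnorm(n),
      grp = ifelse(z + 0.5 * stats::rnorm(n) > 0, "high", "low")
    )
    holes <- truth
    miss1 <- sample(n, 30)
    holes$x1[miss1] <- NA
    holes$grp[sample(n, 30)] <- NA
  })
  det <- make_det(holes)
  imp <- impute_iterative(det, seed = 2)
  # observed cells never change
  obs <- !is.na(holes$x1)
  expect_identical(imp$data$x1[obs], holes$x1[obs])
  # RF imputation error below mean-imputation error
  rf_rmse <- sqrt(mean((imp$data$x1[miss1] - truth$x1[miss1])^2))
  mean_rmse <- sqrt(mean((mean(holes$x1, na.rm = TRUE) - truth$x1[miss1])^2))
  expect_lt(rf_rmse, mean_rmse)
  # categorical values stay in the declared level set
  expect_true(all(as.character(imp$data$grp) %in% c("high", "low")))
  # deterministic given seed
  expect_identical(impute_iterative(det, seed = 2)$data, imp$data)
  # no missing values: untouched
  expect_identical(impute_iterative(make_det(truth), seed = 1)$data, make_det(truth)$data)
})

test_that("IQR scaling centers the median and unit-scales the IQR", {
  withr::with_seed(3, x <- stats::rexp(200))
  s <- iqr_scale(x)
  expect_equal(stats::median(s), 0)
  expect_equal(stats::IQR(s), 1)
  expect_error(iqr_scale(rep(2, 10), name = "flat"), "flat")
})

test_that("dummy coding expands categoricals against the reference level", {
  d <- tibble::tibble(
    subject_id = as.character(1:6),
    parity = c("nulliparous", "primiparous", "multiparous", "nulliparous", "nulliparous", "primiparous"),
    smoker = c("no", "yes", "no", "no", "yes", "no"),
    age = c(30, 32, 35, 28, 40, 33)
  )
  schema <- tibble::tibble(
    id = c("parity", "smoker", "age"),
    type = c("categorical", "categorical", "continuous"),
    family = "clinical", forced = FALSE,
    levels = list(c("nulliparous", "primiparous", "multiparous"), c("no", "yes"), NULL),
    reference = c("nulliparous", "no", NA)
  )
  ex <- dummy_code(sh_determinants(d, schema))
  expect_setequal(
    setdiff(names(ex), "subject_id"),
    c("parity_primiparous", "parity_multiparous", "smoker_yes", "age")
  )
  expect_equal(ex$parity_primiparous, c(0, 1, 0, 0, 0, 1))
  expect_equal(ex$smoker_yes, c(0, 1, 0, 0, 1, 0))
  # an undeclared level is rejected at construction
  d_bad <- d
  d_bad$smoker[1] <- "sometimes"
  expect_error(sh_determinants(d_bad, schema), "sometimes")
})

test_that("the default design is full rank after dummy coding", {
  fx <- small_prepared()
  X <- cbind(
    steromap:::exposure_matrix(fx$expo, FALSE),
    steromap:::exposure_matrix(fx$expo, TRUE)
  )
  expect_identical(qr(X)$rank, ncol(X))
})
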