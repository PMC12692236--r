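test_that("orthogonal predictors receive exactly their marginal R2", {
  withr::with_seed(10, Z <- matrix(stats::rnorm(120 * 2), 120, 2))
  X <- qr.Q(qr(cbind(1, Z)))[, 2:3] # exactly orthogonal, zero-mean columns
  colnames(X) <- c("x1", "x2")
  y <- drop(X %*% c(2, 1.2)) # noiseless
  d <- lmg_decomposition(y, X, groups = list(x1 = "x1", x2 = "x2"))
  marg1 <- summary(stats::lm(y ~ X[, 1]))$r.squared
  marg2 <- summary(stats::lm(y ~ X[, 2]))$r.squared
  expect_equal(d$shares$share[d$shares$group == "x1"], marg1, tolerance = 1e-10)
  expect_equal(d$shares$share[d$shares$group == "x2"], marg2, tolerance = 1e-10)
  expect_equal(sum(d$shares$share), d$total_r2, tolerance = 1e-10)
  expect_equal(d$total_r2, 1)
})

test_that("identical predictors split their contribution evenly", {
  withr::with_seed(11, {
    x <- stats::rnorm(150)
    y <- x + stats::rnorm(150)
  })
  X <- cbind(a = x, b = x)
  d <- lmg_decomposition(y, X, groups = list(a = "a", b = "b"))
  joint <- summary(stats::lm(y ~ x))$r.squared
  expect_equal(d$shares$share, rep(joint / 2, 2), tolerance = 1e-10)
})

test_that("exact shares equal brute-force enumeration up to p = 6", {
  withr::with_seed(12, {
    n <- 90
    z <- stats::rnorm(n)
    X <- sapply(1:6, function(k) 0.5 * z + stats::rnorm(n))
    colnames(X) <- paste0("x", 1:6)
    y <- drop(X %*% c(1, -0.5, 0.3, 0, 0.2, -0.1) + stats::rnorm(n))
  })
  groups4 <- list(x1 = "x1", x2 = "x2", x3 = "x3", x4 = "x4")
  d4 <- lmg_decomposition(y, X[, 1:4], groups4)
  oracle4 <- lmg_bruteforce(y, X[, 1:4], groups4)
  expect_equal(stats::setNames(d4$shares$share, d4$shares$group), oracle4, tolerance = 1e-10)
  groups6 <- stats::setNames(as.list(colnames(X)), colnames(X))
  d6 <- lmg_decomposition(y, X, groups6)
  oracle6 <- lmg_bruteforce(y, X, groups6)
  expect_equal(stats::setNames(d6$shares$share, d6$shares$group), oracle6, tolerance = 1e-10)
  expect_true(all(d6$shares$share > -1e-10))
  expect_equal(sum(d6$shares$share), d6$total_r2, tolerance = 1e-10)
})

test_that("grouped dummies enter and leave together", {
  withr::with_seed(13, {
    n <- 200
    f <- sample(c("a", "b", "c"), n, replace = TRUE)
    x <- stats::rnorm(n)
    y <- (f == "b") * 1 + (f == "c") * 2 + 0.5 * x + stats::rnorm(n)
  })
  X <- cbind(f_b = as.numeric(f == "b"), f_c = as.numeric(f == "c"), x = x)
  d <- lmg_decomposition(y, X, groups = list(f = c("f_b", "f_c"), x = "x"))
  oracle <- lmg_bruteforce(y, X, list(f = c("f_b", "f_c"), x = "x"))
  expect_equal(stats::setNames(d$shares$share, d$shares$group), oracle, tolerance = 1e-10)
})

test_that("shares are invariant to ordering and affine rescaling", {
  withr::with_seed(14, {
    X <- matrix(stats::rnorm(150 * 3), 150, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(X %*% c(1, 0.5, -0.3) + stats::rnorm(150))
  })
  g1 <- list(a = "a", b = "b", c = "c")
  d1 <- lmg_decomposition(y, X, g1)
  d2 <- lmg_decomposition(y, X[, c("c", "a", "b")], g1[c("c", "a", "b")])
  expect_equal(
    d1$shares$share[match(c("a", "b", "c"), d1$shares$group)],
    d2$shares$share[match(c("a", "b", "c"), d2$shares$group)],
    tolerance = 1e-12
  )
  X_scaled <- X
  X_scaled[, "a"] <- 100 * X[, "a"] - 7
  d3 <- lmg_decomposition(y, X_scaled, g1)
  expect_equal(d3$shares$share, d1$shares$share, tolerance = 1e-10)
})

test_that("sampled orderings converge to the exact decomposition", {
  withr::with_seed(15, {
    n <- 40
    z <- stats::rnorm(n)
    X <- sapply(1:6, function(k) 0.4 * z + stats::rnorm(n))
    colnames(X) <- paste0("x", 1:6)
    y <- drop(X %*% c(0.8, -0.4, 0.3, 0.2, 0, 0.1) + stats::rnorm(n, 0, 0.5))
  })
  groups <- stats::setNames(as.list(colnames(X)), colnames(X))
  exact <- lmg_decomposition(y, X, groups)
  sampled <- lmg_decomposition(y, X, groups,
    exact_max_groups = 0,
    n_perm = 50000, seed = 3
  )
  expect_false(sampled$exact)
  expect_lt(max(abs(sampled$shares$share - exact$shares$share)), 1e-3)
})

test_that("final models report covariate baselines and catch collinearity", {
  withr::with_seed(16, {
    n <- 120
    covar <- stats::rnorm(n)
    x <- stats::rnorm(n)
    y <- 0.5 * covar + x + stats::rnorm(n)
  })
  # empty stable set: covariates-only R2
  f0 <- fit_final_model(y, matrix(nrow = n, ncol = 0), cbind(covar = covar))
  expect_equal(f0$r2, summary(stats::lm(y ~ covar))$r.squared, tolerance = 1e-10)
  # noiseless fit explains everything
  f1 <- fit_final_model(x + covar, cbind(x = x), cbind(covar = covar))
  expect_equal(f1$r2, 1, tolerance = 1e-12)
  # aliased columns are named
  expect_error(fit_final_model(y, cbind(x = x, x_dup = x), NULL), "x_dup")
  # recovery: coefficients within 2 SE of truth at n = 1000
  withr::with_seed(17, {
    xx <- stats::rnorm(1000)
    yy <- 0.7 * xx + stats::rnorm(1000)
  })
  f2 <- fit_final_model(yy, cbind(x = xx), NULL)
  se <- summary(stats::lm(yy ~ xx))$coefficients["xx", "Std. Error"]
  expect_lt(abs(f2$coefficients["x"] - 0.7), 2 * se)
})

test_that("variance summaries conserve the decomposed R2", {
  fx <- small_prepared()
  feats <- subset_features(fx$feats, c("PD-G", "F-G"))
  sel <- select_all_features(feats, fx$expo, B = 10, freq_threshold = 0.5, seed = 21)
  dec <- decompose_all_features(feats, fx$expo, sel, seed = 1)
  sv <- summarize_variance(dec,
    feature_class = feature_classes(feats),
    family = steromap:::determinant_families(fx$expo)
  )
  if (nrow(sv$table)) {
    agg <- tapply(sv$table$share, sv$table$feature, sum)
    for (f in names(agg)) {
      expect_equal(
        unname(agg[f]), dec[[f]]$total_r2 - dec[[f]]$baseline_r2,
        tolerance = 1e-8
      )
    }
  }
  dec2 <- decompose_all_features(feats, fx$expo, sel, seed = 1)
  expect_identical(dec, dec2)
})
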