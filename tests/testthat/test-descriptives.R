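test_that("weighted prevalence reduces to the weighted/unweighted mean", {
  d <- data.frame(outcome = c(1, 1, 0, 0), weight = 1, stratum = 1,
                  psu = c(1, 1, 2, 2))
  expect_equal(weighted_prevalence(d)$proportion, 0.5)
  d2 <- data.frame(outcome = c(1, 0, 0, 0), weight = c(3, 1, 1, 1),
                   stratum = 1, psu = c(1, 1, 2, 2))
  expect_equal(weighted_prevalence(d2)$proportion, 0.5)
  # equal weights reproduce the unweighted proportion exactly
  set.seed(8)
  d3 <- data.frame(outcome = rbinom(200, 1, 0.3), weight = 1,
                   stratum = rep(1:4, each = 50),
                   psu = rep(1:40, each = 5))
  expect_identical(weighted_prevalence(d3)$proportion, mean(d3$outcome))
})

test_that("design variance matches an independent linearization oracle", {
  set.seed(14)
  d <- data.frame(outcome = rbinom(120, 1, 0.4),
                  weight = rgamma(120, 4, 4),
                  stratum = rep(1:2, each = 60),
                  psu = rep(1:12, each = 10))
  est <- weighted_prevalence(d)
  v <- oracle_prevalence_var(d$outcome, d$weight, d$stratum, d$psu)
  expect_equal(est$se^2, v, tolerance = 1e-10)
  expect_true(est$ci_low <= est$proportion && est$proportion <= est$ci_high)
})

test_that("logit-Wald CI stays inside [0,1] near the boundary", {
  d <- data.frame(outcome = c(1, rep(0, 39)), weight = 1,
                  stratum = rep(1:2, each = 20), psu = rep(1:8, each = 5))
  est <- weighted_prevalence(d)
  expect_gt(est$ci_low, 0)
  expect_lt(est$ci_high, 1)
  expect_equal(est$proportion, 1 / 40)
})

test_that("single-PSU strata fail loudly unless marked certainty units", {
  d <- data.frame(outcome = c(1, 0, 1, 0), weight = 1,
                  stratum = c(1, 1, 2, 2), psu = c(1, 2, 3, 3))
  expect_error(weighted_prevalence(d), "stratum '2'")
  est <- weighted_prevalence(d, single_psu = "certainty")
  expect_equal(est$proportion, 0.5)
})

test_that("design chi-square equals classical Pearson under a trivial design", {
  d <- toy_2x2_records()  # 2x2 toy table [[10,20],[5,40]]
  res <- design_chisq(d, factor_col = "exposed")
  # closed form n*(ad-bc)^2 / (row and column margins)
  x2_closed <- 75 * (10 * 40 - 20 * 5)^2 / (30 * 45 * 15 * 60)
  expect_equal(res$statistic, x2_closed, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$delta_bar, 1, tolerance = 1e-10)
  # random table, equality with stats::chisq.test (no continuity correction)
  set.seed(3)
  d2 <- data.frame(outcome = rbinom(150, 1, 0.4),
                   grp = sample(c("a", "b", "c"), 150, replace = TRUE),
                   weight = 1, stratum = 1, psu = seq_len(150))
  res2 <- design_chisq(d2, factor_col = "grp")
  ref <- suppressWarnings(chisq.test(table(d2$outcome, d2$grp),
                                     correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res2$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("degenerate tables are rejected", {
  d <- toy_2x2_records()
  d$grp <- "same"
  expect_error(design_chisq(d, factor_col = "grp"), "degenerate")
})

test_that("design chi-square holds its nominal level under independence", {
  set.seed(77)
  rej <- 0
  n_rep <- 1000
  for (k in seq_len(n_rep)) {
    d <- data.frame(outcome = rbinom(120, 1, 0.5),
                    grp = sample(c("a", "b"), 120, replace = TRUE),
                    weight = 1, stratum = 1, psu = seq_len(120))
    p <- tryCatch(design_chisq(d, factor_col = "grp")$p_value,
                  error = function(e) 1)
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("logistic ML recovers the 2x2 cross-product odds ratio", {
  d <- toy_2x2_records()
  tab <- fit_logistic_ml(d, covariates = "exposed")
  or <- tab$or[tab$term == "exposedyes"]
  expect_equal(or, 4.0, tolerance = 1e-6)
})

test_that("logistic ML flags rank deficiency and recovers a true OR", {
  d <- toy_2x2_records()
  d$null_cov <- "same"
  expect_error(fit_logistic_ml(d, covariates = "null_cov"), "rank")
  set.seed(4)
  x <- rbinom(5000, 1, 0.5)
  y <- rbinom(5000, 1, plogis(-0.5 + log(3) * x))
  d2 <- data.frame(outcome = y, x = factor(x))
  tab <- fit_logistic_ml(d2, covariates = "x")
  expect_lt(abs(tab$or[tab$term == "x1"] - 3.0), 0.3)
})

test_that("perfect separation is flagged, not silently reported", {
  d <- data.frame(outcome = rep(c(0, 1), each = 15),
                  x = rep(c("a", "b"), each = 15))
  w <- capture_warnings(tab <- fit_logistic_ml(d, covariates = "x"))
  expect_true(any(grepl("separation", w)))
  expect_true(any(tab$separation_flag))
})

test_that("screening applies the p-value threshold and forcing list", {
  set.seed(6)
  n <- 800
  d <- data.frame(outcome = rbinom(n, 1, 0.5),
                  a = sample(c("x", "y"), n, replace = TRUE),
                  b = sample(c("x", "y"), n, replace = TRUE),
                  c = sample(c("x", "y"), n, replace = TRUE))
  d$outcome <- rbinom(n, 1, plogis(-0.2 + 0.5 * (d$a == "y")))
  tab <- fit_logistic_ml(d, covariates = c("a", "b", "c"))
  p <- vapply(c("a", "b", "c"),
              function(v) min(tab$p_value[tab$covariate == v]), 0)
  # pick a threshold between two realized p-values: selection must split there
  stopifnot(length(unique(p)) == 3)
  ps <- sort(p)
  alpha_mid <- mean(ps[2:3])
  sel <- screen_covariates(d, candidates = c("a", "b", "c"),
                           alpha = alpha_mid)
  expect_setequal(sel, names(p)[p <= alpha_mid])
  # forcing bypasses the threshold
  worst <- names(p)[which.max(p)]
  sel2 <- screen_covariates(d, candidates = c("a", "b", "c"),
                            alpha = 1e-12, always_keep = worst)
  expect_true(worst %in% sel2)
  det <- attr(sel2, "details")
  expect_named(det, c("covariate", "p_multivariable", "p_univariate",
                      "selected"))
})
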