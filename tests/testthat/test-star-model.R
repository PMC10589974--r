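test_that("Polya-Gamma sampler matches the closed-form moments", {
  set.seed(31)
  x <- rpg(40000, 0)
  se_m <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.25), 4 * se_m)
  expect_equal(var(x), 1 / 24, tolerance = 0.05)
  for (z in c(1, 2, -2, 6)) {
    xz <- rpg(40000, z)
    mz <- tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(xz) - mz), 4 * sd(xz) / sqrt(length(xz)))
  }
})

test_that("non-integer-shape Polya-Gamma draws have the right mean", {
  set.seed(32)
  b <- 2.5; z <- 1.3
  x <- spatstar:::.rpg_weighted_cpp(rep(b, 30000), rep(z, 30000))
  expect_lt(abs(mean(x) - b * tanh(z / 2) / (2 * z)),
            4 * sd(x) / sqrt(length(x)))
})

test_that("structured field draws are centred and summaries order-invariant", {
  cfg <- rwanda_like_config("women", seed = 51,
                            n_individuals = 600, tau2_str = 0.3,
                            tau2_unstr = 0.1)
  dat <- simulate_survey(cfg)
  sp <- star_spec(fixed_terms = c("controlling", "alcohol"),
                  spatial_term = list(district = "district",
                                      graph = cfg$graph))
  mc <- quick_mcmc(n_iter = 800, burn_in = 200, thin = 2)
  f <- fit_star(dat, sp, mc)
  fs <- f$draws$theta[, f$param_index$f_str, drop = FALSE]
  expect_lt(max(abs(rowSums(fs))), 1e-8)
  # permuting record order changes nothing (canonical sort + same seed)
  set.seed(99)
  rec_perm <- dat$records[sample(nrow(dat$records)), ]
  f2 <- fit_star(rec_perm, sp, mc)
  expect_equal(f$summaries, f2$summaries, tolerance = 1e-12)
})

test_that("odds table conventions: reference rows and degenerate draws", {
  cfg <- rwanda_like_config("women", seed = 52, n_individuals = 400,
                            tau2_str = 0, tau2_unstr = 0)
  dat <- simulate_survey(cfg)
  sp <- star_spec(fixed_terms = c("controlling", "wealth"))
  f <- fit_star(dat, sp, quick_mcmc(n_iter = 600, burn_in = 100, thin = 2))
  # force a degenerate posterior for one coefficient
  cols <- colnames(f$draws$theta)
  f$draws$theta[, "controllingyes"] <- log(2)
  tab <- posterior_odds_table(f)
  row <- tab[tab$covariate == "controlling" & tab$level == "yes", ]
  expect_equal(row$aor, 2.0)
  expect_equal(row$ci_low, 2.0)
  expect_equal(row$ci_high, 2.0)
  ref <- tab[tab$covariate == "wealth" & tab$reference, ]
  expect_equal(ref$level, "poorest")
  expect_equal(ref$aor, 1)
  expect_true(is.na(ref$ci_low))
  expect_true(all(tab$aor > 0))
})

test_that("DIC: degenerate posteriors have pD = 0, genuine ones pD > 0", {
  cfg <- rwanda_like_config("women", seed = 53, n_individuals = 400,
                            tau2_str = 0, tau2_unstr = 0)
  dat <- simulate_survey(cfg)
  sp <- star_spec(fixed_terms = "controlling")
  f <- fit_star(dat, sp, quick_mcmc(n_iter = 600, burn_in = 100, thin = 2))
  d <- compute_dic(f)
  expect_gt(d$pd, 0)
  expect_equal(d$dic, d$mean_deviance + d$pd)
  # identical draws: no parameter uncertainty
  f2 <- f
  f2$draws$theta <- f$draws$theta[rep(1, 50), , drop = FALSE]
  d2 <- compute_dic(f2)
  expect_equal(d2$pd, 0, tolerance = 1e-8)
})

test_that("null spatial field shrinks variances and district odds", {
  g <- make_lattice(5, 6)
  cfg <- simulation_config(5000, g, intercept = -0.3, tau2_str = 0,
                           tau2_unstr = 0, seed = 54)
  dat <- simulate_survey(cfg)
  sp <- star_spec(spatial_term = list(district = "district", graph = g))
  f <- fit_star(dat, sp, quick_mcmc(n_iter = 3000, burn_in = 1000, thin = 4))
  t2 <- f$draws$tau2
  expect_lt(median(t2[, "tau2_str"]), 0.05)
  expect_lt(median(t2[, "tau2_unstr"]), 0.05)
  pd <- predicted_district_prevalence(f)
  # shrinkage: posterior district odds are far tighter than raw
  # empirical district odds and close to 1
  raw <- tapply(dat$records$outcome, dat$records$district, mean)
  raw_lo <- log(raw / (1 - raw))
  expect_lt(sd(log(pd$odds)), 0.5 * sd(raw_lo))
  expect_true(all(pd$odds > 0.8 & pd$odds < 1.25))
  # centring convention and monotone ranking
  expect_equal(exp(mean(log(pd$odds))), 1, tolerance = 1e-8)
  expect_identical(order(pd$odds), order(pd$f_str + pd$f_unstr))
  expect_true(all(is.finite(pd$prevalence)))
})

test_that("the P-spline smooth recovers a strong nonlinear age effect", {
  g <- make_lattice(2, 3)
  curve_true <- function(a) {
    s <- (a - 32) / 17
    1.5 * (s^2 - 1 / 3)
  }
  cfg <- simulation_config(3000, g, intercept = -0.2,
                           age_range = c(15, 49), age_curve = curve_true,
                           seed = 55)
  dat <- simulate_survey(cfg)
  sp <- star_spec(smooth_terms = "age")
  f <- fit_star(dat, sp, quick_mcmc(n_iter = 2500, burn_in = 500, thin = 4))
  sm <- smooth_effect(f, "age")
  truth <- curve_true(sm$x)
  expect_gt(cor(sm$mean, truth - mean(truth)), 0.9)
})

test_that("variance decomposition handles fits, scalars and edge cases", {
  expect_equal(variance_decomposition(0.1, 0.1)$phi_structured_pct, 50.0)
  expect_warning(vd <- variance_decomposition(0, 0), "undefined")
  expect_true(is.na(vd$phi_structured))
  cfg <- rwanda_like_config("women", seed = 56, n_individuals = 300)
  dat <- simulate_survey(cfg)
  f <- fit_star(dat, star_spec(spatial_term = list(district = "district",
                                                   graph = cfg$graph)),
                quick_mcmc(n_iter = 400, burn_in = 100, thin = 2))
  vd2 <- variance_decomposition(f)
  expect_true(vd2$phi_structured >= 0 && vd2$phi_structured <= 1)
  expect_length(vd2$ci_structured_pct, 2)
  f_nospat <- fit_star(dat, star_spec(fixed_terms = "controlling"),
                       quick_mcmc(n_iter = 300, burn_in = 100, thin = 2))
  expect_error(variance_decomposition(f_nospat), "both spatial")
})

test_that("raw draw export names every parameter", {
  d <- data.frame(outcome = rep(c(1, 0), c(6, 4)))
  f <- fit_star(d, star_spec(), quick_mcmc(400, 100, 2, n_chains = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(f, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(back), c("chain", "(Intercept)"))
  expect_equal(back[["(Intercept)"]], unname(f$draws$theta[, 1]))
})

test_that("bad inputs are rejected with informative errors", {
  cfg <- rwanda_like_config("women", seed = 57, n_individuals = 100)
  dat <- simulate_survey(cfg)
  rec <- dat$records
  rec$district <- as.character(rec$district)
  rec$district[1] <- "atlantis"
  sp <- star_spec(spatial_term = list(district = "district",
                                      graph = cfg$graph))
  expect_error(fit_star(rec, sp, quick_mcmc(300, 100, 1)), "atlantis")
  rec2 <- dat$records
  rec2$outcome[1] <- 2
  expect_error(fit_star(rec2, star_spec(), quick_mcmc(300, 100, 1)),
               "binary")
})
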