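test_that("terciles split exact thirds and respect boundaries", {
  d <- tibble::tibble(county_id = as.character(1:9), value = 1:9)
  st <- tercile_stratify(d, "value")
  expect_equal(unname(split(d$county_id, st$assignments$stratum)),
               list(c("1", "2", "3"), c("4", "5", "6"), c("7", "8", "9")))
  # a value exactly on a cutpoint goes to the lower stratum
  d2 <- tibble::tibble(county_id = as.character(1:6),
                       value = c(1, 2, 2, 3, 4, 5))
  st2 <- tercile_stratify(d2, "value")
  q <- st2$cutpoints
  expect_true(all(st2$assignments$stratum[d2$value == q[1]] == "low"))
})

test_that("degenerate stratification inputs are rejected", {
  d <- tibble::tibble(county_id = as.character(1:5), value = rep(3, 5))
  expect_error(tercile_stratify(d, "value"), "distinct")
  expect_error(tercile_stratify(d, "nope"), "not in data")
})

test_that("fixed-effects pooling reduces correctly in simple cases", {
  one <- fixed_effects_meta(tibble::tibble(estimate = -4, se = 1.5))
  expect_equal(one$pooled, -4)
  expect_equal(one$pooled_se, 1.5)
  expect_equal(one$q, 0)
  expect_equal(one$i2, 0)

  two <- fixed_effects_meta(tibble::tibble(estimate = c(-2, -6),
                                           se = c(2, 2)))
  expect_equal(two$pooled, -4)

  equal <- fixed_effects_meta(tibble::tibble(estimate = rep(-3, 4),
                                             se = c(1, 2, 3, 4)))
  expect_equal(equal$q, 0)
  expect_equal(equal$i2, 0)
  expect_error(fixed_effects_meta(tibble::tibble(estimate = 1, se = 0)),
               "positive")
})

test_that("pooling is invariant to ordering and variance rescaling", {
  est <- tibble::tibble(estimate = c(-8, -12, -5, -10), se = c(2, 3, 1.5, 4))
  a <- fixed_effects_meta(est)
  b <- fixed_effects_meta(est[c(3, 1, 4, 2), ])
  expect_equal(a$pooled, b$pooled)
  expect_equal(a$q, b$q)
  expect_equal(a$i2, b$i2)
  # rescaling all variances by c: estimate unchanged, SE scales by sqrt(c)
  sc <- fixed_effects_meta(dplyr::mutate(est, se = se * 2))
  expect_equal(sc$pooled, a$pooled)
  expect_equal(sc$pooled_se, 2 * a$pooled_se)
  expect_true(a$pooled >= min(est$estimate) && a$pooled <= max(est$estimate))
})

test_that("pooled estimate, Q and I2 match metafor", {
  skip_if_not_installed("metafor")
  set.seed(83)
  est <- tibble::tibble(estimate = rnorm(8, -10, 3),
                        se = runif(8, 0.8, 3))
  ours <- fixed_effects_meta(est, ci_level = 0.99)
  ref <- metafor::rma(yi = est$estimate, sei = est$se, method = "FE")
  expect_equal(ours$pooled, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$pooled_se, ref$se, tolerance = 1e-10)
  expect_equal(ours$q, ref$QE, tolerance = 1e-10)
  expect_equal(ours$i2, ref$I2, tolerance = 1e-6)
})

test_that("the Q-profile I2 interval inverts the generalised Q", {
  est <- tibble::tibble(estimate = c(-14, -6, -12, -2, -9),
                        se = c(1.5, 2, 1.2, 2.5, 1.8))
  m <- fixed_effects_meta(est)
  expect_true(all(m$i2_conf >= 0 & m$i2_conf <= 100))
  expect_lte(m$i2_conf[1], m$i2_conf[2])
  v <- est$se^2
  dfq <- nrow(est) - 1
  s2 <- dfq * sum(1 / v) / (sum(1 / v)^2 - sum(1 / v^2))
  gen_q <- function(tau2) {
    wi <- 1 / (v + tau2)
    mu <- sum(wi * est$estimate) / sum(wi)
    sum(wi * (est$estimate - mu)^2)
  }
  tau2_hi <- s2 * m$i2_conf[2] / (100 - m$i2_conf[2])
  expect_equal(gen_q(tau2_hi), qchisq(0.025, dfq), tolerance = 1e-5)
  if (m$i2_conf[1] > 0) {
    tau2_lo <- s2 * m$i2_conf[1] / (100 - m$i2_conf[1])
    expect_equal(gen_q(tau2_lo), qchisq(0.975, dfq), tolerance = 1e-5)
  }
})

test_that("state-stratified models pool the per-state exposure slopes", {
  sim <- simulate_counties(sim_spec(seed = 87))
  d <- filter_counties(sim$counties)$counties
  m <- state_meta(d, "lung")
  expect_equal(nrow(m$strata), length(unique(d$state)))
  # oracle: refit one state by normal equations
  st <- m$strata$label[1]
  ds <- d[d$state == st, ]
  cc <- complete.cases(ds[, c("lung", "elevation", "smoking")])
  o <- ols_oracle(ds$lung[cc], ds[cc, c("elevation", "smoking")],
                  weights_from_population(ds$population)[cc])
  expect_equal(m$strata$estimate[1], unname(o$beta[2]), tolerance = 1e-8)
})

test_that("a null interaction term stays null and a real one is found", {
  null_p <- numeric(15)
  for (s in 1:15) {
    sim <- simulate_counties(sim_spec(n_counties = 300,
                                      state_slope_sd = c(), seed = 900 + s))
    d <- filter_counties(sim$counties)$counties
    covs <- names(study_effects()$lung$coef)
    f <- interaction_test(d, "lung", covs, "smoking", "elevation")
    co <- f$coefficients
    null_p[s] <- co$p_two[co$term == "smoking_x_elevation"]
  }
  # under the null the two-sided p-values should not pile up near zero
  expect_gte(mean(null_p > 0.05), 0.8)

  hits <- 0
  for (s in 1:5) {
    sim <- simulate_counties(sim_spec(n_counties = 400,
                                      state_slope_sd = c(), seed = 950 + s))
    d <- filter_counties(sim$counties)$counties
    d <- d[complete.cases(d[, c("smoking", "elevation", "lung")]), ]
    w <- weights_from_population(d$population)
    zs <- weighted_zscore(d$smoking, w)
    ze <- weighted_zscore(d$elevation, w)
    d$lung <- d$lung + 0.5 * 14.4 * zs * ze
    covs <- names(study_effects()$lung$coef)
    f <- interaction_test(d, "lung", covs, "smoking", "elevation",
                          weights = w)
    co <- f$coefficients
    hits <- hits + (co$p_two[co$term == "smoking_x_elevation"] < 0.01)
  }
  expect_equal(hits, 5)
})

test_that("subgroup refits reduce to the global fit on identical outcomes", {
  sim <- simulate_counties(sim_spec(n_counties = 300, seed = 89))
  d <- filter_counties(sim$counties)$counties
  covs <- names(study_effects()$lung$coef)
  for (col in c("lung_male", "lung_female", "lung_under65", "lung_65plus")) {
    d[[col]] <- d$lung
  }
  sg <- subgroup_refit(d, covs, smoking_map = list())
  cc <- complete.cases(d[, c(covs, "lung")])
  ref <- fit_wols(d[cc, ], "lung", covs)
  for (lab in names(sg$fits)) {
    expect_equal(
      sg$summary$estimate[sg$summary$subgroup == lab],
      ref$coefficients$estimate[ref$coefficients$term == "elevation"],
      tolerance = 1e-10)
  }
})

test_that("homogeneous subgroup effects give mutually overlapping CIs", {
  overlap_all <- TRUE
  sim <- simulate_counties(sim_spec(seed = 91))
  d <- filter_counties(sim$counties)$counties
  sg <- subgroup_refit(d, names(study_effects()$lung$coef))
  s <- sg$summary
  for (i in 1:3) for (j in (i + 1):4) {
    overlap <- s$beta_z_low[i] <= s$beta_z_high[j] &&
      s$beta_z_low[j] <= s$beta_z_high[i]
    overlap_all <- overlap_all && overlap
  }
  expect_true(overlap_all)
  expect_true(all(s$estimate < 0))
  expect_true(all(s$p_one < 0.01))
})
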