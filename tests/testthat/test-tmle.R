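# saturated cell-mean outcome + empirical cell-frequency propensity,
# ignoring covariates: TMLE must collapse to the cell's sample mean
saturated_nuisances <- function(d) {
  cell_means <- tapply(d$Y, list(factor(d$V1, 0:2), factor(d$V2, 0:2)),
                       mean)
  freq <- tabulate(3 * d$V1 + d$V2 + 1L, 9L) / nrow(d)
  custom_nuisances(
    mu = function(v1, v2, data)
      cell_means[cbind(rep_len(v1, nrow(data)) + 1,
                       rep_len(v2, nrow(data)) + 1)],
    g = function(data) matrix(rep(freq, each = nrow(data)), nrow(data), 9),
    data = d, floor = 1e-6)
}

test_that("saturated no-confounder TMLE collapses to the cell sample mean", {
  d <- toy_data(n = 300, seed = 81)
  nus <- saturated_nuisances(d)
  for (cell in list(c(0L, 0L), c(1L, 1L), c(2L, 0L))) {
    res <- tmle_counterfactual_mean(d, nus, cell)
    expect_equal(res$estimate,
                 mean(d$Y[d$V1 == cell[1] & d$V2 == cell[2]]),
                 tolerance = 1e-8)
    expect_lt(abs(mean(res$eic)), 1e-8)
  }
  expect_error(tmle_counterfactual_mean(d, nus, c(5L, 5L)))
})

test_that("targeting solves the EIC score equation for fitted nuisances", {
  cfg <- sim_config(n = 3000, alpha1 = 0.3, gamma = 0.2, delta = c(1),
                    confound_strength = 0.5, seed = 82)
  d <- simulate_cohort(cfg)$data
  nus <- fit_nuisances(d, nuisance_spec("glm"), "continuous", seed = 82)
  comps <- tmle_components(d, nus, candidates <- list(
    transition(c(0, 1), c(0, 1)), transition(c(1, 2), c(1, 2))))
  for (cm in comps) {
    # bounded-scale tolerance: back-transformed by the outcome range
    expect_lt(abs(mean(cm$eic)) / diff(range(d$Y)), 1e-8)
    expect_equal(cm$se, sqrt(mean((cm$eic - mean(cm$eic))^2) /
                               length(cm$eic)))
  }
})

test_that("oracle nuisances recover the true counterfactual mean", {
  cfg <- sim_config(n = 20000, alpha0 = 1, alpha1 = 0.3, alpha2 = -0.1,
                    gamma = 0.25, delta = c(0.8), confound_strength = 0.8,
                    seed = 83)
  d <- simulate_cohort(cfg)$data
  nus <- custom_nuisances(structural_mu(cfg), structural_propensity(cfg),
                          d)
  for (cell in list(c(1L, 1L), c(0L, 2L))) {
    truth <- 1 + 0.3 * cell[1] - 0.1 * cell[2] + 0.25 * prod(cell)
    res <- tmle_counterfactual_mean(d, nus, cell)
    se <- sd(res$eic) / sqrt(nrow(d))
    expect_lt(abs(res$estimate - truth), 3 * se)
  }
  # and the interaction component recovers gamma
  cm <- tmle_component(d, nus, transition(c(0, 1), c(0, 1)))
  expect_lt(abs(cm$estimate - 0.25), 3 * cm$se)
})

test_that("TMLE removes confounding bias that the naive contrast keeps", {
  cfg <- sim_config(n = 50000, alpha1 = 0.3, alpha2 = 0.2, gamma = 0.3,
                    delta = c(2), confound_strength = 1, seed = 84)
  d <- simulate_cohort(cfg)$data
  cm <- tapply(d$Y, list(d$V1, d$V2), mean)
  naive <- cm["1", "1"] - cm["0", "1"] - cm["1", "0"] + cm["0", "0"]
  res <- tmle_component(d, fit_nuisances(d, nuisance_spec("glm"),
                                         "continuous", seed = 84),
                        transition(c(0, 1), c(0, 1)))
  expect_gt(abs(naive - 0.3), 3 * res$se)
  expect_lt(abs(res$estimate - 0.3), 3 * res$se)
})

test_that("either correct nuisance alone removes the bias (double
           robustness, moderate n)", {
  cfg <- sim_config(n = 20000, alpha1 = 0.3, alpha2 = 0.2, gamma = 0.3,
                    delta = c(1.5), confound_strength = 0.8, seed = 85)
  d <- simulate_cohort(cfg)$data
  tr <- transition(c(0, 1), c(0, 1))
  # wrong outcome (grand mean), true propensity
  nus_a <- custom_nuisances(function(v1, v2, data)
    rep(mean(d$Y), nrow(data)), structural_propensity(cfg), d)
  cm_a <- tmle_component(d, nus_a, tr)
  expect_lt(abs(cm_a$estimate - 0.3), 3 * cm_a$se)
  # true outcome, wrong propensity (marginal cell frequencies)
  freq <- tabulate(3 * d$V1 + d$V2 + 1L, 9L) / nrow(d)
  nus_b <- custom_nuisances(structural_mu(cfg), function(data)
    matrix(rep(freq, each = nrow(data)), nrow(data), 9), d)
  cm_b <- tmle_component(d, nus_b, tr)
  expect_lt(abs(cm_b$estimate - 0.3), 3 * cm_b$se)
})

test_that("component covariance is a PSD Gram matrix with se^2 diagonal", {
  cfg <- sim_config(n = 2000, maf1 = 0.5, maf2 = 0.5, alpha1 = 0.2,
                    gamma = 0.1, delta = c(1), confound_strength = 0.3,
                    seed = 86)
  d <- simulate_cohort(cfg)$data
  nus <- fit_nuisances(d, nuisance_spec("glm"), "continuous", seed = 86)
  comps <- tmle_components(d, nus, candidate_set <- list(
    transition(c(0, 1), c(0, 1)), transition(c(0, 1), c(1, 2)),
    transition(c(1, 2), c(0, 1)), transition(c(1, 2), c(1, 2))))
  sigma <- component_covariance(comps)
  expect_equal(unname(diag(sigma)),
               vapply(comps, function(x) x$se^2, numeric(1)))
  expect_true(all(eigen(sigma, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_equal(unclass(sigma), t(unclass(sigma)))
  # single component: the 1x1 covariance is its squared standard error
  s1 <- component_covariance(comps[1])
  expect_equal(as.numeric(s1), comps[[1]]$se^2)
  short <- comps[[1]] ; short$eic <- short$eic[-1]
  expect_error(component_covariance(list(short, comps[[2]])),
               "sample counts")
})

test_that("estimates are equivariant under affine rescaling of Y", {
  cfg <- sim_config(n = 5000, alpha1 = 0.3, gamma = 0.2, delta = c(1),
                    confound_strength = 0.4, seed = 87)
  d <- simulate_cohort(cfg)$data
  tr <- transition(c(0, 1), c(0, 1))
  cm1 <- tmle_component(d, fit_nuisances(d, nuisance_spec("glm"),
                                         "continuous", seed = 1), tr)
  d2 <- d ; d2$Y <- 10 + 3 * d$Y
  cm2 <- tmle_component(d2, fit_nuisances(d2, nuisance_spec("glm"),
                                          "continuous", seed = 1), tr)
  expect_equal(cm2$estimate, 3 * cm1$estimate, tolerance = 1e-6)
  expect_equal(cm2$se, 3 * cm1$se, tolerance = 1e-6)
})

test_that("3-point components difference the sex strata with inflated EICs", {
  cfg <- sim_config(n = 8000, gamma = 0.15, gamma_sex = 0.3,
                    delta = c(0.8), confound_strength = 0.4, seed = 88)
  d <- simulate_cohort(cfg)$data
  nus <- fit_nuisances(d, nuisance_spec("glm"), "continuous", seed = 88,
                       by_sex = TRUE)
  tr <- transition(c(0, 1), c(0, 1), sex = TRUE)
  cm <- tmle_component(d, nus, tr)
  expect_length(cm$eic, nrow(d))
  expect_lt(abs(cm$estimate - 0.3), 3 * cm$se)
  # mixing 2- and 3-point transitions in one call is refused
  expect_error(tmle_components(d, nus, list(tr, transition(c(0, 1),
                                                           c(0, 1)))),
               "mix")
})
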