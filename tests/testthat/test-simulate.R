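test_that("noise-free simulation reproduces the deterministic mean structure", {
  d <- build_design(list(pop_spec("A", n_pairs = 2),
                         pop_spec("B", n_pairs = 2)), 1)
  plan <- build_stocking(d, list(s1 = 10))
  pars <- sim_params(mu = 100, pop_effects = c(A = 0, B = 0),
                     stream_effects = c(s1 = 0), sigma2_family = 0,
                     sigma2_resid = 0, seed = 1)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 5)
  expect_true(all(ph$length == 100))

  pars2 <- sim_params(mu = 100, pop_effects = c(A = 0, B = 10),
                      stream_effects = c(s1 = 0), sigma2_family = 0,
                      sigma2_resid = 0, seed = 1)
  ph2 <- simulate_phenotypes(d, plan, pars2, survivors = 5)
  means <- tapply(ph2$length, ph2$population, mean)
  expect_equal(unname(means["B"] - means["A"]), 10)
})

test_that("residual draws have the stated variance at large n", {
  d <- build_design(list(pop_spec("A", n_pairs = 1)), 1)
  plan <- build_stocking(d, list(s1 = 10000))
  pars <- sim_params(mu = 0, pop_effects = c(A = 0),
                     stream_effects = c(s1 = 0), sigma2_family = 0,
                     sigma2_resid = 4, seed = 11)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 10000)
  expect_equal(nrow(ph), 10000)
  expect_lt(abs(var(ph$length) - 4) / 4, 0.05)
})

test_that("simulation is reproducible from the seed", {
  d <- five_pop_design(4)
  plan <- build_stocking(d, list(experimental = 50))
  p1 <- five_pop_params(seed = 5)
  expect_identical(simulate_phenotypes(d, plan, p1, survivors = 5),
                   simulate_phenotypes(d, plan, p1, survivors = 5))
  p2 <- five_pop_params(seed = 6)
  expect_false(isTRUE(all.equal(
    simulate_phenotypes(d, plan, p1, survivors = 5)$length,
    simulate_phenotypes(d, plan, p2, survivors = 5)$length)))
})

test_that("degenerate survival probabilities give exact recapture counts", {
  d <- build_design(list(pop_spec("A", n_pairs = 5)), 1)
  plan <- build_stocking(d, list(s1 = 100))
  p0 <- sim_params(pop_effects = c(A = 0), stream_effects = c(s1 = 0),
                   survival_p = c(s1 = 0), seed = 1)
  expect_true(all(simulate_survival(plan, p0)$n_recaptured == 0))
  p1 <- sim_params(pop_effects = c(A = 0), stream_effects = c(s1 = 0),
                   survival_p = c(s1 = 1), seed = 1)
  sv <- simulate_survival(plan, p1)
  expect_equal(sv$n_recaptured, sv$n_stocked)
})

test_that("pooled recapture fraction matches the binomial rate", {
  d <- build_design(list(pop_spec("A", n_pairs = 50)), 1)
  plan <- build_stocking(d, list(s1 = 600))
  pars <- sim_params(pop_effects = c(A = 0), stream_effects = c(s1 = 0),
                     survival_p = c(s1 = 0.003), seed = 21)
  sv <- simulate_survival(plan, pars)
  n <- sum(sv$n_stocked)
  se <- sqrt(0.003 * 0.997 / n)
  expect_lt(abs(sum(sv$n_recaptured) / n - 0.003), 3 * se)
})

test_that("missing parameter keys are reported", {
  d <- build_design(list(pop_spec("A", n_pairs = 1)), 1)
  plan <- build_stocking(d, list(s1 = 10))
  pars <- sim_params(pop_effects = c(B = 0), stream_effects = c(s1 = 0))
  expect_error(simulate_phenotypes(d, plan, pars, survivors = 2),
               "no population effect")
  pars2 <- sim_params(pop_effects = c(A = 0), stream_effects = c(s2 = 0))
  expect_error(simulate_phenotypes(d, plan, pars2, survivors = 2),
               "no stream effect")
  pars3 <- sim_params(pop_effects = c(A = 0), stream_effects = c(s1 = 0),
                      survival_p = c(s2 = 0.1))
  expect_error(simulate_survival(plan, pars3), "no survival probability")
})

test_that("diallel sibling structure reflects the parental variances", {
  d <- build_design(list(pop_spec("A", n_matrices = 100)), 2)
  plan <- build_stocking(d, list(s1 = 1))
  pars <- sim_params(mu = 0, pop_effects = c(A = 0),
                     stream_effects = c(s1 = 0), sigma2_family = 0,
                     sigma2_sire = 1, sigma2_dam = 0.5, sigma2_resid = 0,
                     seed = 31)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 1, mode = "diallel")
  # cross value = sire + dam effect; its variance is sigma2_sire + sigma2_dam
  expect_lt(abs(var(ph$length) - 1.5) / 1.5, 0.25)
  # crosses sharing a sire covary by sigma2_sire
  by_sire <- split(ph$length, ph$sire_id)
  pairs <- t(vapply(by_sire, function(v) v[1:2], numeric(2)))
  expect_lt(abs(cov(pairs[, 1], pairs[, 2]) - 1), 3 * 1.5 / sqrt(nrow(pairs)))
})

test_that("ground truth matches the divergence formula", {
  # family variance 1, no residual: within-variance 1, h2 clips to 1
  pars <- sim_params(pop_effects = c(A = 1, B = -1, C = 1, D = -1),
                     sigma2_family = 1, sigma2_resid = 0)
  gt <- ground_truth(pars, c = 1, mode = "fullsib")
  expect_equal(gt$true_sigma2_B, var(c(1, -1, 1, -1)))
  expect_equal(gt$true_h2, 1)
  expect_equal(gt$true_pst,
               gt$true_sigma2_B / (gt$true_sigma2_B + 2))

  # all population effects equal: no divergence
  flat <- sim_params(pop_effects = c(A = 3, B = 3))
  expect_equal(ground_truth(flat, mode = "fullsib")$true_pst, 0)

  # cross-module consistency over random parameter sets
  set.seed(41)
  for (i in 1:100) {
    pars <- sim_params(pop_effects = rnorm(4) + c(A = 0, B = 0, C = 0, D = 0),
                       sigma2_family = runif(1, 0.05, 2),
                       sigma2_resid = runif(1, 0.5, 4))
    cc <- runif(1, 0.2, 1)
    gt <- ground_truth(pars, c = cc, mode = "fullsib")
    expect_equal(gt$true_pst,
                 pst_from_components(gt$true_sigma2_B, gt$true_sigma2_W,
                                     c = cc, h2 = gt$true_h2))
  }
})
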