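test_that("retained-draw bookkeeping matches the MCMC arithmetic", {
  expect_equal(retained_draws(mcmc_preset("paper")), 9000)
  expect_equal(retained_draws(mcmc_preset("paper"), per_chain = TRUE), 1500)
  expect_equal(retained_draws(mcmc_spec(3, 1000, 100, 7)), 3 * 128)
  expect_error(mcmc_spec(2, 100, 100, 1), "smaller")

  fit <- gibbs_fit(
    data.frame(cross_id = rep(c("a", "b"), each = 6),
               length = rnorm(12, 100)),
    model_spec(random = "family"), mcmc_spec(3, 200, 50, 7, seed = 1))
  expect_equal(nrow(as.matrix(fit)), 3 * ((200 - 50) %/% 7))
})

test_that("model specification rejects inconsistent terms", {
  expect_error(model_spec(fixed = "population", random = "population"),
               "both fixed and random")
  expect_error(model_spec(fixed = "population:stream", random = "family"),
               "main effects")
  expect_error(model_spec(fixed = "year"), "unknown fixed")
})

test_that("posterior means approach group means on near-deterministic data", {
  set.seed(2)
  n <- 2000
  d <- data.frame(
    population = rep(c("A", "B"), each = n),
    stream = "s1",
    cross_id = rep(sprintf("f%02d", 1:40), length.out = 2 * n),
    length = rep(c(100, 110), each = n) + rnorm(2 * n, 0, 0.05))
  fit <- gibbs_fit(d, model_spec(fixed = "population", random = "family"),
                   mcmc_spec(2, 1000, 200, 2, seed = 2))
  m <- colMeans(as.matrix(fit))
  expect_lt(abs(m[["(Intercept)"]] - 100) / 100, 0.01)
  expect_lt(abs((m[["(Intercept)"]] + m[["populationB"]]) - 110) / 110, 0.01)
})

test_that("variance components are recovered at the stated design size", {
  d <- build_design(list(pop_spec("A", n_pairs = 200)), 1)
  plan <- build_stocking(d, list(s1 = 20))
  pars <- sim_params(mu = 50, pop_effects = c(A = 0),
                     stream_effects = c(s1 = 0), sigma2_family = 1,
                     sigma2_resid = 1, seed = 7)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 20)
  fit <- gibbs_fit(ph, model_spec(random = "family"),
                   mcmc_spec(2, 2000, 500, 3, seed = 7))
  med <- apply(as.matrix(fit), 2, median)
  expect_gt(med[["sigma2_family"]], 0.8)
  expect_lt(med[["sigma2_family"]], 1.25)
  expect_gt(med[["sigma2_resid"]], 0.8)
  expect_lt(med[["sigma2_resid"]], 1.25)
})

test_that("variance draws are strictly positive and a null component shrinks", {
  d <- build_design(list(pop_spec("A", n_pairs = 40)), 1)
  plan <- build_stocking(d, list(s1 = 25))
  pars <- sim_params(mu = 0, pop_effects = c(A = 0),
                     stream_effects = c(s1 = 0), sigma2_family = 0,
                     sigma2_resid = 2, seed = 9)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 25)
  fit <- gibbs_fit(ph, model_spec(random = "family"),
                   mcmc_spec(2, 2000, 500, 3, seed = 9))
  m <- as.matrix(fit)
  expect_true(all(m[, c("sigma2_family", "sigma2_resid")] > 0))
  expect_lt(quantile(m[, "sigma2_family"], 0.025),
            0.01 * median(m[, "sigma2_resid"]))
})

test_that("degenerate inputs error or are pruned as documented", {
  expect_error(gibbs_fit(data.frame(cross_id = character(),
                                    length = numeric()),
                         model_spec(random = "family")),
               "empty")
  # population confounded with stream: singular fixed design
  d <- data.frame(population = rep(c("A", "B"), each = 10),
                  stream = rep(c("s1", "s2"), each = 10),
                  cross_id = rep(c("f1", "f2"), each = 10),
                  length = rnorm(20, 100))
  expect_error(
    suppressWarnings(gibbs_fit(d, model_spec(
      fixed = c("population", "stream", "population:stream"),
      random = "family"), mcmc_spec(2, 100, 10, 1))),
    "singular")
  # single-level factor is dropped with a warning, not an error
  d2 <- d
  d2$stream <- "s1"
  expect_warning(
    gibbs_fit(d2, model_spec(fixed = c("population", "stream"),
                             random = "family"),
              mcmc_spec(2, 100, 10, 1, seed = 1)),
    "single-level")
})

test_that("heritability follows the stated variance-component conventions", {
  mk <- function(cols) fake_chains(matrix(rep(cols, each = 50),
                                          nrow = 50,
                                          dimnames = list(NULL, names(cols))),
                                   matrix(rep(cols, each = 50),
                                          nrow = 50,
                                          dimnames = list(NULL, names(cols))))
  fs <- estimate_h2(mk(c(sigma2_family = 1, sigma2_resid = 3)), "fullsib")
  expect_true(all(fs$draws == 0.5))
  expect_equal(fs$n_clipped, 0)

  di <- estimate_h2(mk(c(sigma2_sire = 0.25, sigma2_dam = 0.25,
                         sigma2_resid = 1)), "diallel")
  expect_true(all(abs(di$draws - 2 / 3) < 1e-12))

  z <- estimate_h2(mk(c(sigma2_family = 0, sigma2_resid = 1)), "fullsib")
  expect_true(all(z$draws == 0))

  # family variance above residual: h2 clips to 1 and the clip is counted
  cl <- estimate_h2(mk(c(sigma2_family = 3, sigma2_resid = 1)), "fullsib")
  expect_true(all(cl$draws == 1))
  expect_equal(cl$n_clipped, 100)

  # population variance never enters the denominator
  wp <- estimate_h2(mk(c(sigma2_population = 9, sigma2_family = 1,
                         sigma2_resid = 3)), "fullsib")
  expect_true(all(wp$draws == 0.5))

  expect_error(estimate_h2(mk(c(sigma2_family = 1, sigma2_resid = 1)),
                           "diallel"), "lack variance terms")
})
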