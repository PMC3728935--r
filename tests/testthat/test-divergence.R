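test_that("the divergence index follows the variance-component formula", {
  expect_equal(pst_from_components(2, 1, c = 1, h2 = 1), 0.5)
  expect_equal(pst_from_components(0, 5, c = 1, h2 = 0.3), 0)
  expect_equal(pst_from_components(2, 1, c = 1, h2 = 0.5), 2 / 3)
  expect_equal(pst_from_components(2, 1, c = 0.5, h2 = 1), 1 / 3)

  expect_error(pst_from_components(0, 0, c = 1, h2 = 1), "undefined")
  expect_error(pst_from_components(1, 1, c = 0, h2 = 1), "'c'")
  expect_error(pst_from_components(1, 1, c = 1, h2 = 1.5), "'h2'")
  expect_error(pst_from_components(-1, 1, c = 1, h2 = 1), "non-negative")
})

test_that("the divergence index is bounded and monotone", {
  set.seed(8)
  for (i in 1:200) {
    s2b <- runif(1, 0, 5); s2w <- runif(1, 0.01, 5)
    cc <- runif(1, 0.05, 1); h2 <- runif(1, 0.05, 1)
    v <- pst_from_components(s2b, s2w, cc, h2)
    expect_gte(v, 0); expect_lte(v, 1)
    eps <- 0.1
    expect_gte(pst_from_components(s2b + eps, s2w, cc, h2), v)
    expect_lte(pst_from_components(s2b, s2w + eps, cc, h2), v)
    expect_lte(pst_from_components(s2b, s2w, cc * 0.5, h2), v)
    expect_lte(pst_from_components(s2b, s2w, cc, min(h2 + eps, 1)), v)
  }
})

make_div_chains <- function(s2p, s2f, s2e, n = 100) {
  m <- cbind(sigma2_population = s2p, sigma2_family = s2f, sigma2_resid = s2e)
  m <- m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
  fake_chains(m[1:(n / 2), , drop = FALSE], m[(n / 2 + 1):n, , drop = FALSE])
}

test_that("posterior P_ST equals per-draw evaluation of the formula", {
  ch <- make_div_chains(2, 0.4, 0.6)
  p <- pst_posterior(ch, h2 = 1, config = pst_config(c = 1, fst_upper = 0.1))
  expect_true(all(p$draws == 0.5))  # sigma2_W = 0.4 + 0.6 = 1
  expect_equal(p$median, 0.5)
  expect_equal(p$verdict, "divergent")

  set.seed(9)
  m <- cbind(sigma2_population = runif(200, 0.1, 3),
             sigma2_family = runif(200, 0.1, 1),
             sigma2_resid = runif(200, 0.1, 3))
  ch <- fake_chains(m[1:100, ], m[101:200, ])
  h2d <- runif(200, 0.2, 1)
  p <- pst_posterior(ch, h2 = h2d, config = pst_config(c = 0.8))
  brute <- vapply(seq_len(200), function(i)
    0.8 * m[i, 1] / (0.8 * m[i, 1] +
                       2 * h2d[i] * (m[i, 2] + m[i, 3])), 0)
  expect_equal(unname(p$draws), brute)
  expect_equal(p$median, median(brute))

  # halving c weakly decreases every draw
  p2 <- pst_posterior(ch, h2 = h2d, config = pst_config(c = 0.4))
  expect_true(all(p2$draws <= p$draws))

  # residual-only within-variance switch
  pr <- pst_posterior(ch, h2 = h2d,
                      config = pst_config(c = 0.8, within = "residual-only"))
  expect_true(all(pr$draws >= p$draws))

  expect_error(pst_posterior(ch, h2 = h2d[1:10]), "mismatch")
})

test_that("the F_ST comparison issues the documented verdicts", {
  mk <- function(v) {
    ch <- make_div_chains(v / (1 - v) * 2 * 1, 0.4, 0.6)  # constant draws = v
    pst_posterior(ch, h2 = 1, config = pst_config(fst_upper = 0.1))
  }
  expect_equal(mk(0.6)$verdict, "divergent")
  expect_equal(mk(0.05)$verdict, "stabilizing")
  straddle <- fake_chains(
    cbind(sigma2_population = c(0.01, 10), sigma2_family = 0.5,
          sigma2_resid = 0.5),
    cbind(sigma2_population = c(0.01, 10), sigma2_family = 0.5,
          sigma2_resid = 0.5))
  ps <- pst_posterior(straddle, h2 = 1, config = pst_config(fst_upper = 0.1))
  expect_equal(ps$verdict, "neutral")
  expect_equal(compare_to_fst(ps, fst_upper = 0.001), "divergent")
})

test_that("intraclass correlations normalise every draw exactly", {
  ch <- fake_chains(
    cbind(sigma2_population = 1, sigma2_stream = 1, sigma2_family = 0,
          sigma2_resid = 2),
    cbind(sigma2_population = 1, sigma2_stream = 1, sigma2_family = 0,
          sigma2_resid = 2))
  r <- icc(ch)
  expect_equal(r$summary$median[r$summary$component == "icc_population"], 0.25)
  expect_equal(r$summary$median[r$summary$component == "icc_stream"], 0.25)

  only <- fake_chains(cbind(sigma2_family = 3, sigma2_resid = 0) + 0,
                      cbind(sigma2_family = 3, sigma2_resid = 0) + 0)
  expect_equal(unname(icc(only)$draws[1, "icc_family"]), 1)

  set.seed(10)
  m1 <- matrix(runif(4 * 4500, 0.01, 5), ncol = 4,
               dimnames = list(NULL, c("sigma2_population", "sigma2_stream",
                                       "sigma2_family", "sigma2_resid")))
  m2 <- matrix(runif(4 * 4500, 0.01, 5), ncol = 4,
               dimnames = list(NULL, colnames(m1)))
  r2 <- icc(fake_chains(m1, m2))
  expect_equal(unname(rowSums(r2$draws)), rep(1, 9000))
})

test_that("reaction norms recover parallel and shifted structures", {
  d <- build_design(lapply(c("A", "B", "C"),
                           function(nm) pop_spec(nm, n_pairs = 6)), 1)
  plan <- build_stocking(d, list(s1 = 30, s2 = 30))
  pars <- sim_params(mu = 100, pop_effects = c(A = 10, B = 0, C = -2),
                     stream_effects = c(s1 = 0, s2 = 3),
                     sigma2_family = 0.5, sigma2_resid = 2, seed = 17)
  ph <- simulate_phenotypes(d, plan, pars, survivors = 20)
  fit <- gibbs_fit(ph, model_spec(
    fixed = c("population", "stream", "population:stream"),
    random = "family"), mcmc_spec(2, 2000, 500, 3, seed = 17))
  rn <- reaction_norm_summary(fit)
  # simulated with zero interaction: parallelism ratio near zero
  expect_lt(rn$parallelism$median, 0.2)
  # population A sits ~10 above B in every stream
  cells <- rn$cells
  for (s in c("s1", "s2")) {
    dA <- cells$median[cells$population == "A" & cells$stream == s] -
      cells$median[cells$population == "B" & cells$stream == s]
    expect_lt(abs(dA - 10), 1.5)
  }
  # near-noise-free data: cell means equal direct per-cell sample means
  pars0 <- sim_params(mu = 100, pop_effects = c(A = 10, B = 0, C = -2),
                      stream_effects = c(s1 = 0, s2 = 3),
                      sigma2_family = 0, sigma2_resid = 1e-8, seed = 18)
  ph0 <- simulate_phenotypes(d, plan, pars0, survivors = 5)
  fit0 <- gibbs_fit(ph0, model_spec(
    fixed = c("population", "stream", "population:stream"),
    random = "family"), mcmc_spec(2, 1000, 200, 2, seed = 18))
  rn0 <- reaction_norm_summary(fit0)
  direct <- aggregate(length ~ population + stream, ph0, mean)
  merged <- merge(rn0$cells, direct)
  expect_equal(merged$median, merged$length, tolerance = 1e-3)
})
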