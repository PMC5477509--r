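test_that("ne_from_theta reproduces the published scaling arithmetic", {
  expect_equal(ne_from_theta(2.2e-3, 6.5e-9, 1), 84615L)
  expect_equal(ne_from_theta(1e-3, 6.5e-9, 1), 38461L)
  expect_equal(ne_from_theta(4 * 6.5e-9, 6.5e-9, 1), 1L)
  expect_error(ne_from_theta(0, 6.5e-9, 1), class = "fs_param_error")
})

test_that("demographic_model validates per-model parameter sets", {
  m <- demographic_model("BN", nu_w = 0.8, tau = 0.1, nu_b = 0.05,
                         tau_b = 0.05)
  expect_equal(m$M, 0)
  expect_error(demographic_model("BN", nu_w = 0.8, tau = 0.1),
               class = "fs_param_error")
  nb <- demographic_model("NOBN", nu_w = 0.8, tau = 0.1)
  expect_null(nb$nu_b)
  expect_error(demographic_model("EXP", nu_w = 1, tau = 0.1),
               class = "fs_param_error")
  # nesting relations
  expect_true(model_nests("BN+MIG", "BN"))
  expect_true(model_nests("BN+MIG", "NOBN+MIG"))
  expect_true(model_nests("BN", "NOBN"))
  expect_false(model_nests("BN", "BN+MIG"))
  expect_false(model_nests("NOBN", "BN"))
})

test_that("expected_sfs is seed-reproducible and respects model nesting", {
  bnm0 <- demographic_model("BN+MIG", nu_w = 0.8, tau = 0.1, nu_b = 0.05,
                            tau_b = 0.05, M = 0)
  bn <- demographic_model("BN", nu_w = 0.8, tau = 0.1, nu_b = 0.05,
                          tau_b = 0.05)
  a <- expected_sfs(bn, 16, 16, 8000, seed = 12)
  b <- expected_sfs(bn, 16, 16, 8000, seed = 12)
  expect_identical(a$counts, b$counts)
  # migration at M = 0 is deterministic mixing: identical trajectories
  c2 <- expected_sfs(bnm0, 16, 16, 8000, seed = 12)
  expect_identical(a$counts, c2$counts)
  # probabilities over unmasked entries sum to 1
  expect_equal(sum(a$counts[!a$masked]), 1, tolerance = 1e-9)
  expect_true(a$folded)
})

test_that("tau = 0 reproduces the single-population equilibrium SFS", {
  # Both samples then come from one equilibrium population whose
  # frequency density is proportional to 1/(x(1-x)) (recurrent-mutation
  # stationary density in the small-theta limit); the analytic joint
  # spectrum under the binomial sampling kernel is the oracle.
  e <- expected_sfs(demographic_model("NOBN", nu_w = 1, tau = 0),
                    20, 20, 1e5, seed = 9)
  n1 <- 20; n2 <- 20
  xs <- (1:1999) / 2000
  phi <- 1 / (xs * (1 - xs))
  P <- matrix(0, n1 + 1, n2 + 1)
  for (j1 in 0:n1)
    P[j1 + 1, ] <- vapply(0:n2, function(j2)
      sum(dbinom(j1, n1, xs) * dbinom(j2, n2, xs) * phi), numeric(1))
  f <- sfs_normalize(mask_singletons(fold_sfs(
    feralscan:::new_sfs(P, c(n1, n2)))))
  tv <- 0.5 * sum(abs(f$counts[!f$masked] - e$counts[!e$masked]))
  # bound: Monte-Carlo half-L1 error at ~8,500 segregating sites over
  # ~200 cells is ~0.06; small-theta bias adds a little
  expect_lt(tv, 0.08)
})

test_that("composite log-likelihood has its closed-form optima", {
  base <- mask_singletons(fold_sfs(feralscan:::new_sfs(
    matrix(rpois(11 * 11, 4) + 1, 11, 11), c(10, 10))))
  K <- sum(!base$masked)
  uniform <- base
  uniform$counts[!uniform$masked] <- 1 / K
  uniform$counts[uniform$masked] <- 0
  N <- sum(base$counts[!base$masked])
  expect_equal(composite_log_likelihood(base, uniform), N * log(1 / K),
               tolerance = 1e-9)
  # observed proportional to expected maximizes LL over probability vectors
  best <- sfs_normalize(base)
  ll_best <- composite_log_likelihood(base, best)
  set.seed(14)
  for (i in 1:10) {
    other <- base
    other$counts[!other$masked] <- stats::runif(K)
    other <- sfs_normalize(other)
    expect_lte(composite_log_likelihood(base, other), ll_best)
  }
  # shape mismatch is an input error
  small <- mask_singletons(fold_sfs(feralscan:::new_sfs(
    matrix(1, 9, 9), c(8, 8))))
  expect_error(composite_log_likelihood(base, small),
               class = "fs_input_error")
})

test_that("fit_model bookkeeping and budget monotonicity hold", {
  set.seed(2)
  obs <- expected_sfs(preset_model("BN"), 12, 12, 6000, seed = 31)
  obs$counts <- obs$counts * 3000   # pseudo-counts
  f1 <- fit_model(obs, "NOBN", n_runs = 1, optimizer_budget = 25,
                  seed = 5, n_replicate_sites = 2000)
  expect_equal(nrow(f1$runs), 1L)
  expect_true(is.finite(f1$best$ll))
  f2 <- fit_model(obs, "NOBN", n_runs = 1, optimizer_budget = 50,
                  seed = 5, n_replicate_sites = 2000)
  expect_gte(f2$best$ll, f1$best$ll)   # doubling the budget never hurts
  # identical model supplied twice gives identical likelihoods
  cmp <- compare_models(obs, model_ids = c("NOBN", "NOBN"), n_runs = 1,
                        optimizer_budget = 20, seed = 5,
                        n_replicate_sites = 2000)
  expect_equal(cmp$ranking$ll[1], cmp$ranking$ll[2], tolerance = 1e-9)
})
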