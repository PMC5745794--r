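test_that("expected SFS is a normalized spectrum with the neutral 1/i shape", {
  m <- const_model(N = 1e4)
  e <- expected_sfs(m, 10, n_sims = 4000, seed = 2, fold = FALSE)
  expect_equal(sum(e$counts[!e$mask]), 1)
  shape <- e$counts[2:10, 1] / e$counts[2, 1]
  theory <- (1 / 1:9)
  expect_lt(max(abs(shape - theory)), 0.06)
  expect_error(expected_sfs(m, c(5, 5), 100, seed = 1), "1-deme")
})

test_that("a panmictic split gives a deme-exchange-symmetric joint SFS", {
  m <- two_deme_model(N1 = 1e4, N2 = 1e4, t_div = 1, N_anc = 1e4)
  e <- expected_sfs(m, c(6, 6), n_sims = 6000, seed = 3, fold = FALSE)
  asym <- abs(e$counts - t(e$counts))
  expect_lt(max(asym), 0.01)
})

test_that("composite log-likelihood matches hand arithmetic", {
  mk <- function(counts, mask) coalsweep:::new_joint_sfs(
    counts, c(1, 1), FALSE, mask)
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  obs <- mk(matrix(c(0, 30, 70, 0), 2), mask)
  ex <- mk(matrix(c(0, 0.5, 0.5, 0), 2), mask)
  expect_equal(composite_log_likelihood(obs, ex, min_support = 1),
               100 * log(0.5))
  # self-consistency: expected = observed proportions attains the
  # multinomial maximum over any alternative expectation
  obs2 <- mk(matrix(c(0, 40, 60, 0), 2), mask)
  exact <- mk(matrix(c(0, .4, .6, 0), 2), mask)
  ll_max <- composite_log_likelihood(obs2, exact, min_support = 1)
  expect_equal(ll_max, 40 * log(.4) + 60 * log(.6))
  expect_gt(ll_max, composite_log_likelihood(obs2, ex, min_support = 1))
})

test_that("cells under the support threshold are ignored", {
  mask <- matrix(FALSE, 2, 2)
  mk <- function(counts) coalsweep:::new_joint_sfs(counts, c(1, 1), FALSE, mask)
  obs <- mk(matrix(c(9, 30, 70, 9), 2))
  ex <- mk(matrix(c(0.25, 0.25, 0.25, 0.25), 2))
  # the two 9-count cells drop; expectation renormalizes to (0.5, 0.5)
  expect_equal(composite_log_likelihood(obs, ex, min_support = 10),
               100 * log(0.5))
  expect_error(composite_log_likelihood(mk(matrix(1, 2, 2)), ex,
                                        min_support = 10), "masked")
  # dimension mismatch
  ex2 <- coalsweep:::new_joint_sfs(matrix(0.5, 1, 2), c(1, 1), FALSE,
                                   matrix(FALSE, 1, 2))
  expect_error(composite_log_likelihood(obs, ex2), "match")
})

test_that("fitting recovers an identifiable size parameter", {
  # two-epoch model: recent size free; shape of the SFS identifies it
  truth <- demographic_model(
    epochs = data.frame(deme = 1, t_start = c(0, 8000), size = c(5e4, 1.5e4)),
    n_demes = 1
  )
  ests <- vapply(1:5, function(s) {
    obs <- simulate_sfs_dataset(truth, 5e4, 12, n_sims = 2e4, seed = 100 + s)
    fit <- fit_model(obs, truth, bounds = list(n1_e1 = c(5e3, 5e5)),
                     n_runs = 4, sims_schedule = c(5e3, 5e3), n_cycles = 6,
                     seed = 300 + s)
    unname(fit$estimate)
  }, double(1))
  expect_lt(abs(median(ests) - 5e4) / 5e4, 0.15)
})

test_that("collapsed bounds return the pinned point with its likelihood", {
  m <- const_model(N = 2e4)
  obs <- simulate_sfs_dataset(m, 1e4, 8, n_sims = 5e3, seed = 4)
  fit <- fit_model(obs, m, bounds = list(n1_e1 = c(2e4, 2e4)), n_runs = 2,
                   sims_schedule = c(2e3, 2e3), n_cycles = 2, seed = 5)
  expect_equal(unname(fit$estimate), 2e4)
  expect_true(is.finite(fit$loglik))
  expect_equal(fit$k, 0)
  expect_equal(nrow(tidy(fit)), 1)
  expect_equal(glance(fit)$AIC, 2 * 0 - 2 * fit$loglik)
})

test_that("AIC comparison reproduces closed forms and is order-invariant", {
  fake_fit <- function(id, ll, k) {
    structure(list(model_id = id, loglik = ll, k = k, converged = TRUE,
                   n_snps = 100), class = "demog_fit")
  }
  one <- compare_models(list(fake_fit("a", -10, 2)))
  expect_equal(one$weight, 1)
  # equal k, delta logLik = 1 -> delta AIC = 2 -> weights (0.731, 0.269)
  two <- compare_models(list(fake_fit("a", -10, 2), fake_fit("b", -11, 2)))
  expect_equal(two$delta_AIC, c(0, 2))
  expect_equal(round(two$weight, 3), c(0.731, 0.269))
  expect_equal(sum(two$weight), 1)
  perm <- compare_models(list(fake_fit("b", -11, 2), fake_fit("a", -10, 2)))
  expect_equal(as.data.frame(perm), as.data.frame(two))
})

test_that("a superfluous parameter raises AIC on recovery data", {
  truth <- demographic_model(
    epochs = data.frame(deme = 1, t_start = c(0, 8000), size = c(5e4, 1.5e4)),
    n_demes = 1
  )
  wins <- 0
  for (s in 1:5) {
    obs <- simulate_sfs_dataset(truth, 3e4, 10, n_sims = 1e4, seed = 40 + s)
    fit1 <- fit_model(obs, truth, bounds = list(n1_e1 = c(1e4, 2e5)),
                      n_runs = 3, sims_schedule = c(4e3, 4e3), n_cycles = 4,
                      seed = 50 + s)
    fit2 <- fit_model(obs, truth,
                      bounds = list(n1_e1 = c(1e4, 2e5),
                                    t1_e2 = c(2000, 30000)),
                      n_runs = 3, sims_schedule = c(4e3, 4e3), n_cycles = 4,
                      seed = 60 + s)
    cmp <- compare_models(list(fit1, fit2))
    if (cmp$model[1] == fit1$model_id || cmp$k[1] == 1) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("parametric bootstrap brackets the point estimate", {
  truth <- demographic_model(
    epochs = data.frame(deme = 1, t_start = c(0, 8000), size = c(5e4, 1.5e4)),
    n_demes = 1
  )
  obs <- simulate_sfs_dataset(truth, 5e4, 10, n_sims = 2e4, seed = 77)
  fit <- fit_model(obs, truth, bounds = list(n1_e1 = c(5e3, 5e5)),
                   n_runs = 3, sims_schedule = c(5e3, 5e3), n_cycles = 5,
                   seed = 78)
  ci <- bootstrap_ci(fit, n_boot = 8, seed = 79, n_runs = 2, n_cycles = 3,
                     n_sims = 5e3)
  expect_equal(nrow(ci), 1)
  expect_lte(ci$ci_low, fit$estimate + 1)
  expect_gte(ci$ci_high, fit$estimate - 1)
  expect_true(ci$ci_low <= ci$ci_high)
  expect_identical(attr(ci, "n_failed"), 0L)
  expect_equal(dim(attr(ci, "replicates")), c(8L, 1L))
})

test_that("generation-time calibration scales only time parameters", {
  v <- c(t_div = 61409, n_anc = 179724, m12_w1 = 1e-5, tw1_start = 14307)
  out1 <- years_from_generations(v, g = 1)
  expect_equal(out1$calibrated[out1$term == "t_div"], 61409)
  out2 <- years_from_generations(v, g = 2)
  expect_equal(out2$calibrated[out2$term == "t_div"], 2 * 61409)
  expect_equal(out2$calibrated[out2$term == "tw1_start"], 2 * 14307)
  expect_equal(out2$calibrated[out2$term == "n_anc"], 179724)
  expect_equal(out2$calibrated[out2$term == "m12_w1"], 1e-5)
  expect_error(years_from_generations(v, g = 0), "g must be")
})

test_that("likelihood scales linearly in the total SNP count", {
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  mk <- function(counts) coalsweep:::new_joint_sfs(counts, c(1, 1), FALSE, mask)
  obs1 <- mk(matrix(c(0, 30, 70, 0), 2))
  obs3 <- mk(matrix(c(0, 90, 210, 0), 2))
  ex <- mk(matrix(c(0, .5, .5, 0), 2))
  expect_equal(composite_log_likelihood(obs3, ex, min_support = 1),
               3 * composite_log_likelihood(obs1, ex, min_support = 1))
})
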