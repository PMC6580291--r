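# Poisson composite likelihood, fitting, and AIC model selection.

test_that("the composite likelihood is saturated when the model matches", {
  obs <- hybridscape:::new_jafs(array(c(0, 3, 7, 0), c(2, 2)), c(1L, 1L))
  model <- hybridscape:::new_jafs(array(c(9, 0.3, 0.7, 9), c(2, 2)) , c(1L, 1L))
  res <- poisson_loglik(obs, model)
  expect_equal(res$theta_hat, 10)
  o <- c(3, 7)
  expect_equal(res$loglik, sum(o * log(o) - o - lgamma(o + 1)))
  # doubling the per-theta model halves theta and leaves the loglik alone
  model2 <- hybridscape:::new_jafs(2 * model$entries, c(1L, 1L))
  res2 <- poisson_loglik(obs, model2)
  expect_equal(res2$theta_hat, 5)
  expect_equal(res2$loglik, res$loglik)
})

test_that("a hand-computed toy spectrum gives the expected likelihood", {
  obs <- hybridscape:::new_jafs(array(c(0, 4, 2, 0), c(2, 2)), c(1L, 1L))
  model <- hybridscape:::new_jafs(array(c(1, 1, 2, 1), c(2, 2)), c(1L, 1L))
  res <- poisson_loglik(obs, model)
  theta <- 6 / 3
  by_hand <- (4 * log(theta * 1) - theta * 1 - lgamma(5)) +
             (2 * log(theta * 2) - theta * 2 - lgamma(3))
  expect_equal(res$theta_hat, theta)
  expect_equal(res$loglik, by_hand)
  bad <- hybridscape:::new_jafs(array(1, c(3, 3)), c(2L, 2L))
  expect_error(poisson_loglik(obs, bad), "shape")
})

test_that("AIC is 2k - 2 lnL for fits and raw likelihood values", {
  expect_equal(aic(0, k = 0), 0)
  expect_equal(aic(-10, k = 2), 24)
  fit <- structure(list(model = "SI", k = 3, loglik = -100),
                   class = "scenario_fit")
  expect_equal(aic(fit), 206)
})

test_that("the selection table satisfies the score, weight and retention rules", {
  tab <- model_selection(data.frame(model = c("a", "b", "c"),
                                    loglik = c(-50, -52.5, -60),
                                    k = c(0, 0, 0)))
  expect_equal(tab$AIC, c(100, 105, 120))
  expect_equal(tab$delta_aic, c(0, 5, 20))
  expect_equal(tab$score, c(1, 0.75, 0))
  w <- exp(-c(0, 5, 20) / 2)
  expect_equal(tab$w_aic, w / sum(w))
  expect_equal(tab$retained, c(TRUE, TRUE, FALSE))
  # two tied models share the weight (and trip the flat-score warning)
  expect_warning(
    tied <- model_selection(data.frame(model = c("a", "b"),
                                       loglik = c(-1, -1), k = c(1, 1))),
    "identical AIC")
  expect_equal(tied$w_aic, c(0.5, 0.5))
  expect_equal(tied$score, c(1, 1))
  # a dominating model takes essentially all the weight
  dom <- model_selection(data.frame(model = c("best", "other"),
                                    loglik = c(-10, -20), k = c(2, 2)))
  expect_gt(dom$w_aic[dom$model == "best"], 0.99)
  expect_error(model_selection(data.frame(model = "a", loglik = 1, k = 1)),
               "at least two")
})

test_that("selection identities hold on random fit collections", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    tab <- suppressWarnings(model_selection(data.frame(
      model = paste0("m", seq_len(n)),
      loglik = round(-runif(n, 10, 200), 2),
      k = sample(3:10, n, replace = TRUE)
    )))
    expect_equal(sum(tab$w_aic), 1, tolerance = 1e-12)
    expect_true(all(tab$score >= 0 & tab$score <= 1))
    expect_equal(sum(tab$delta_aic == 0) >= 1, TRUE)
    expect_equal(tab$retained, tab$delta_aic < 10)
    expect_equal(tab$score[which.min(tab$AIC)], 1)
  }
})

test_that("fits are deterministic given a seed", {
  sim <- gen_species_complex("SI", list(nu1 = 1, nu2 = 0.5, Ts = 0.5),
                             n_ind = 8, n_tags = 400, theta_tag = 0,
                             missing_rate = 0, species = c("A", "B"), seed = 2)
  obs <- project_jafs(build_jafs(sim$gm, c("A", "B")), c(10, 10))
  f1 <- fit_scenario(obs, "SI", n_restarts = 1, seed = 3, n_reps = 2000, maxit = 40)
  f2 <- fit_scenario(obs, "SI", n_restarts = 1, seed = 3, n_reps = 2000, maxit = 40)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(glance(f1)$AIC, glance(f2)$AIC)
  expect_named(tidy(f1), c("term", "estimate"))
})

test_that("the generating model outscores a nested restriction of itself", {
  sim <- gen_species_complex("IM", list(nu1 = 1, nu2 = 0.5, M12 = 0.5, M21 = 0.25, Ts = 1),
                             n_ind = 15, n_tags = 1500, theta_tag = 0,
                             missing_rate = 0, species = c("A", "B"), seed = 22)
  obs <- project_jafs(build_jafs(sim$gm, c("A", "B")), c(12, 12))
  fit_si <- fit_scenario(obs, "SI", n_restarts = 2, seed = 5, n_reps = 8000, maxit = 300)
  # start the richer model from the nested optimum as well as its default,
  # so its maximized likelihood dominates by construction
  init_im <- c(fit_si$par, list(M12 = 0.05, M21 = 0.05))
  fit_im <- fit_scenario(obs, "IM", n_restarts = 2, seed = 5, n_reps = 8000,
                         maxit = 400, init = init_im[model_params("IM")])
  expect_gte(fit_im$loglik, fit_si$loglik)
})
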