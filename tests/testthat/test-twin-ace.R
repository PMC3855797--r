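test_that("twin log-likelihood matches independence and a direct density oracle", {
  tw <- simulate_twin_trait(40, 60, 0.5, 0.2, seed = 31)
  pairs <- pairs_from_sim(tw)
  # independence factorization at (0, 0, 1)
  ll_ind <- twin_loglik(pairs, 0, 0, 1)
  expect_equal(ll_ind, sum(dnorm(c(tw$mz, tw$dz), log = TRUE)),
               tolerance = 1e-10)
  # brute-force per-pair 2x2 multivariate normal evaluation
  for (par in list(c(0.5, 0.2, 0.3), c(0.1, 0.1, 1.2), c(0, 0.6, 0.4))) {
    smz <- matrix(c(sum(par), par[1] + par[2], par[1] + par[2], sum(par)), 2)
    sdz <- matrix(c(sum(par), par[1] / 2 + par[2], par[1] / 2 + par[2],
                    sum(par)), 2)
    brute <- sum(apply(tw$mz, 1, dmvnorm2_log, sigma = smz)) +
      sum(apply(tw$dz, 1, dmvnorm2_log, sigma = sdz))
    expect_equal(twin_loglik(pairs, par[1], par[2], par[3]), brute,
                 tolerance = 1e-10)
  }
  # permutation invariance
  expect_equal(twin_loglik(pairs[sample(nrow(pairs)), ], 0.5, 0.2, 0.3),
               twin_loglik(pairs, 0.5, 0.2, 0.3))
  expect_error(twin_loglik(pairs, -0.1, 0, 1), "nonnegative")
})

test_that("the ACE fit attains the Falconer closed form in large samples", {
  # population rMZ = 0.75, rDZ = 0.45 -> a2 = 0.60, c2 = 0.15, e2 = 0.25
  tw <- simulate_twin_trait(2e5, 2e5, 0.6, 0.15, seed = 32)
  fit <- twin_ace(pairs_from_sim(tw), model = "ACE", ci = FALSE)
  expect_equal(unname(coef(fit)), c(0.60, 0.15, 0.25), tolerance = 0.01)
})

test_that("submodel fits recover planted structure and respect nesting", {
  # strong AE trait: a2 = 0.8 recovered within 0.03 at n = 5000/5000
  tw <- simulate_twin_trait(5000, 5000, 0.8, 0, seed = 33)
  pairs <- pairs_from_sim(tw)
  fit_ae <- twin_ace(pairs, model = "AE", ci = FALSE)
  expect_lt(abs(coef(fit_ae)["a2"] - 0.8), 0.03)
  expect_identical(unname(coef(fit_ae)["c2"]), 0)

  # E model forces independence
  fit_e <- twin_ace(pairs, model = "E", ci = FALSE)
  expect_equal(unname(coef(fit_e)), c(0, 0, 1))
  ve <- unname(fit_e$variances["ve"])
  expect_equal(fit_e$loglik, twin_loglik(pairs, 0, 0, ve), tolerance = 1e-8)

  # nesting: ACE >= AE >= E and ACE >= CE >= E on arbitrary data
  for (s in 34:36) {
    twx <- simulate_twin_trait(300, 300, runif(1, 0, 0.6), runif(1, 0, 0.3),
                               seed = s)
    px <- pairs_from_sim(twx)
    ll <- vapply(c("ACE", "AE", "CE", "E"),
                 function(m) twin_ace(px, model = m, ci = FALSE)$loglik,
                 numeric(1))
    expect_gte(ll["ACE"] + 1e-6, ll["AE"])
    expect_gte(ll["ACE"] + 1e-6, ll["CE"])
    expect_gte(ll["AE"] + 1e-6, ll["E"])
    expect_gte(ll["CE"] + 1e-6, ll["E"])
  }
})

test_that("parameter recovery holds across a grid of variance structures", {
  grid <- expand.grid(a2 = c(0, 0.3, 0.6), c2 = c(0, 0.15, 0.3))
  for (i in seq_len(nrow(grid))) {
    tw <- simulate_twin_trait(5000, 5000, grid$a2[i], grid$c2[i],
                              seed = 40 + i)
    fit <- twin_ace(pairs_from_sim(tw), model = "ACE", ci = FALSE)
    expect_lt(abs(coef(fit)["a2"] - grid$a2[i]), 0.03)
    expect_lt(abs(coef(fit)["c2"] - grid$c2[i]), 0.03)
  }
})

test_that("model selection follows sequential drops with AIC arbitration", {
  # pure noise: E chosen in at least 80% of replicates
  set.seed(51)
  pick <- replicate(100, {
    tw <- simulate_twin_trait(500, 500, 0, 0)
    twin_ace(pairs_from_sim(tw), ci = FALSE)$model
  })
  expect_gte(sum(pick == "E"), 80)

  # strong additive trait: AE chosen in at least 90% of replicates
  set.seed(52)
  pick2 <- replicate(100, {
    tw <- simulate_twin_trait(2000, 2000, 0.7, 0)
    twin_ace(pairs_from_sim(tw), ci = FALSE)$model
  })
  expect_gte(sum(pick2 == "AE"), 90)

  # identical logliks (c2 estimate exactly 0): AE wins on AIC by 2
  fits <- list(
    ACE = list(model = "ACE", loglik = -100, k = 3L, aic = 206),
    AE = list(model = "AE", loglik = -100, k = 2L, aic = 204),
    CE = list(model = "CE", loglik = -120, k = 2L, aic = 244),
    E = list(model = "E", loglik = -125, k = 1L, aic = 252))
  sel <- select_best_model(fits)
  expect_identical(sel$model, "AE")
  expect_true(all(c("model", "aic", "lrt_p", "accepted") %in%
                    names(sel$trace)))
  expect_error(select_best_model(fits[c("ACE", "AE")]), "missing submodel")
})

test_that("profile confidence intervals are coherent and cover boundaries", {
  tw <- simulate_twin_trait(400, 500, 0.6, 0, seed = 53)
  fit <- twin_ace(pairs_from_sim(tw), model = "AE")
  ci_a <- confint(fit, "a2")
  ci_e <- confint(fit, "e2")
  # standardized complement: CI(a2) = 1 - CI(e2) reversed
  expect_equal(unname(ci_a[1, ]), unname(1 - ci_e[1, 2:1]), tolerance = 1e-3)
  expect_true(ci_a[1, 1] < coef(fit)["a2"] &&
                coef(fit)["a2"] < ci_a[1, 2])

  # degenerate data: 3 pairs per zygosity give a wide interval floored at 0
  tw3 <- simulate_twin_trait(3, 3, 0.3, 0, seed = 54)
  fit3 <- twin_ace(pairs_from_sim(tw3), model = "AE")
  ci3 <- confint(fit3, "a2")
  expect_equal(unname(ci3[1, 1]), 0)
  expect_gt(ci3[1, 2] - ci3[1, 1], 0.5)

  # components fixed at zero by the model carry no interval
  expect_true(all(is.na(confint(fit, "c2"))))
})

test_that("double-entry ICC matches the ANOVA oracle and its limits", {
  expect_equal(twin_icc(cbind(1:3, 1:3))$estimate, 1)
  expect_equal(twin_icc(cbind(c(1, 2, 0), c(-1, -2, 0)))$estimate, -1)
  expect_error(twin_icc(cbind(1:2, 1:2)), "3 complete pairs")
  set.seed(55)
  for (r in 1:50) {
    tw <- simulate_twin_trait(200, 1, 0.5, 0.1)
    icc <- twin_icc(tw$mz)
    expect_lt(abs(icc$estimate - anova_icc(tw$mz)), 0.02)
    expect_true(icc$lower < icc$estimate && icc$estimate < icc$upper)
  }
})

test_that("twin_ace S3 methods expose the fit consistently", {
  tw <- simulate_twin_trait(300, 400, 0.6, 0.1, seed = 56)
  fit <- twin_ace(pairs_from_sim(tw))
  expect_s3_class(fit, "twin_ace")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-6)
  expect_true(all(coef(fit) >= 0))
  ll <- logLik(fit)
  expect_equal(AIC(ll), fit$aic)
  out <- capture.output(print(fit))
  expect_true(any(grepl("Best model", out)))
  expect_true(any(grepl("ICC\\(MZ\\)", out)))
  sims <- simulate(fit, nsim = 2, seed = 57)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 700)
  # a refit on data simulated from the fit lands near the estimates
  refit <- twin_ace(sims[[1]], model = fit$model, ci = FALSE)
  expect_lt(abs(coef(refit)["a2"] - coef(fit)["a2"]), 0.15)
})
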