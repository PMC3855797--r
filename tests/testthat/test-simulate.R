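test_that("twin trait simulation honors the ACE covariance structure", {
  # degenerate: fully additive -> MZ co-twins identical, DZ correlation 1/2
  tw <- simulate_twin_trait(500, 50000, a2 = 1, c2 = 0, seed = 1)
  expect_equal(tw$mz[, 1], tw$mz[, 2])
  expect_lt(abs(cor(tw$dz[, 1], tw$dz[, 2]) - 0.5), 0.02)

  # independence: no familial components -> both correlations vanish
  tw0 <- simulate_twin_trait(50000, 50000, a2 = 0, c2 = 0, seed = 2)
  expect_lt(abs(cor(tw0$mz[, 1], tw0$mz[, 2])), 0.02)
  expect_lt(abs(cor(tw0$dz[, 1], tw0$dz[, 2])), 0.02)

  # Monte-Carlo check against the closed-form cross-twin covariances
  tw2 <- simulate_twin_trait(1e5, 1e5, a2 = 0.7, c2 = 0.1, seed = 3)
  expect_lt(abs(cor(tw2$mz[, 1], tw2$mz[, 2]) - 0.8), 0.01)
  expect_lt(abs(cor(tw2$dz[, 1], tw2$dz[, 2]) - 0.45), 0.01)

  expect_error(simulate_twin_trait(10, 10, a2 = 0.8, c2 = 0.4), "a2")
  expect_error(simulate_twin_trait(10, 10, a2 = -0.1, c2 = 0), "a2")
})

test_that("simulated marginals are standardized and reproducible", {
  for (spec in list(c(0.6, 0.2), c(0, 0.5), c(0.8, 0))) {
    tw <- simulate_twin_trait(20000, 20000, spec[1], spec[2], seed = 9)
    vals <- c(tw$mz, tw$dz)
    expect_lt(abs(var(vals) - 1), 4 / sqrt(length(vals) / 2))
    expect_lt(abs(cov(tw$mz[, 1], tw$mz[, 2]) - sum(spec)), 4 / sqrt(20000))
    expect_lt(abs(cov(tw$dz[, 1], tw$dz[, 2]) - (spec[1] / 2 + spec[2])),
              4 / sqrt(20000))
  }
  expect_identical(simulate_twin_trait(50, 50, 0.5, 0.2, seed = 4),
                   simulate_twin_trait(50, 50, 0.5, 0.2, seed = 4))
})

test_that("covariate simulation shares age within pairs and uses all batches", {
  pt <- make_pair_table(300, 200)
  cv <- simulate_covariates(pt, list(age_mean = 58.71, age_sd = 9.37,
                                     n_batches = 4), seed = 5)
  expect_equal(nrow(cv), 1000)
  age1 <- cv$age[match(pt$sample_1, cv$sample_id)]
  age2 <- cv$age[match(pt$sample_2, cv$sample_id)]
  expect_equal(age1, age2)
  expect_true(all(cv$sex == "F"))
  expect_setequal(unique(cv$batch), 1:4)
  # sample mean within 3 standard errors of the configured mean
  expect_lt(abs(mean(age1) - 58.71), 3 * 9.37 / sqrt(500))
  # zero-variance age collapses to the mean
  cv0 <- simulate_covariates(pt[1:2, ], list(age_sd = 0, age_mean = 58))
  expect_true(all(cv0$age == 58))
  expect_error(simulate_covariates(pt[0, ]), "empty")
})

test_that("peak profiles live on the 100% simplex with configured means", {
  means <- default_peak_means()
  x <- simulate_peak_profiles(4000, list(means = means, dispersion = 0.01),
                              seed = 6)
  expect_equal(unname(rowSums(x)), rep(100, 4000), tolerance = 1e-9)
  # per-peak sample means within 3 SE of targets (check the major peaks)
  for (pk in c("GP4", "GP8", "GP14")) {
    se <- sd(x[, pk]) / sqrt(nrow(x))
    expect_lt(abs(mean(x[, pk]) - means[pk]), 3 * se)
  }
  # larger dispersion -> strictly larger per-peak variance, same seed pattern
  lo <- simulate_peak_profiles(2000, list(means = means, dispersion = 0.005),
                               seed = 7)
  hi <- simulate_peak_profiles(2000, list(means = means, dispersion = 0.05),
                               seed = 7)
  expect_true(all(apply(hi, 2, var) > apply(lo, 2, var)))
  expect_error(simulate_peak_profiles(5, list(means = means[1:23])), "24")
  bad <- means; bad[1] <- bad[1] + 5
  expect_error(simulate_peak_profiles(5, list(means = bad)), "100")
})

test_that("methylation probes are standardized with family structure and planted effects", {
  pt <- make_pair_table(400, 400)
  traits <- matrix(rnorm(1600), 1600, 1,
                   dimnames = list(c(rbind(pt$sample_1, pt$sample_2)), "t1"))
  mm <- list(n_probes = 50, family_var = 0.4,
             planted = data.frame(probe = "cg0000001", trait = "t1",
                                  beta = 0.35))
  res <- simulate_methylation(pt, traits, mm, seed = 8)
  expect_equal(dim(res$methyl), c(1600, 50))
  expect_lt(max(abs(colMeans(res$methyl))), 0.15)
  expect_lt(max(abs(apply(res$methyl, 2, var) - 1)), 0.25)
  # co-twin correlation of a probe reflects the family intercept share
  m1 <- res$methyl[pt$sample_1, 2]; m2 <- res$methyl[pt$sample_2, 2]
  expect_lt(abs(cor(m1, m2) - 0.4), 0.15)
  # the planted effect is wired into the trait generating equation
  delta <- res$traits[, "t1"] - traits[, "t1"]
  expect_equal(unname(delta), unname(0.35 * res$methyl[, "cg0000001"]))
  expect_error(
    simulate_methylation(pt, traits,
                         list(n_probes = 10,
                              planted = data.frame(probe = "cg1", trait = "nope",
                                                   beta = 1))),
    "unknown traits")
})

test_that("cohort simulation is deterministic with a faithful truth block", {
  cfg <- simulation_config(n_mz = 60, n_dz = 80,
                           methyl_model = list(n_probes = 30), seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$traits, c2$traits)
  expect_identical(c1$peaks, c2$peaks)
  expect_identical(c1$methyl, c2$methyl)
  expect_identical(c1$truth, cfg)
  # every sample belongs to exactly one pair, two members each
  ids <- c(c1$pairs$sample_1, c1$pairs$sample_2)
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(rownames(c1$traits), ids)
  # truth block round-trips through the on-disk YAML form
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$n_mz, cfg$n_mz)
  expect_equal(truth$seed, cfg$seed)
  expect_equal(unlist(truth$trait_specs$a2), cfg$trait_specs$a2)
})

test_that("cohort trait cross-twin covariances match their generating spec", {
  cfg <- simulation_config(n_mz = 2500, n_dz = 2500,
                           methyl_model = list(n_probes = 2), seed = 12)
  ch <- simulate_cohort(cfg)
  is_mz <- ch$pairs$zygosity == "MZ"
  for (j in seq_len(nrow(cfg$trait_specs))) {
    sp <- cfg$trait_specs[j, ]
    v1 <- ch$traits[ch$pairs$sample_1, sp$name]
    v2 <- ch$traits[ch$pairs$sample_2, sp$name]
    tol <- 4 / sqrt(2500)
    expect_lt(abs(cov(v1[is_mz], v2[is_mz]) - (sp$a2 + sp$c2)), tol)
    expect_lt(abs(cov(v1[!is_mz], v2[!is_mz]) - (sp$a2 / 2 + sp$c2)), tol)
    expect_lt(abs(var(c(v1, v2)) - 1), tol)
  }
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_mz = 0), "at least one pair")
  bad <- default_trait_specs(); bad$a2[1] <- 0.5
  expect_error(simulation_config(trait_specs = bad), "equal 1")
  expect_error(simulation_config(methyl_model = list(n_probes = 1,
    planted = data.frame(probe = c("a", "b"), trait = "trait_h80",
                         beta = 0.1))), "fewer probes")
  expect_error(simulation_config(peak_model = list(dispersion = -1)),
               "dispersion")
})
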