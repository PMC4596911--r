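test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(maf = 0.3), "sim_config")
  expect_error(sim_config(maf = 0), "maf")
  expect_error(sim_config(maf = 0.3, odds_ratio = -1))
  expect_error(sim_config(maf = 0.3, disease_model = "recessive",
                          chromosome = "X"), "additive")
  expect_equal(sim_config(maf = 0.1, scheme = "Mixed")$n_case_families, 600L)
})

test_that("ascertainment accepts exactly the scheme's affection pattern", {
  expect_true(ascertain(c(1, 0, 0), "ASP1"))
  expect_false(ascertain(c(1, 0, 0), "ASP2"))
  expect_false(ascertain(c(1, 0, 0), "ASP3"))
  expect_true(ascertain(c(1, 1, 0), "ASP2"))
  expect_true(ascertain(c(1, 1, 1), "ASP3"))
  expect_equal(ascertain(rbind(c(1, 1, 1), c(0, 1, 0)), "ASP3"),
               c(TRUE, FALSE))
})

test_that("baseline affection rate matches the disease model", {
  set.seed(41)
  cfg <- sim_config(maf = 0.3, odds_ratio = 1, sigma_u2 = 0)
  fam <- simulate_family(cfg, 100000)
  rate <- mean(fam$aff)
  se <- sqrt(0.1 * 0.9 / length(fam$aff))
  expect_lt(abs(rate - 0.10), 3 * se)

  # with a family effect the marginal rate is the logistic-normal integral
  cfg1 <- sim_config(maf = 0.3, odds_ratio = 1, sigma_u2 = 1)
  fam1 <- simulate_family(cfg1, 100000)
  oracle <- stats::integrate(function(u)
    stats::plogis(stats::qlogis(0.1) + u) * stats::dnorm(u, 0, 1),
    -Inf, Inf)$value
  se1 <- sqrt(oracle * (1 - oracle) / length(fam1$aff))
  expect_lt(abs(mean(fam1$aff) - oracle), 3 * se1)
})

test_that("Mendelian transmission preserves the allele frequency", {
  set.seed(42)
  cfg <- sim_config(maf = 0.2, odds_ratio = 1.5)
  fam <- simulate_family(cfg, 50000)
  af <- mean(fam$geno) / 2
  expect_lt(abs(af - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * length(fam$geno))))

  cfgx <- sim_config(maf = 0.2, odds_ratio = 1, chromosome = "X")
  famx <- simulate_family(cfgx, 50000)
  alleles <- ifelse(famx$sex == "male", 1L, 2L)
  afx <- sum(famx$geno) / sum(alleles)
  expect_lt(abs(afx - 0.2), 3 * sqrt(0.2 * 0.8 / sum(alleles)))
  # males carry a single allele
  expect_true(all(famx$geno[famx$sex == "male"] <= 1))
})

test_that("simulated datasets honour quota, schemes and structure", {
  set.seed(43)
  cfg <- sim_config(maf = 0.3, scheme = "Mixed", n_case_families = 600,
                    n_controls = 600)
  ds <- simulate_dataset(cfg)
  expect_equal(as.integer(table(ds$scheme)), c(200L, 200L, 200L))
  expect_equal(length(ds$case_geno), 600L)
  expect_equal(length(ds$control_geno), 600L)

  # ASP1: both un-genotyped sibs unaffected; ASP3: both affected
  expect_true(all(ds$sib_aff[ds$scheme == "ASP1", ] == 0))
  expect_true(all(ds$sib_aff[ds$scheme == "ASP3", ] == 1))
  expect_true(all(rowSums(ds$sib_aff[ds$scheme == "ASP2", ]) == 1))

  # under H0, case and control allele frequencies agree
  p_case <- mean(ds$case_geno) / 2
  p_ctl <- mean(ds$control_geno) / 2
  expect_lt(abs(p_case - p_ctl),
            3 * sqrt(0.3 * 0.7 / (2 * 600) + 0.3 * 0.7 / (2 * 600)))
})

test_that("ascertainment under H0 does not distort sib genotype IBD", {
  # gene-dropping check: correlation between the case genotype and an
  # (internally tracked) sib genotype under OR = 1 should be ~ 0.5
  set.seed(44)
  cfg <- sim_config(maf = 0.3, odds_ratio = 1, scheme = "ASP2",
                    n_case_families = 4000)
  fam <- simulate_family(cfg, 60000)
  keep <- rowSums(fam$aff) == 2
  r <- cor(fam$geno[keep, 1], fam$geno[keep, 2])
  se <- (1 - 0.25) / sqrt(sum(keep))
  expect_lt(abs(r - 0.5), 3 * se)
})

test_that("seeded runs are bit-reproducible", {
  cfg <- sim_config(maf = 0.3, replicates = 5, n_case_families = 50,
                    n_controls = 50)
  r1 <- empirical_rate(cfg, "ST", seed = 99)
  r2 <- empirical_rate(cfg, "ST", seed = 99)
  expect_identical(r1, r2)
  set.seed(7); d1 <- simulate_dataset(cfg)
  set.seed(7); d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("alpha = 1 rejects everything", {
  cfg <- sim_config(maf = 0.3, replicates = 5, n_case_families = 40,
                    n_controls = 40, alpha = 1)
  expect_equal(empirical_rate(cfg, "ST", seed = 5)$rate, 1)
})

test_that("the fast scoring kernel agrees with the full pipeline", {
  set.seed(45)
  for (setup in list(list(model = "additive", chrom = "autosome",
                          test = "ST"),
                     list(model = "additive", chrom = "autosome",
                          test = "ST_fam"),
                     list(model = "recessive", chrom = "autosome",
                          test = "ST_fam", maf = 0.4),
                     list(model = "additive", chrom = "X",
                          test = "ST_fam"))) {
    cfg <- sim_config(maf = if (is.null(setup$maf)) 0.3 else setup$maf,
                      odds_ratio = 1.4, scheme = "ASP2",
                      disease_model = setup$model,
                      chromosome = setup$chrom,
                      n_case_families = 60, n_controls = 60, replicates = 1)
    ds <- simulate_dataset(cfg)
    p_kernel <- famscore:::.kernel_test_p(ds, setup$test,
                                          famscore:::.template_sib_rho())
    dat <- sim_to_data(ds)
    res <- if (setup$test == "ST")
      run_score_test(dat$ped, dat$geno, "M1", model = setup$model)
    else
      weighted_score_test(dat$ped, dat$geno, "M1", model = setup$model)
    expect_equal(p_kernel, res$p, tolerance = 1e-10,
                 label = paste(setup$model, setup$chrom, setup$test))
  }
})

test_that("under H0 the replicate p-values are uniform", {
  cfg <- sim_config(maf = 0.3, odds_ratio = 1, scheme = "ASP1",
                    n_case_families = 200, n_controls = 200,
                    replicates = 1000)
  set.seed(46)
  tmpl <- famscore:::.template_sib_rho()
  pvals <- replicate(cfg$replicates,
                     famscore:::.kernel_test_p(simulate_dataset(cfg), "ST",
                                               tmpl))
  # ties are expected (finite genotype-count support), hence exact = FALSE
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("pathological configurations abort with a diagnostic", {
  cfg <- sim_config(maf = 1e-4, odds_ratio = 1, sigma_u2 = 0,
                    baseline_risk = 1e-4, scheme = "ASP3",
                    n_case_families = 5, n_controls = 5)
  expect_error(simulate_dataset(cfg), "acceptance probability")
})
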