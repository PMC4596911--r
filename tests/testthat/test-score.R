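test_that("genotype frequencies are counted correctly", {
  f <- estimate_frequencies(c(0, 0, 1, 1, 2, 2))
  expect_equal(f$p, rep(1/3, 3))
  expect_equal(f$p_hat, 0.5)
  expect_false(f$monomorphic)

  f0 <- estimate_frequencies(c(0, 0, 0, NA))
  expect_equal(f0$p_hat, 0)
  expect_true(f0$monomorphic)
  expect_error(estimate_frequencies(c(NA, NA)), "missing")

  # X: females contribute two alleles, males one
  fx <- estimate_frequencies(c(0, 1, 2, 0, 2),
                             sex = c("female", "female", "female",
                                     "male", "male"),
                             chromosome = "X")
  expect_equal(fx$p_hat, 0.5)
  expect_equal(fx$q_male, 0.5)
  expect_equal(fx$p_female, c(1/3, 1/3, 1/3))
})

test_that("genotypic variance matches the frequency-based formulas", {
  hwe <- estimate_frequencies(c(rep(0, 25), rep(1, 50), rep(2, 25)))
  expect_equal(genotype_variance(hwe, "additive"), 0.5)

  # all homozygotes, equiprobable: variance of X in {0,2} is 1
  f <- estimate_frequencies(c(0, 2))
  expect_equal(genotype_variance(f, "additive"), 1.0)

  frec <- list(p = c(0.7, 0.21, 0.09), chromosome = "autosome")
  class(frec) <- "genotype_frequencies"
  expect_equal(genotype_variance(frec, "recessive"), 0.09 * 0.91)
  expect_equal(genotype_variance(frec, "dominant"), 0.7 * 0.3)

  # monomorphic: zero variance, not an error
  mono <- estimate_frequencies(c(0, 0, 0))
  expect_equal(genotype_variance(mono, "additive"), 0)
})

test_that("score statistic and variance follow the quadratic forms", {
  y <- c(1, 1, 0, 0)
  x <- c(2, 1, 1, 0)
  expect_equal(score_statistic(y, x), 1.0)
  expect_equal(score_statistic(y, rep(1.3, 4)), 0)
  expect_equal(score_statistic(rep(1, 4), x), 0)
  expect_error(score_statistic(y, x[-1]), "length")

  # K = identity reduces to sigma^2 * sum((y - ybar)^2)
  expect_equal(score_variance(y, diag(4), sqrt(0.5)), 0.5)
  expect_equal(score_variance(rep(1, 4), diag(4), 1), 0)

  # sib pair of two cases + two unrelated controls, rho = 0.5
  K <- diag(4); K[1, 2] <- K[2, 1] <- 0.5
  expect_equal(score_variance(y, K, sqrt(0.5)), 0.625)
})

test_that("chi-square p-values hit the reference quantiles", {
  expect_equal(chi_square_p(sqrt(stats::qchisq(0.95, 1)), 1), 0.05)
  expect_equal(chi_square_p(sqrt(stats::qchisq(0.99, 1)), 1), 0.01)
  expect_equal(chi_square_p(0, 1), 1)
  expect_true(is.na(chi_square_p(1, 0)))
})

test_that("unrelated-sample test equals the Cochran-Armitage trend test", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 200
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    dat <- unrelated_cc_data(g, y)
    res <- run_score_test(dat$ped, dat$geno, "M1")
    expect_equal(res$chi2, ca_trend_chi2(g, y), tolerance = 1e-8)
  }
})

test_that("dominant model equals recessive model after allele swap", {
  set.seed(12)
  g <- rbinom(120, 2, 0.4)
  y <- rbinom(120, 1, 0.5)
  dat <- unrelated_cc_data(g, y)
  dat_sw <- unrelated_cc_data(2 - g, y)
  dom <- run_score_test(dat$ped, dat$geno, "M1", model = "dominant")
  rec <- run_score_test(dat_sw$ped, dat_sw$geno, "M1", model = "recessive")
  expect_equal(dom$chi2, rec$chi2)
  expect_equal(dom$p, rec$p)
})

test_that("related samples shrink to the familial variance", {
  # two case sibs + two unrelated controls, additive, worked by hand above
  ped <- pedigree(fid = c("F", "F", "F", "F", "C1", "C2"),
                  iid = c("f", "m", "s1", "s2", "c1", "c2"),
                  father = c(NA, NA, "f", "f", NA, NA),
                  mother = c(NA, NA, "m", "m", NA, NA),
                  sex = c("male", "female", "female", "male", "male",
                          "female"),
                  affection = c(NA, NA, 1, 1, 0, 0))
  g <- c(2, 1, 1, 0)
  geno <- as_geno_matrix(matrix(g, 1, dimnames = list("M1",
                          c("s1", "s2", "c1", "c2"))),
                         data.frame(marker = "M1", chrom = "1", pos = 1,
                                    a1 = "A", a2 = "B"))
  res <- run_score_test(ped, geno, "M1")
  f <- estimate_frequencies(g)
  s2 <- genotype_variance(f, "additive")
  expect_equal(res$U, 1.0)
  expect_equal(res$V, s2 * (1 + 2 * 0.5 * 0.25))
  expect_equal(res$r2T, 1)
})

test_that("monomorphic markers come back degenerate", {
  dat <- unrelated_cc_data(rep(0, 10), rep(c(1, 0), 5))
  res <- run_score_test(dat$ped, dat$geno, "M1")
  expect_equal(res$status, "degenerate")
  expect_true(is.na(res$p))
})

test_that("X-linked test uses sex-specific variances and 0/2 male coding", {
  set.seed(13)
  n <- 300
  sex <- rep(c("male", "female"), length.out = n)
  g <- ifelse(sex == "male", 2 * rbinom(n, 1, 0.3), rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, 0.5)
  ped <- pedigree(fid = sprintf("U%03d", 1:n), iid = sprintf("i%03d", 1:n),
                  sex = sex, affection = y)
  geno <- as_geno_matrix(matrix(g, 1, dimnames = list("MX", ped$iid)),
                         data.frame(marker = "MX", chrom = "X", pos = 1,
                                    a1 = "A", a2 = "B"))
  res <- run_score_test(ped, geno, "MX")
  expect_equal(res$chromosome, "X")
  f <- estimate_frequencies(g, sex = sex, chromosome = "X")
  s2 <- genotype_variance(f, "additive")
  yc <- y - mean(y)
  Vman <- sum(yc^2 * ifelse(sex == "male", s2["male"], s2["female"]))
  expect_equal(res$V, Vman)
  expect_error(run_score_test(ped, geno, "MX", model = "recessive"),
               "additive")
})

test_that("null chi-squares follow the chi-squared(1) reference", {
  set.seed(14)
  n <- 400; reps <- 2000
  pvals <- numeric(reps)
  y <- rep(c(1, 0), n / 2)
  yc <- y - mean(y)
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.3)
    f <- estimate_frequencies(g)
    U <- sum(yc * g)
    V <- genotype_variance(f, "additive") * sum(yc^2)
    pvals[r] <- chi_square_p(U, V)
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.036)
  expect_lt(rate, 0.064)
})
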