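test_that("pair coefficients reproduce classical relationships exactly", {
  sib <- pair_coefficients(sib_ped(), "s1", "s2")
  expect_equal(c(sib$pi0, sib$pi1, sib$pi2), c(1/4, 1/2, 1/4))
  expect_equal(sib$phi, 1/4)

  dfc <- pair_coefficients(double_first_cousins_ped(), "i", "j")
  expect_equal(dfc$pi2, 1/16)
  expect_equal(dfc$pi1, 6/16)

  fc <- pair_coefficients(first_cousins_ped(), "i", "j")
  expect_equal(c(fc$pi0, fc$pi1, fc$pi2), c(3/4, 1/4, 0))

  po <- pair_coefficients(sib_ped(), "f", "s1")
  expect_equal(c(po$pi0, po$pi1, po$pi2), c(0, 1, 0))
  expect_equal(po$phi, 1/4)

  two <- pedigree(fid = c("A", "B"), iid = c("x", "y"),
                  sex = c("male", "female"))
  un <- pair_coefficients(two, "x", "y")
  expect_equal(c(un$pi0, un$pi1, un$pi2, un$phi, un$phiX), c(1, 0, 0, 0, 0))
})

test_that("model-specific correlations match their closed forms", {
  sib <- pair_coefficients(sib_ped(), "s1", "s2")
  expect_equal(additive_rho(sib), 1/2)
  expect_equal(additive_rho(pair_coefficients(double_first_cousins_ped(),
                                              "i", "j")), 1/4)
  # degree-3 relationship: rho = (1/2)^3
  expect_equal(additive_rho(pair_coefficients(first_cousins_ped(),
                                              "i", "j")), 1/8)

  # sib pair recessive at p: (1 + 3p) / (4 (1 + p))
  expect_equal(recessive_rho(sib, 0.2), (1 + 3 * 0.2) / (4 * 1.2))
  expect_equal(recessive_rho(sib, 0.2), 1/3)
  # p -> 1 recovers the additive value
  expect_equal(recessive_rho(sib, 1 - 1e-12), 1/2, tolerance = 1e-9)
  un <- pair_coefficients(pedigree(fid = c("A", "B"), iid = c("x", "y")),
                          "x", "y")
  expect_equal(recessive_rho(un, 0.37), 0)
  expect_error(recessive_rho(sib, 0), "frequency")
  # dominant = recessive after allele-label flip
  expect_equal(dominant_rho(sib, 0.2), recessive_rho(sib, 0.8))
})

test_that("X-linked correlations reproduce the printed pair values", {
  ped <- three_gen_ped()
  expect_equal(x_rho(ped, "s", "s2"), 3/4)            # full sisters
  expect_equal(x_rho(ped, "u", "n"), 1/(4 * sqrt(2))) # maternal uncle-niece
  expect_equal(x_rho(ped, "h", "b"), 0)               # father-son
  bros <- sib_ped(c("male", "male"))
  expect_equal(x_rho(bros, "s1", "s2"), 1/2)          # full brothers
  expect_equal(x_rho(bros, "m", "s1"), 1/sqrt(2))     # mother-son
  expect_equal(x_rho(bros, "f", "s1"), 0)             # father-son again
})

test_that("x_rho matches the X-transmission enumeration oracle exactly", {
  ped <- three_gen_ped()
  ids <- ped$iid
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      expect_equal(x_rho(ped, ids[a], ids[b]),
                   x_corr_enum(ped, ids[a], ids[b]),
                   tolerance = 1e-12,
                   label = paste("x_rho", ids[a], ids[b]))
    }
  }
})

test_that("correlations agree with an exact transmission-enumeration oracle", {
  for (p in c(0.1, 0.3, 0.5)) {
    for (cs in list(list(ped = sib_ped(), i = "s1", j = "s2"),
                    list(ped = first_cousins_ped(), i = "i", j = "j"),
                    list(ped = double_first_cousins_ped(), i = "i",
                         j = "j"),
                    list(ped = sib_ped(), i = "f", j = "s1"))) {
      pc <- pair_coefficients(cs$ped, cs$i, cs$j)
      expect_equal(additive_rho(pc),
                   pair_corr_exact(cs$ped, cs$i, cs$j, p, "additive"),
                   tolerance = 1e-12)
      expect_equal(recessive_rho(pc, p),
                   pair_corr_exact(cs$ped, cs$i, cs$j, p, "recessive"),
                   tolerance = 1e-12)
    }
  }
})

test_that("additive and recessive correlations agree with gene dropping", {
  set.seed(1)
  reps <- 200000
  cases <- list(list(ped = sib_ped(), i = "s1", j = "s2"),
                list(ped = first_cousins_ped(), i = "i", j = "j"),
                list(ped = double_first_cousins_ped(), i = "i", j = "j"))
  p <- 0.3
  for (cs in cases) {
    g <- gene_drop(cs$ped, p, reps)
    gi <- g[, match(cs$i, cs$ped$iid)]
    gj <- g[, match(cs$j, cs$ped$iid)]
    pc <- pair_coefficients(cs$ped, cs$i, cs$j)

    emp <- corr_with_se(gi, gj)
    expect_lt(abs(emp$est - additive_rho(pc)), 3 * emp$se + 1e-6)

    emp_rec <- corr_with_se(as.numeric(gi == 2), as.numeric(gj == 2))
    expect_lt(abs(emp_rec$est - recessive_rho(pc, p)),
              3 * emp_rec$se + 1e-6)
  }
})

test_that("correlation matrices have block structure and are PSD", {
  ped <- pedigree(fid = c("A", "A", "A", "A", "B", "C"),
                  iid = c("f", "m", "s1", "s2", "u1", "u2"),
                  father = c(NA, NA, "f", "f", NA, NA),
                  mother = c(NA, NA, "m", "m", NA, NA),
                  sex = c("male", "female", "female", "male", "male",
                          "female"))
  ids <- c("s1", "s2", "u1", "u2")
  K <- correlation_matrix(ped, ids, model = "additive")
  expect_equal(diag(K), setNames(rep(1, 4), ids))
  expect_equal(K["s1", "s2"], 1/2)
  expect_equal(K["s1", "u1"], 0)
  expect_equal(K["u1", "u2"], 0)
  expect_true(isSymmetric(K))

  Kr <- correlation_matrix(ped, ids, model = "recessive", p = 0.2)
  expect_equal(Kr["s1", "s2"], 1/3)
  expect_error(correlation_matrix(ped, ids, model = "recessive"),
               "frequency")

  Kx <- correlation_matrix(ped, ids, model = "additive", chromosome = "X")
  expect_equal(Kx["s1", "s2"], 1/(2 * sqrt(2)))  # sister-brother
  expect_error(correlation_matrix(ped, ids, model = "recessive",
                                  chromosome = "X", p = 0.2), "additive")

  for (M in list(K, Kr, Kx)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }

  # unrelated individuals: identity
  expect_equal(unname(correlation_matrix(ped, c("f", "u1", "u2"))),
               diag(3))
})
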