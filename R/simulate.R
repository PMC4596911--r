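# Simulator for ascertained nuclear-family case-control datasets.
#
# Case families: two parents under random mating and Hardy-Weinberg
# equilibrium, three offspring by Mendelian transmission, disease status
# from a logistic model logit(mu) = beta0 + beta_g * x + u with baseline
# risk K_b (beta0 = logit(K_b)), genotypic score x, and a shared family
# effect u ~ N(0, sigma_u2) carrying the residual familial correlation.
# Families are rejection-sampled to the exact affection pattern of the
# ascertainment scheme (ASP1/ASP2/ASP3 = exactly 1/2/3 affected among 3
# sibs); one affected sib (uniformly chosen) is genotyped as the case,
# the other sibs stay as un-genotyped relatives with their phenotypes.
# Controls are unrelated singletons with no phenotype screening.
#
# X-linked variant: mothers carry two X alleles under HWE, fathers one
# Bernoulli X allele plus a Y; paternal transmission of X vs Y sets the
# offspring sex, and a male's genotypic score is his allele coded 0/2.

#' Simulation configuration
#'
#' @param maf risk (minor) allele frequency.
#' @param odds_ratio per-score odds ratio exp(beta_g); 1 under the null.
#' @param baseline_risk baseline disease risk K_b (intercept
#'   beta0 = logit(K_b)); default 0.10.
#' @param sigma_u2 variance of the shared family effect on the logit scale;
#'   with the intrinsic logistic-scale residual taken as 3, sigma_u2 = 1
#'   corresponds to broad-sense heritability of about 25% and 0.5 to about
#'   14%.
#' @param scheme ascertainment scheme: `"ASP1"`, `"ASP2"`, `"ASP3"` (exactly
#'   1/2/3 affected of 3 sibs) or `"Mixed"` (equal thirds of the three).
#' @param disease_model genotypic score in the disease model: `"additive"`
#'   (0/1/2, X males 0/2) or `"recessive"` (risk-homozygote indicator;
#'   autosomes only).
#' @param chromosome `"autosome"` or `"X"`.
#' @param n_case_families number of ascertained case families (default 500;
#'   600 for Mixed).
#' @param n_controls number of unrelated controls (defaults to
#'   `n_case_families`).
#' @param replicates number of replicates for [empirical_rate()].
#' @param alpha nominal significance level.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(maf, odds_ratio = 1, baseline_risk = 0.10,
                       sigma_u2 = 1,
                       scheme = c("ASP1", "ASP2", "ASP3", "Mixed"),
                       disease_model = c("additive", "recessive"),
                       chromosome = c("autosome", "X"),
                       n_case_families = NULL, n_controls = NULL,
                       replicates = 1000, alpha = 0.05) {
  scheme <- match.arg(scheme)
  disease_model <- match.arg(disease_model)
  chromosome <- match.arg(chromosome)
  stopifnot(maf > 0, maf < 1, odds_ratio > 0,
            baseline_risk > 0, baseline_risk < 1,
            sigma_u2 >= 0, replicates >= 1, alpha > 0, alpha <= 1)
  if (chromosome == "X" && disease_model == "recessive")
    stop("X-linked simulation supports the additive model only")
  if (is.null(n_case_families))
    n_case_families <- if (scheme == "Mixed") 600L else 500L
  if (is.null(n_controls)) n_controls <- n_case_families
  structure(list(maf = maf, odds_ratio = odds_ratio,
                 baseline_risk = baseline_risk, sigma_u2 = sigma_u2,
                 scheme = scheme, disease_model = disease_model,
                 chromosome = chromosome,
                 n_case_families = as.integer(n_case_families),
                 n_controls = as.integer(n_controls),
                 replicates = as.integer(replicates), alpha = alpha),
            class = "sim_config")
}

#' Simulate candidate nuclear families
#'
#' Draws `n` three-sib nuclear families (before ascertainment) under the
#' configured disease model. Genotypes are stored as risk-allele counts:
#' 0/1/2, except X-linked males who carry 0/1 (a single allele).
#'
#' @param cfg a [sim_config()].
#' @param n number of families.
#' @return A list with n x 3 matrices `geno` (allele counts), `sex`, `aff`
#'   (0/1 affection), and the family effects `u`.
#' @export
simulate_family <- function(cfg, n = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  maf <- cfg$maf
  b0 <- stats::qlogis(cfg$baseline_risk)
  bg <- log(cfg$odds_ratio)
  u <- if (cfg$sigma_u2 > 0) stats::rnorm(n, 0, sqrt(cfg$sigma_u2))
       else numeric(n)
  geno <- matrix(0L, n, 3)
  sexm <- matrix("", n, 3)
  if (cfg$chromosome == "autosome") {
    fa1 <- stats::rbinom(n, 1L, maf); fa2 <- stats::rbinom(n, 1L, maf)
    ma1 <- stats::rbinom(n, 1L, maf); ma2 <- stats::rbinom(n, 1L, maf)
    for (k in 1:3) {
      pat <- ifelse(stats::runif(n) < 0.5, fa1, fa2)
      mat <- ifelse(stats::runif(n) < 0.5, ma1, ma2)
      geno[, k] <- pat + mat
      sexm[, k] <- ifelse(stats::runif(n) < 0.5, "male", "female")
    }
    score <- if (cfg$disease_model == "additive") geno
             else (geno == 2L) + 0L
  } else {
    ma1 <- stats::rbinom(n, 1L, maf); ma2 <- stats::rbinom(n, 1L, maf)
    fa <- stats::rbinom(n, 1L, maf)
    for (k in 1:3) {
      mat <- ifelse(stats::runif(n) < 0.5, ma1, ma2)
      isf <- stats::runif(n) < 0.5          # father transmits X -> daughter
      geno[, k] <- ifelse(isf, fa + mat, mat)
      sexm[, k] <- ifelse(isf, "female", "male")
    }
    # X-inactivation coding: males equivalent to homozygous females
    score <- ifelse(sexm == "male", 2L * geno, geno)
  }
  mu <- stats::plogis(b0 + bg * score + u)
  aff <- matrix(stats::rbinom(3L * n, 1L, mu), n, 3)
  list(geno = geno, sex = sexm, aff = aff, u = u)
}

#' Ascertainment of a candidate family
#'
#' A family is accepted if its affection pattern among the three sibs
#' matches the scheme exactly: ASP1 = exactly one affected, ASP2 = exactly
#' two, ASP3 = all three.
#'
#' @param aff length-3 0/1 affection vector, or an n x 3 matrix.
#' @param scheme `"ASP1"`, `"ASP2"` or `"ASP3"`.
#' @return Logical acceptance flag(s).
#' @export
ascertain <- function(aff, scheme = c("ASP1", "ASP2", "ASP3")) {
  scheme <- match.arg(scheme)
  need <- c(ASP1 = 1L, ASP2 = 2L, ASP3 = 3L)[[scheme]]
  if (is.matrix(aff)) rowSums(aff) == need else sum(aff) == need
}

#' Simulate an ascertained case-control dataset
#'
#' Rejection-samples case families until the quota is met (Mixed: equal
#' thirds from ASP1/ASP2/ASP3), selects one genotyped case per family
#' uniformly among its affected sibs, keeps the other sibs as un-genotyped
#' relatives with their phenotypes, and draws unrelated singleton controls.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `"sim_dataset"`: per-family `case_geno` (allele
#'   count; X males 0/1), `case_sex`, `sib_aff` / `sib_sex` (n x 2 matrices
#'   for the two un-genotyped sibs), `scheme` labels, and `control_geno`,
#'   `control_sex`; plus the `cfg` used.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  schemes <- if (cfg$scheme == "Mixed") c("ASP1", "ASP2", "ASP3")
             else cfg$scheme
  quota <- if (cfg$scheme == "Mixed") {
    q <- rep(cfg$n_case_families %/% 3L, 3L)
    q[seq_len(cfg$n_case_families %% 3L)] <- q[seq_len(cfg$n_case_families %% 3L)] + 1L
    stats::setNames(q, schemes)
  } else stats::setNames(cfg$n_case_families, schemes)

  got <- lapply(schemes, function(s) list())
  names(got) <- schemes
  have <- stats::setNames(integer(length(schemes)), schemes)
  trials <- 0
  accepted_total <- 0
  repeat {
    miss <- quota - have
    if (all(miss <= 0L)) break
    rate_guess <- if (trials > 0) max(accepted_total / trials, 1e-3) else 0.1
    batch <- min(5e5, max(2000L, ceiling(1.5 * sum(miss) / rate_guess)))
    fam <- simulate_family(cfg, batch)
    trials <- trials + batch
    naff <- rowSums(fam$aff)
    for (s in schemes) {
      if (have[[s]] >= quota[[s]]) next
      idx <- which(naff == c(ASP1 = 1L, ASP2 = 2L, ASP3 = 3L)[[s]])
      accepted_total <- accepted_total + length(idx)
      take <- idx[seq_len(min(length(idx), quota[[s]] - have[[s]]))]
      if (length(take)) {
        got[[s]][[length(got[[s]]) + 1L]] <-
          lapply(fam[c("geno", "sex", "aff")],
                 function(m) m[take, , drop = FALSE])
        have[[s]] <- have[[s]] + length(take)
      }
    }
    if (trials >= 2e6 && accepted_total / trials < 1e-6)
      stop("ascertainment acceptance probability below 1e-6; ",
           "configuration is pathological")
  }

  geno <- do.call(rbind, unlist(lapply(schemes, function(s)
    lapply(got[[s]], `[[`, "geno")), recursive = FALSE))
  sexm <- do.call(rbind, unlist(lapply(schemes, function(s)
    lapply(got[[s]], `[[`, "sex")), recursive = FALSE))
  aff <- do.call(rbind, unlist(lapply(schemes, function(s)
    lapply(got[[s]], `[[`, "aff")), recursive = FALSE))
  scheme_lab <- rep(schemes, times = vapply(schemes, function(s)
    sum(vapply(got[[s]], function(g) nrow(g$geno), integer(1))),
    integer(1)))

  nfam <- nrow(geno)
  # uniformly pick the genotyped case among affected sibs
  r <- stats::runif(nfam)
  naff <- rowSums(aff)
  cum1 <- aff[, 1]
  cum2 <- aff[, 1] + aff[, 2]
  pick <- ifelse(r < cum1 / naff, 1L, ifelse(r < cum2 / naff, 2L, 3L))
  sel <- cbind(seq_len(nfam), pick)
  case_geno <- geno[sel]
  case_sex <- sexm[sel]
  others <- t(vapply(seq_len(nfam),
                     function(i) setdiff(1:3, pick[i]), integer(2)))
  sib_aff <- cbind(aff[cbind(seq_len(nfam), others[, 1])],
                   aff[cbind(seq_len(nfam), others[, 2])])
  sib_sex <- cbind(sexm[cbind(seq_len(nfam), others[, 1])],
                   sexm[cbind(seq_len(nfam), others[, 2])])

  nc <- cfg$n_controls
  if (cfg$chromosome == "autosome") {
    control_geno <- stats::rbinom(nc, 2L, cfg$maf)
    control_sex <- ifelse(stats::runif(nc) < 0.5, "male", "female")
  } else {
    control_sex <- ifelse(stats::runif(nc) < 0.5, "male", "female")
    control_geno <- ifelse(control_sex == "female",
                           stats::rbinom(nc, 2L, cfg$maf),
                           stats::rbinom(nc, 1L, cfg$maf))
  }

  structure(list(case_geno = case_geno, case_sex = case_sex,
                 sib_aff = sib_aff, sib_sex = sib_sex,
                 scheme = scheme_lab,
                 control_geno = control_geno, control_sex = control_sex,
                 cfg = cfg, acceptance_rate = accepted_total / trials),
            class = "sim_dataset")
}

#' Convert a simulated dataset to pedigree + genotype objects
#'
#' Expands the compact simulator output into a [pedigree()] (case families
#' as 2 parents + 3 sibs with only the selected case genotyped; controls as
#' singleton families) and a single-marker `geno_matrix`, so simulator
#' output round-trips through the file writers and the association
#' interface.
#'
#' @param ds a [simulate_dataset()] result.
#' @return `list(ped = , geno = )`.
#' @export
sim_to_data <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  nfam <- length(ds$case_geno)
  nc <- length(ds$control_geno)
  fam_id <- sprintf("FAM%04d", seq_len(nfam))
  rows <- list()
  for (i in seq_len(nfam)) {
    f <- fam_id[i]
    rows[[i]] <- data.frame(
      fid = f,
      iid = paste0(f, c("_p1", "_p2", "_c", "_s1", "_s2")),
      father = c(NA, NA, rep(paste0(f, "_p1"), 3)),
      mother = c(NA, NA, rep(paste0(f, "_p2"), 3)),
      sex = c("male", "female", ds$case_sex[i], ds$sib_sex[i, ]),
      affection = c(NA, NA, 1, ds$sib_aff[i, ]),
      stringsAsFactors = FALSE)
  }
  ctl <- data.frame(fid = sprintf("CTRL%04d", seq_len(nc)),
                    iid = sprintf("CTRL%04d_1", seq_len(nc)),
                    father = NA, mother = NA,
                    sex = ds$control_sex, affection = 0,
                    stringsAsFactors = FALSE)
  tab <- rbind(do.call(rbind, rows), ctl)
  ped <- pedigree(fid = tab$fid, iid = tab$iid, father = tab$father,
                  mother = tab$mother, sex = tab$sex,
                  affection = tab$affection)

  samples <- c(paste0(fam_id, "_c"), ctl$iid)
  sex <- c(ds$case_sex, ds$control_sex)
  raw <- c(ds$case_geno, ds$control_geno)
  dosage <- if (ds$cfg$chromosome == "X") ifelse(sex == "male", 2 * raw, raw)
            else raw
  geno <- as_geno_matrix(matrix(dosage, nrow = 1,
                                dimnames = list("M1", samples)),
                         markers = data.frame(
                           marker = "M1",
                           chrom = if (ds$cfg$chromosome == "X") "X" else "1",
                           pos = 1L, a1 = "A", a2 = "B",
                           stringsAsFactors = FALSE))
  list(ped = ped, geno = geno)
}

# Template sib-sib correlations for the fast scoring kernel, computed from
# the real pair-coefficient machinery on a two-parent/two-child pedigree.
.template_sib_rho <- function() {
  tp <- pedigree(fid = "T", iid = c("f", "m", "a", "b", "c", "d"),
                 father = c(NA, NA, "f", "f", "f", "f"),
                 mother = c(NA, NA, "m", "m", "m", "m"),
                 sex = c("male", "female", "female", "female",
                         "male", "male"))
  pc <- pair_coefficients(tp, "a", "b")
  list(pi1 = pc$pi1, pi2 = pc$pi2,
       additive = additive_rho(pc),
       x_ff = x_rho(tp, "a", "b"),
       x_fm = x_rho(tp, "a", "c"),
       x_mm = x_rho(tp, "c", "d"))
}

#' Empirical type-I error or power of the score test
#'
#' Runs the full pipeline (simulate an ascertained dataset, estimate
#' frequencies, build the correlation structure, test) for each replicate
#' and reports the proportion of replicates with p below `alpha`. With one
#' genotyped case per family the genotyped individuals are mutually
#' unrelated, so the test reduces to the trend test with (for `ST_fam`)
#' family-history weights built from the template sib correlations.
#' Degenerate replicates (monomorphic or uninformative marker, relevant for
#' rare recessive variants) count as non-rejections.
#'
#' @param cfg a [sim_config()].
#' @param test `"ST"` (score test) or `"ST_fam"` (score test with
#'   family-history weights for the un-genotyped sibs).
#' @param seed optional integer seed for bit-reproducible runs.
#' @return A list: `rate`, `se` (binomial), `n_rejected`, `n_degenerate`,
#'   `replicates`, `alpha`, `test`.
#' @export
empirical_rate <- function(cfg, test = c("ST", "ST_fam"), seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  tmpl <- .template_sib_rho()
  reject <- 0L
  degen <- 0L
  for (r in seq_len(cfg$replicates)) {
    ds <- simulate_dataset(cfg)
    p <- .kernel_test_p(ds, test, tmpl)
    if (is.na(p)) degen <- degen + 1L
    else if (p < cfg$alpha) reject <- reject + 1L
  }
  rate <- reject / cfg$replicates
  list(rate = rate, se = sqrt(rate * (1 - rate) / cfg$replicates),
       n_rejected = reject, n_degenerate = degen,
       replicates = cfg$replicates, alpha = cfg$alpha, test = test)
}

# Fast scoring kernel for simulator output: one genotyped case per family,
# unrelated controls => K restricted to genotyped individuals is the
# identity; Y* adds template sib correlations times sib affection.
.kernel_test_p <- function(ds, test, tmpl) {
  cfg <- ds$cfg
  model <- cfg$disease_model
  sex <- c(ds$case_sex, ds$control_sex)
  raw <- c(ds$case_geno, ds$control_geno)
  g <- if (cfg$chromosome == "X") ifelse(sex == "male", 2L * raw, raw)
       else raw
  nfam <- length(ds$case_geno)
  y <- c(rep(1, nfam), rep(0, length(ds$control_geno)))

  freqs <- estimate_frequencies(g, sex = sex, chromosome = cfg$chromosome)
  if (freqs$monomorphic) return(NA_real_)
  sig2 <- genotype_variance(freqs, model)
  sigma2 <- if (cfg$chromosome == "X")
    ifelse(sex == "male", sig2[["male"]], sig2[["female"]])
  else rep(sig2, length(g))

  x <- if (model == "additive") g else as.numeric(g == 2)

  if (test == "ST_fam") {
    rho <- if (cfg$chromosome == "X") {
      lk <- function(cs, ss) ifelse(cs == "female" & ss == "female",
                                    tmpl$x_ff,
                             ifelse(cs == "male" & ss == "male",
                                    tmpl$x_mm, tmpl$x_fm))
      cbind(lk(ds$case_sex, ds$sib_sex[, 1]),
            lk(ds$case_sex, ds$sib_sex[, 2]))
    } else if (model == "additive") {
      matrix(tmpl$additive, nfam, 2)
    } else {
      p <- freqs$p_hat
      matrix(tmpl$pi2 + tmpl$pi1 * p / (1 + p), nfam, 2)
    }
    y[seq_len(nfam)] <- 1 + rowSums(rho * ds$sib_aff)
  }

  yc <- y - mean(y)
  U <- sum(yc * x)
  V <- sum(yc^2 * sigma2)
  chi_square_p(U, V)
}
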