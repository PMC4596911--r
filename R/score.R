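# The genotype-based score test: U = (Y - Ybar)' X with a variance built
# from estimated genotype frequencies and, for related samples, the
# pedigree-derived genotype correlation matrix K:
#
#   Var U = (Y - Ybar)' [K o Sigma] (Y - Ybar),   Sigma_ij = sigma_i sigma_j.
#
# U^2 / Var U is compared with a chi-squared(1) reference. With unrelated
# samples and additive hard calls this is the Cochran-Armitage trend test.

#' Estimate genotype frequencies
#'
#' Naive pooled counting over the supplied genotypes. For X-linked markers,
#' female genotype frequencies are estimated from females (codes 0/1/2) and
#' the male allele frequency from males (codes 0/2 = hemizygous reference /
#' alternative); the pooled allele frequency weights females by two alleles
#' and males by one.
#'
#' @param g numeric vector of additive genotype codes: 0/1/2 (females,
#'   autosomes) or 0/2 (X males); `NA` = missing. Fractional dosages are
#'   accepted only together with `posteriors`.
#' @param sex per-individual sex, required when `chromosome = "X"`.
#' @param chromosome `"autosome"` or `"X"`.
#' @param posteriors optional n x 3 matrix of genotype posterior
#'   probabilities used for (soft) genotype counting instead of hard calls.
#' @return A list of class `"genotype_frequencies"`: `p` (genotype relative
#'   frequencies), `p_hat` (risk/alternative-allele frequency), `counts`,
#'   `monomorphic`, and for X additionally `p_female`, `q_male`, `n_female`,
#'   `n_male`.
#' @export
estimate_frequencies <- function(g, sex = NULL,
                                 chromosome = c("autosome", "X"),
                                 posteriors = NULL) {
  chromosome <- match.arg(chromosome)
  keep <- !is.na(g)
  if (!any(keep)) stop("all genotypes are missing")
  soft_counts <- function(gg, post, levels) {
    if (!is.null(post)) {
      colSums(post, na.rm = TRUE)
    } else {
      if (any(!(gg %in% levels)))
        stop("hard genotype calls must lie in {",
             paste(levels, collapse = ", "), "}")
      vapply(levels, function(v) sum(gg == v), numeric(1))
    }
  }
  # fractional dosages without posteriors: frequency from the mean dosage,
  # genotypic variance from the empirical dosage variance
  if (is.null(posteriors) && any(!(g[keep] %in% c(0, 1, 2)))) {
    if (chromosome == "autosome") {
      p_hat <- mean(g[keep]) / 2
      v <- stats::var(g[keep]) * (sum(keep) - 1) / sum(keep)
      out <- list(p = c(NA, NA, NA), p_hat = p_hat, counts = NULL,
                  dosage_variance = v, monomorphic = v <= 0,
                  chromosome = chromosome)
    } else {
      if (is.null(sex) || anyNA(sex[keep]))
        stop("sex is required for X-linked frequency estimation")
      fem <- keep & sex == "female"; mal <- keep & sex == "male"
      nv <- function(z) if (length(z) > 1) stats::var(z) * (length(z) - 1) /
        length(z) else 0
      p_hat <- (sum(g[fem]) + sum(g[mal]) / 2) / (2 * sum(fem) + sum(mal))
      out <- list(p = c(NA, NA, NA), p_hat = p_hat, counts = NULL,
                  p_female = c(NA, NA, NA),
                  q_male = if (any(mal)) mean(g[mal]) / 2 else NA_real_,
                  n_female = sum(fem), n_male = sum(mal),
                  dosage_variance = c(female = nv(g[fem]), male = nv(g[mal])),
                  monomorphic = p_hat <= 0 || p_hat >= 1,
                  chromosome = chromosome)
    }
    class(out) <- "genotype_frequencies"
    return(out)
  }
  if (chromosome == "autosome") {
    cnt <- soft_counts(g[keep],
                       if (!is.null(posteriors)) posteriors[keep, , drop = FALSE],
                       c(0, 1, 2))
    names(cnt) <- c("n0", "n1", "n2")
    p <- cnt / sum(cnt)
    p_hat <- p[2] / 2 + p[3]
    out <- list(p = unname(p), p_hat = unname(p_hat), counts = cnt,
                monomorphic = p_hat <= 0 || p_hat >= 1,
                chromosome = chromosome)
  } else {
    if (is.null(sex) || anyNA(sex[keep]))
      stop("sex is required for X-linked frequency estimation")
    fem <- keep & sex == "female"
    mal <- keep & sex == "male"
    pf <- c(NA, NA, NA); q <- NA_real_
    cf <- c(n0 = 0, n1 = 0, n2 = 0); cm <- c(n0 = 0, n2 = 0)
    if (any(fem)) {
      cf[] <- soft_counts(g[fem],
                          if (!is.null(posteriors)) posteriors[fem, , drop = FALSE],
                          c(0, 1, 2))
      pf <- cf / sum(cf)
    }
    if (any(mal)) {
      pm <- if (!is.null(posteriors)) {
        cm[] <- colSums(posteriors[mal, c(1, 3), drop = FALSE], na.rm = TRUE)
        cm / sum(cm)
      } else {
        if (any(g[mal] == 1))
          stop("heterozygous male genotype on X; set to missing upstream")
        cm[] <- c(sum(g[mal] == 0), sum(g[mal] == 2))
        cm / sum(cm)
      }
      q <- unname(pm[2])
    }
    alt_alleles <- unname(cf["n1"] + 2 * cf["n2"] + cm["n2"])
    tot_alleles <- 2 * sum(cf) + sum(cm)
    p_hat <- alt_alleles / tot_alleles
    out <- list(p = unname(pf), p_hat = p_hat,
                counts = c(cf, cm), p_female = unname(pf), q_male = q,
                n_female = sum(cf), n_male = sum(cm),
                monomorphic = p_hat <= 0 || p_hat >= 1,
                chromosome = chromosome)
  }
  class(out) <- "genotype_frequencies"
  out
}

#' Genotypic variance from estimated frequencies
#'
#' Additive coding: \eqn{\sigma^2_X = \tilde p_1(1-\tilde p_1) +
#' 4\tilde p_2(1-\tilde p_2) - 4\tilde p_1 \tilde p_2}, which is the
#' empirical variance of the 0/1/2 dosage and does not assume
#' Hardy-Weinberg proportions. Recessive coding: \eqn{\tilde p_2(1-\tilde
#' p_2)}; dominant coding: \eqn{\tilde p_0(1-\tilde p_0)}.
#'
#' For X-linked markers a vector of two variances is returned: the female
#' genotypic variance (by the additive formula on female genotype
#' frequencies) and the male variance \eqn{4q(1-q)} from the male allele
#' frequency.
#'
#' @param freqs a [estimate_frequencies()] result.
#' @param model `"additive"`, `"recessive"` or `"dominant"`.
#' @return A single variance (autosome) or `c(female = , male = )` for X.
#' @export
genotype_variance <- function(freqs,
                              model = c("additive", "recessive", "dominant")) {
  model <- match.arg(model)
  add_var <- function(p) p[2] * (1 - p[2]) + 4 * p[3] * (1 - p[3]) -
    4 * p[2] * p[3]
  if (!is.null(freqs$dosage_variance)) {
    if (model != "additive")
      stop("dosage-only input supports the additive model only")
    if (freqs$chromosome == "X")
      return(c(female = unname(freqs$dosage_variance["female"]),
               male = unname(freqs$dosage_variance["male"])))
    return(freqs$dosage_variance)
  }
  if (freqs$chromosome == "X") {
    if (model != "additive")
      stop("X-linked testing supports the additive model only")
    sf <- if (anyNA(freqs$p_female)) 0 else add_var(freqs$p_female)
    sm <- if (is.na(freqs$q_male)) 0 else 4 * freqs$q_male * (1 - freqs$q_male)
    return(c(female = sf, male = sm))
  }
  p <- freqs$p
  switch(model,
         additive = add_var(p),
         recessive = p[3] * (1 - p[3]),
         dominant = p[1] * (1 - p[1]))
}

#' Score statistic
#'
#' \eqn{U = (Y - \bar Y)^\top X}; for binary traits \eqn{\bar Y} is the case
#' proportion among the individuals entering the test, for quantitative
#' traits the sample mean.
#'
#' @param y phenotype / weight vector (same length as `x`).
#' @param x genotype dosage vector, already coded for the genetic model;
#'   no missing values (exclude missing-genotype individuals first).
#' @return The score U.
#' @export
score_statistic <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  sum((y - mean(y)) * x)
}

#' Kinship-adjusted variance of the score
#'
#' \eqn{\mathrm{Var}\,U = (Y-\bar Y)^\top [K \circ \Sigma](Y - \bar Y)} with
#' \eqn{\Sigma_{ij} = \sigma_i \sigma_j}. With `K = diag(n)` this reduces to
#' the unrelated-sample variance \eqn{\sigma^2 \sum_i (y_i - \bar y)^2}.
#'
#' @param y phenotype / weight vector.
#' @param K genotype correlation matrix (see [correlation_matrix()]).
#' @param sigma per-individual genotypic standard deviations (recycled if
#'   scalar).
#' @return The variance of U.
#' @export
score_variance <- function(y, K, sigma) {
  n <- length(y)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("K must be an n x n matrix matching y")
  sigma <- rep_len(sigma, n)
  yc <- (y - mean(y)) * sigma
  drop(crossprod(yc, K %*% yc))
}

#' Chi-squared p-value for the score test
#'
#' Upper-tail probability of \eqn{U^2/V} against a chi-squared distribution
#' with one degree of freedom.
#'
#' @param U score statistic.
#' @param V its variance; `V <= 0` yields `NA` (degenerate marker).
#' @return The p-value, or `NA_real_` when degenerate.
#' @export
chi_square_p <- function(U, V) {
  if (!is.finite(V) || V <= 0) return(NA_real_)
  stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

# Code additive 0..2 genotypes (X males 0/2) under a genetic model.
.code_genotypes <- function(g, model, chromosome, sex = NULL) {
  if (model == "additive") return(g)
  if (chromosome == "X")
    stop("X-linked testing supports the additive model only")
  switch(model,
         recessive = as.numeric(g == 2),
         dominant = as.numeric(g >= 1))
}

# Posterior-based coded dosage and per-individual loss for a model.
.code_posteriors <- function(post, model, chromosome, sex = NULL) {
  if (chromosome == "X" && !is.null(sex)) {
    # males: two-state posterior over {0, 2}; renormalize mass off the
    # heterozygote class (upstream readers zero it with a warning)
    mal <- sex == "male"
    if (any(mal, na.rm = TRUE)) {
      pm <- post[mal, , drop = FALSE]
      s <- pm[, 1] + pm[, 3]
      pm[, 1] <- pm[, 1] / s; pm[, 3] <- pm[, 3] / s; pm[, 2] <- 0
      post[mal, ] <- pm
    }
  }
  switch(model,
         additive = {
           dos <- post[, 2] + 2 * post[, 3]
           loss <- post[, 2] * (1 - post[, 2]) +
             4 * post[, 3] * (1 - post[, 3]) - 4 * post[, 2] * post[, 3]
         },
         recessive = {
           dos <- post[, 3]
           loss <- post[, 3] * (1 - post[, 3])
         },
         dominant = {
           dos <- post[, 2] + post[, 3]
           loss <- dos * (1 - dos)
         })
  list(dosage = dos, loss = pmax(loss, 0))
}

#' Run the score test for one marker
#'
#' Excludes missing-genotype individuals, estimates genotype frequencies,
#' codes genotypes for the genetic model (X-linked males 0/2), builds the
#' model-specific correlation matrix for the genotyped subset, and returns
#' the full test result. With posterior genotype probabilities the dosage
#' score and the information-loss-corrected variance are used and the
#' efficiency measure \eqn{R^2_T} is reported; with hard calls
#' \eqn{R^2_T = 1}.
#'
#' @param ped a [pedigree()] object covering all genotyped individuals.
#' @param genotypes a `geno_matrix` (see [read_genotypes()] /
#'   [as_geno_matrix()]).
#' @param marker marker id (row of the genotype object).
#' @param model `"additive"`, `"recessive"` or `"dominant"`.
#' @param chromosome `"autosome"`, `"X"`, or `NULL` to take it from the
#'   marker metadata.
#' @param phenotype optional named numeric vector overriding the pedigree
#'   affection column (names = individual ids).
#' @param freq_source `"pooled"` (all genotyped individuals; default) or
#'   `"controls"` (genotyped individuals with phenotype 0).
#' @param weights optional per-individual weight vector (named by id)
#'   replacing Y, e.g. family-history weights from [history_weights()].
#' @return A list of class `"score_test_result"`: `U`, `V`, `chi2`, `p`,
#'   `r2T`, `n_cases`, `n_controls`, `eaf_cases`, `eaf_controls`, `p_hat`,
#'   `model`, `chromosome`, `status` (`"ok"`/`"degenerate"`), `marker`.
#' @export
run_score_test <- function(ped, genotypes, marker,
                           model = c("additive", "recessive", "dominant"),
                           chromosome = NULL, phenotype = NULL,
                           freq_source = c("pooled", "controls"),
                           weights = NULL) {
  model <- match.arg(model)
  freq_source <- match.arg(freq_source)
  gm <- genotypes
  mrow <- match(marker, gm$markers$marker)
  if (is.na(mrow)) stop("marker '", marker, "' not found")
  if (is.null(chromosome)) {
    chromosome <- if (isTRUE(gm$markers$is_x[mrow])) "X" else "autosome"
  }
  chromosome <- match.arg(chromosome, c("autosome", "X"))

  ids <- gm$samples
  pidx <- .ped_index(ped, ids)
  y_all <- if (is.null(phenotype)) ped$affection[pidx]
           else as.numeric(phenotype[ids])

  g <- gm$dosage[mrow, ]
  post <- if (!is.null(gm$post)) gm$post[[mrow]] else NULL
  keep <- !is.na(g) & !is.na(y_all)
  if (!any(keep)) stop("no individuals with both genotype and phenotype")
  ids <- ids[keep]
  y <- y_all[keep]
  g <- g[keep]
  sex <- ped$sex[pidx][keep]
  if (!is.null(post)) post <- post[keep, , drop = FALSE]

  res <- list(marker = marker, model = model, chromosome = chromosome,
              n_cases = sum(y == 1), n_controls = sum(y == 0))

  fsub <- if (freq_source == "controls") y == 0 else rep(TRUE, length(g))
  if (!any(fsub) || all(is.na(g[fsub])))
    stop("no genotyped individuals available for frequency estimation")
  freqs <- estimate_frequencies(g[fsub], sex = sex[fsub],
                                chromosome = chromosome,
                                posteriors = if (!is.null(post))
                                  post[fsub, , drop = FALSE])
  res$p_hat <- freqs$p_hat
  eaf <- function(sel) {
    if (!any(sel)) return(NA_real_)
    f <- estimate_frequencies(g[sel], sex = sex[sel], chromosome = chromosome,
                              posteriors = if (!is.null(post))
                                post[sel, , drop = FALSE])
    f$p_hat
  }
  res$eaf_cases <- eaf(y == 1)
  res$eaf_controls <- eaf(y == 0)

  if (freqs$monomorphic) {
    res <- c(res, list(U = NA_real_, V = NA_real_, chi2 = NA_real_,
                       p = NA_real_, r2T = NA_real_, status = "degenerate"))
    class(res) <- "score_test_result"
    return(res)
  }

  if (!is.null(weights)) {
    if (is.null(names(weights))) stop("weights must be named by individual id")
    y <- as.numeric(weights[ids])
    if (anyNA(y)) stop("weights missing for some genotyped individuals")
  }

  if (!is.null(post)) {
    coded <- .code_posteriors(post, model, chromosome, sex)
    x <- coded$dosage
    loss <- coded$loss
  } else {
    x <- .code_genotypes(g, model, chromosome, sex)
    loss <- NULL
  }

  sig2 <- genotype_variance(freqs, model)
  sigma <- if (chromosome == "X") {
    sqrt(ifelse(sex == "male", sig2["male"], sig2["female"]))
  } else rep(sqrt(sig2), length(x))

  K <- correlation_matrix(ped, ids, model = model, chromosome = chromosome,
                          p = if (model != "additive") freqs$p_hat)

  U <- score_statistic(y, x)
  V <- score_variance(y, K, sigma)
  if (!is.null(loss) && any(loss > 0)) {
    Vobs <- observed_variance(y, K, sigma, loss)
    r2T <- if (V > 0) Vobs / V else NA_real_
    V_use <- Vobs
  } else {
    r2T <- 1
    V_use <- V
  }

  if (!is.finite(V_use) || V_use <= 0) {
    res <- c(res, list(U = U, V = V_use, chi2 = NA_real_, p = NA_real_,
                       r2T = r2T, status = "degenerate"))
  } else {
    res <- c(res, list(U = U, V = V_use, chi2 = U^2 / V_use,
                       p = chi_square_p(U, V_use), r2T = r2T, status = "ok"))
  }
  class(res) <- "score_test_result"
  res
}

#' @export
print.score_test_result <- function(x, ...) {
  cat(sprintf("Score test [%s, %s] marker %s\n", x$model, x$chromosome,
              x$marker))
  cat(sprintf("  cases/controls: %d/%d  EAF: %.4g/%.4g\n",
              x$n_cases, x$n_controls, x$eaf_cases, x$eaf_controls))
  if (identical(x$status, "ok")) {
    cat(sprintf("  U = %.5g  Var = %.5g  chi2 = %.5g  p = %.4g  R2_T = %.3g\n",
                x$U, x$V, x$chi2, x$p, x$r2T))
  } else {
    cat("  status: degenerate (monomorphic or uninformative marker)\n")
  }
  invisible(x)
}
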