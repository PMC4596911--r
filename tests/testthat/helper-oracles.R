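# Independent oracles: gene-dropping Monte Carlo for autosomal genotype
# correlations, and exact enumeration of X transmissions.

# Drop founder alleles through a pedigree, vectorized over replicates.
# Returns a reps x n matrix of additive allele counts (0/1/2).
gene_drop <- function(ped, p, reps) {
  n <- nrow(ped)
  ord <- order(ped$depth)
  a1 <- matrix(NA_integer_, reps, n)
  a2 <- matrix(NA_integer_, reps, n)
  for (i in ord) {
    if (ped$fidx[i] == 0L) {
      a1[, i] <- rbinom(reps, 1L, p)
      a2[, i] <- rbinom(reps, 1L, p)
    } else {
      f <- ped$fidx[i]; m <- ped$midx[i]
      pickf <- runif(reps) < 0.5
      pickm <- runif(reps) < 0.5
      a1[, i] <- ifelse(pickf, a1[, f], a2[, f])
      a2[, i] <- ifelse(pickm, a1[, m], a2[, m])
    }
  }
  a1 + a2
}

# Exact X-linked genotype correlation by enumerating every maternal
# transmission choice. Alleles are tracked symbolically as founder-allele
# ids; males carry one X (coded with weight 2), females two (weight 1 each).
# With founder alleles iid Bernoulli, the correlation reduces to the
# expected number of shared allele ids scaled by the sex coding weights.
x_corr_enum <- function(ped, i, j) {
  ii <- match(i, ped$iid); jj <- match(j, ped$iid)
  n <- nrow(ped)
  ord <- order(ped$depth)
  nonf <- ord[ped$fidx[ord] > 0L]
  m <- length(nonf)                      # one maternal choice each
  covsum <- 0
  for (v in seq_len(2^m) - 1L) {
    bits <- as.integer(intToBits(v))[seq_len(max(m, 1))]
    alleles <- vector("list", n)
    aid <- 0L
    for (k in ord) {
      if (ped$fidx[k] == 0L) {
        alleles[[k]] <- if (ped$sex[k] == "male") {
          aid <- aid + 1L; aid
        } else {
          aid <- aid + 2L; c(aid - 1L, aid)
        }
      } else {
        mom <- alleles[[ped$midx[k]]]
        mat <- mom[1L + bits[match(k, nonf)] %% length(mom)]
        alleles[[k]] <- if (ped$sex[k] == "male") mat
                        else c(alleles[[ped$fidx[k]]][1], mat)
      }
    }
    wi <- if (ped$sex[ii] == "male") 2 else 1
    wj <- if (ped$sex[jj] == "male") 2 else 1
    shared <- sum(outer(alleles[[ii]], alleles[[jj]], "=="))
    covsum <- covsum + shared * wi * wj
  }
  vi <- if (ped$sex[ii] == "male") 4 else 2
  vj <- if (ped$sex[jj] == "male") 4 else 2
  (covsum / 2^m) / sqrt(vi * vj)
}

# Exact autosomal genotype correlation by enumerating every transmission
# vector (each non-founder picks one of 2 paternal x 2 maternal alleles).
# Given a transmission vector, each individual's genotype is the sum of two
# specific founder alleles (iid Bernoulli(p)), so all moments are closed
# form; no kinship recursion and no Monte Carlo is involved.
pair_corr_exact <- function(ped, i, j, p, coding = c("additive",
                                                     "recessive")) {
  coding <- match.arg(coding)
  ii <- match(i, ped$iid); jj <- match(j, ped$iid)
  ord <- order(ped$depth)
  nonf <- ord[ped$fidx[ord] > 0L]
  T <- length(nonf)
  founders <- which(ped$fidx == 0L)
  fa <- matrix(seq_len(2 * length(founders)), ncol = 2)  # allele ids
  exx <- 0
  for (v in seq_len(4^T) - 1L) {
    ids <- vector("list", nrow(ped))
    for (k in seq_along(founders)) ids[[founders[k]]] <- fa[k, ]
    code <- v
    for (k in nonf) {
      pat <- code %% 2L; code <- code %/% 2L
      mat <- code %% 2L; code <- code %/% 2L
      ids[[k]] <- c(ids[[ped$fidx[k]]][pat + 1L],
                    ids[[ped$midx[k]]][mat + 1L])
    }
    shared <- sum(outer(ids[[ii]], ids[[jj]], "=="))
    if (coding == "additive") {
      # E[x_i x_j | v] with x = sum of two Bernoulli founder alleles
      exx <- exx + 4 * p^2 + shared * (p - p^2)
    } else {
      # P(both homozygous risk | v) = p^(distinct founder alleles involved)
      u <- length(unique(c(ids[[ii]], ids[[jj]])))
      exx <- exx + p^u
    }
  }
  exx <- exx / 4^T
  if (coding == "additive") {
    (exx - 4 * p^2) / (2 * p * (1 - p))
  } else {
    (exx - p^4) / (p^2 * (1 - p^2))
  }
}

# Correlation estimate with a block-based Monte-Carlo standard error
# (genotype dosages are discrete, so the bivariate-normal SE formula for a
# sample correlation does not apply).
corr_with_se <- function(x, y, blocks = 40) {
  n <- length(x)
  idx <- rep(seq_len(blocks), length.out = n)
  r <- vapply(seq_len(blocks),
              function(b) cor(x[idx == b], y[idx == b]), numeric(1))
  list(est = mean(r), se = sd(r) / sqrt(blocks))
}

# Reference Cochran-Armitage trend chi-square from genotype counts,
# independent of the package implementation (stats::prop.trend.test).
ca_trend_chi2 <- function(g, y) {
  tab <- table(factor(g, levels = 0:2), factor(y, levels = 0:1))
  st <- stats::prop.trend.test(tab[, "1"], rowSums(tab), score = 0:2)
  unname(st$statistic)
}
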