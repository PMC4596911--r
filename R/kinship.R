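# Pairwise IBD-sharing coefficients and model-specific genotype correlations.
#
# Kinship coefficients come from the classical recursion; the probability
# pi2 that a pair shares both alleles IBD needs generalized (two-pair)
# kinship coefficients, computed by Karigl-style recursions. X-chromosomal
# kinship uses its own recursion in which a male carries a single X copied
# from his mother.

# A kinship calculator for one pedigree: memoized closures over an
# internally extended pedigree in which every real founder is given a pair
# of virtual, mutually unrelated founder parents. The extension leaves all
# identity coefficients of real individuals unchanged but lets the pair
# formula pi2 = phi22(f_i, f_j; m_i, m_j) + phi22(f_i, m_j; m_i, f_j) apply
# uniformly, parent-offspring and founder pairs included.
.kin_calc <- function(ped) {
  n <- nrow(ped)
  founders <- which(ped$fidx == 0L)
  nf <- length(founders)
  fidx <- c(ped$fidx, rep(0L, 2L * nf))
  midx <- c(ped$midx, rep(0L, 2L * nf))
  sex <- c(ped$sex, rep(c("male", "female"), nf))
  depth <- c(ped$depth + 1L, rep(0L, 2L * nf))
  fidx[founders] <- n + 2L * seq_len(nf) - 1L
  midx[founders] <- n + 2L * seq_len(nf)

  memo <- new.env(parent = emptyenv(), hash = TRUE)
  # family membership for quick unrelatedness short-circuit: virtual parents
  # inherit their child's family
  fam <- c(ped$fid, rep(ped$fid[founders], each = 2L))

  phi <- function(i, j) {
    if (fam[i] != fam[j]) return(0)
    key <- if (i <= j) paste0("p", i, ".", j) else paste0("p", j, ".", i)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      if (fidx[i] == 0L) 0.5 else 0.5 * (1 + phi(fidx[i], midx[i]))
    } else {
      a <- if (depth[i] >= depth[j]) i else j
      b <- if (a == i) j else i
      if (fidx[a] == 0L) 0 else 0.5 * (phi(fidx[a], b) + phi(midx[a], b))
    }
    memo[[key]] <- v
    v
  }

  phi3 <- function(i, j, k) {
    s <- sort(c(i, j, k))
    key <- paste0("t", paste(s, collapse = "."))
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    # pivot: a maximal-depth member (never a proper ancestor of the others)
    d <- depth[s]
    a <- s[which.max(d)]
    rest <- s[-which.max(d)]
    v <- if (a == rest[1] && a == rest[2]) {
      if (fidx[a] == 0L) 0.25 else 0.25 + 0.75 * phi(fidx[a], midx[a])
    } else if (a == rest[1] || a == rest[2]) {
      o <- if (a == rest[1]) rest[2] else rest[1]
      if (fidx[a] == 0L) 0 else
        0.5 * phi(a, o) + 0.5 * phi3(fidx[a], midx[a], o)
    } else {
      if (fidx[a] == 0L) 0 else
        0.5 * (phi3(fidx[a], rest[1], rest[2]) +
               phi3(midx[a], rest[1], rest[2]))
    }
    memo[[key]] <- v
    v
  }

  # phi22(i,j;k,l): P(random allele of i IBD random allele of j AND random
  # allele of k IBD random allele of l), all draws independent.
  phi22 <- function(i, j, k, l) {
    p1 <- sort(c(i, j)); p2 <- sort(c(k, l))
    if (p1[1] > p2[1] || (p1[1] == p2[1] && p1[2] > p2[2])) {
      tmp <- p1; p1 <- p2; p2 <- tmp
    }
    key <- paste0("q", p1[1], ".", p1[2], ";", p2[1], ".", p2[2])
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    all4 <- c(p1, p2)
    a <- all4[which.max(depth[all4])]
    cnt <- sum(all4 == a)
    fa <- fidx[a]; ma <- midx[a]
    v <- if (cnt == 4L) {
      if (fa == 0L) 0.25 else 0.25 + 0.75 * phi(fa, ma)
    } else if (cnt == 3L) {
      o <- all4[all4 != a]
      if (fa == 0L) 0 else 0.5 * phi(a, o) + 0.5 * phi3(fa, ma, o)
    } else if (cnt == 2L && p1[1] == p1[2]) {
      # both pivots in the first pair (or symmetric): (a,a; k,l)
      if (p1[1] == a) {
        if (fa == 0L) {
          0.5 * phi(p2[1], p2[2])
        } else {
          0.5 * phi(p2[1], p2[2]) + 0.5 * phi22(fa, ma, p2[1], p2[2])
        }
      } else {
        # pivot pair is p2
        if (fa == 0L) {
          0.5 * phi(p1[1], p1[2])
        } else {
          0.5 * phi(p1[1], p1[2]) + 0.5 * phi22(fa, ma, p1[1], p1[2])
        }
      }
    } else if (cnt == 2L && p2[1] == p2[2] && p2[1] == a) {
      if (fa == 0L) 0.5 * phi(p1[1], p1[2]) else
        0.5 * phi(p1[1], p1[2]) + 0.5 * phi22(fa, ma, p1[1], p1[2])
    } else if (cnt == 2L) {
      # pivot once in each pair: (a, b; a, d)
      b <- if (p1[1] == a) p1[2] else p1[1]
      d <- if (p2[1] == a) p2[2] else p2[1]
      if (fa == 0L) 0 else
        0.5 * phi3(a, b, d) +
        0.25 * (phi22(fa, b, ma, d) + phi22(ma, b, fa, d))
    } else {
      # pivot appears once
      if (p1[1] == a || p1[2] == a) {
        b <- if (p1[1] == a) p1[2] else p1[1]
        if (fa == 0L) 0 else
          0.5 * (phi22(fa, b, p2[1], p2[2]) + phi22(ma, b, p2[1], p2[2]))
      } else {
        d <- if (p2[1] == a) p2[2] else p2[1]
        if (fa == 0L) 0 else
          0.5 * (phi22(fa, d, p1[1], p1[2]) + phi22(ma, d, p1[1], p1[2]))
      }
    }
    memo[[key]] <- v
    v
  }

  # X-chromosomal kinship: a male carries one X (his mother's); a female two.
  phiX <- function(i, j) {
    if (fam[i] != fam[j]) return(0)
    if (is.na(sex[i]) || is.na(sex[j]))
      stop("sex required for X-chromosomal kinship")
    key <- if (i <= j) paste0("x", i, ".", j) else paste0("x", j, ".", i)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      if (sex[i] == "male") 1 else {
        if (fidx[i] == 0L) 0.5 else 0.5 * (1 + phiX(fidx[i], midx[i]))
      }
    } else {
      a <- if (depth[i] >= depth[j]) i else j
      b <- if (a == i) j else i
      if (fidx[a] == 0L) 0
      else if (sex[a] == "male") phiX(midx[a], b)
      else 0.5 * (phiX(fidx[a], b) + phiX(midx[a], b))
    }
    memo[[key]] <- v
    v
  }

  checked <- FALSE
  check_not_inbred <- function(idx = seq_len(n)) {
    if (checked) return(invisible(TRUE))
    for (i in seq_len(n)) {
      if (ped$fidx[i] > 0L && phi(ped$fidx[i], ped$midx[i]) > 0)
        stop("inbred individual '", ped$iid[i],
             "' (related parents); inbred pedigrees are not supported")
    }
    checked <<- TRUE
    invisible(TRUE)
  }

  list(phi = phi, phi3 = phi3, phi22 = phi22, phiX = phiX,
       fidx = fidx, midx = midx, check_not_inbred = check_not_inbred)
}

#' IBD-sharing and kinship coefficients for a pair of individuals
#'
#' Computes the probabilities \eqn{\pi_0, \pi_1, \pi_2} that the pair shares
#' 0, 1 or 2 alleles identical by descent, the autosomal kinship coefficient
#' \eqn{\phi}, and the X-chromosomal kinship coefficient \eqn{\phi_X}
#' (defined whenever both sexes are known). Founders are assumed non-inbred
#' and mutually unrelated; inbred pedigrees are rejected.
#'
#' For an outbred pair \eqn{2\phi = \pi_2 + \pi_1/2}, so the additive
#' genotype correlation equals twice the kinship coefficient.
#'
#' @param ped a [pedigree()] object.
#' @param i,j individual ids (distinct).
#' @return A list of class `"pair_coefficients"` with elements `pi0`, `pi1`,
#'   `pi2`, `phi` and `phiX` (`NA` if a sex is unknown).
#' @examples
#' ped <- pedigree(fid = "F1", iid = c("f", "m", "s1", "s2"),
#'                 father = c(NA, NA, "f", "f"),
#'                 mother = c(NA, NA, "m", "m"),
#'                 sex = c("male", "female", "female", "female"))
#' pair_coefficients(ped, "s1", "s2")  # pi = (1/4, 1/2, 1/4), phi = 1/4
#' @export
pair_coefficients <- function(ped, i, j) {
  stopifnot(inherits(ped, "fam_pedigree"))
  ii <- .ped_index(ped, i)
  jj <- .ped_index(ped, j)
  if (ii == jj) stop("i and j must be distinct individuals")
  kc <- .kin_calc(ped)
  kc$check_not_inbred(c(ii, jj))
  phi <- kc$phi(ii, jj)
  fi <- kc$fidx[ii]; mi <- kc$midx[ii]
  fj <- kc$fidx[jj]; mj <- kc$midx[jj]
  pi2 <- kc$phi22(fi, fj, mi, mj) + kc$phi22(fi, mj, mi, fj)
  pi1 <- 4 * phi - 2 * pi2
  phiX <- if (is.na(ped$sex[ii]) || is.na(ped$sex[jj])) NA_real_
          else kc$phiX(ii, jj)
  structure(list(pi0 = 1 - pi1 - pi2, pi1 = pi1, pi2 = pi2,
                 phi = phi, phiX = phiX),
            class = "pair_coefficients")
}

#' Pairwise genotype correlation under the additive coding
#'
#' \eqn{\rho = \pi_2 + \pi_1 \rho_T} with \eqn{\rho_T = 1/2} for autosomal
#' loci; equals twice the kinship coefficient for outbred pairs.
#'
#' @param coef a [pair_coefficients()] object.
#' @return The additive genotype correlation.
#' @export
additive_rho <- function(coef) {
  coef$pi2 + coef$pi1 / 2
}

#' Pairwise genotype correlation under the recessive coding
#'
#' Under the recessive coding (dosage 1 for the risk homozygote, 0
#' otherwise) the correlation depends on the risk-allele frequency:
#' \eqn{\rho = \pi_2 + \pi_1\, p/(1+p)} under random mating.
#'
#' @param coef a [pair_coefficients()] object.
#' @param p risk-allele frequency in (0, 1).
#' @return The recessive-coding genotype correlation.
#' @export
recessive_rho <- function(coef, p) {
  if (coef$pi1 > 0 && (!is.finite(p) || p <= 0 || p >= 1))
    stop("risk-allele frequency must be in (0, 1) for related pairs")
  coef$pi2 + coef$pi1 * p / (1 + p)
}

#' Pairwise genotype correlation under the dominant coding
#'
#' The dominant coding (dosage 1 for any carrier) is the recessive coding
#' after flipping the allele labels, so the correlation is the recessive one
#' evaluated at `1 - p`.
#'
#' @inheritParams recessive_rho
#' @return The dominant-coding genotype correlation.
#' @export
dominant_rho <- function(coef, p) {
  recessive_rho(coef, 1 - p)
}

#' X-linked genotype correlation for a pair
#'
#' With females coded 0/1/2 and males coded 0/2 (males treated as homozygous
#' females under X inactivation), the X-linked genotype correlation is
#' \eqn{\rho_X = 2\,\phi_X\, c_i c_j} with \eqn{c = 1} for females and
#' \eqn{c = 1/\sqrt{2}} for males. This reproduces the classical basic
#' correlations (sister pairs 3/4, maternal uncle-niece \eqn{1/(4\sqrt2)},
#' brother pairs 1/2, father-son 0).
#'
#' @inheritParams pair_coefficients
#' @return The X-linked genotype correlation.
#' @export
x_rho <- function(ped, i, j) {
  ii <- .ped_index(ped, i)
  jj <- .ped_index(ped, j)
  if (ii == jj) stop("i and j must be distinct individuals")
  if (is.na(ped$sex[ii]) || is.na(ped$sex[jj]))
    stop("sex must be known for X-linked correlations")
  kc <- .kin_calc(ped)
  kc$check_not_inbred(c(ii, jj))
  cf <- ifelse(c(ped$sex[ii], ped$sex[jj]) == "male", 1 / sqrt(2), 1)
  2 * kc$phiX(ii, jj) * cf[1] * cf[2]
}

#' Model-specific genotype correlation matrix
#'
#' Assembles the n x n matrix K of pairwise genotype correlations for a set
#' of individuals, with unit diagonal and family-block structure (pairs in
#' different families have correlation 0).
#'
#' @param ped a [pedigree()] object.
#' @param ids ordered individual ids defining the rows/columns.
#' @param model `"additive"`, `"recessive"` or `"dominant"`.
#' @param chromosome `"autosome"` or `"X"`. The X-linked matrix is defined
#'   for the additive coding only.
#' @param p risk-allele frequency; required for the recessive and dominant
#'   models.
#' @return A symmetric positive-semidefinite matrix with `ids` as dimnames.
#' @export
correlation_matrix <- function(ped, ids,
                               model = c("additive", "recessive", "dominant"),
                               chromosome = c("autosome", "X"), p = NULL) {
  model <- match.arg(model)
  chromosome <- match.arg(chromosome)
  idx <- .ped_index(ped, ids)
  n <- length(idx)
  if (chromosome == "X" && model != "additive")
    stop("X-linked correlation matrices are defined for the additive ",
         "model only")
  if (model %in% c("recessive", "dominant")) {
    if (is.null(p)) stop("allele frequency p is required for the ", model,
                         " model")
    if (model == "dominant") p <- 1 - p
  }
  kc <- .kin_calc(ped)
  kc$check_not_inbred(idx)
  K <- diag(1, n)
  if (n > 1) {
    fam <- ped$fid[idx]
    if (chromosome == "X") {
      sx <- ped$sex[idx]
      if (anyNA(sx)) stop("sex must be known for X-linked correlations")
      cf <- ifelse(sx == "male", 1 / sqrt(2), 1)
    }
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        if (fam[a] != fam[b]) next
        ia <- idx[a]; ib <- idx[b]
        if (ia == ib) stop("duplicated individual in ids")
        if (chromosome == "X") {
          rho <- 2 * kc$phiX(ia, ib) * cf[a] * cf[b]
        } else if (model == "additive") {
          rho <- 2 * kc$phi(ia, ib)
        } else {
          phi <- kc$phi(ia, ib)
          pi2 <- kc$phi22(kc$fidx[ia], kc$fidx[ib], kc$midx[ia],
                          kc$midx[ib]) +
                 kc$phi22(kc$fidx[ia], kc$midx[ib], kc$midx[ia],
                          kc$fidx[ib])
          pi1 <- 4 * phi - 2 * pi2
          rho <- if (pi1 == 0 && pi2 == 0) 0 else pi2 + pi1 * p / (1 + p)
        }
        K[a, b] <- K[b, a] <- rho
      }
    }
  }
  dimnames(K) <- list(ids, ids)
  K
}
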