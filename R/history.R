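# Family-history weights: the phenotype of a genotyped individual is
# augmented with the kinship-weighted phenotypes of its un-genotyped
# relatives, Y* = Y_n + K_{n,m} Y_m, and the score test is run with Y*
# in place of Y. Cases carry weight 1 and population controls weight 0
# before augmentation, so a case with two un-genotyped affected siblings
# gets Y* = 1 + (1/2 + 1/2) = 2.

#' Family-history weights Y*
#'
#' For each genotyped individual at a marker, adds \eqn{\rho_{ij}} times the
#' phenotype (1 = affected, 0 = unaffected) of every un-genotyped relative
#' in the same family, where \eqn{\rho_{ij}} is the model-appropriate
#' genotype correlation between the pair. Un-genotyped relatives with
#' missing phenotype contribute 0.
#'
#' @param ped a [pedigree()] object.
#' @param genotyped_ids ids of the individuals genotyped at the marker; the
#'   remaining pedigree members are the un-genotyped relatives.
#' @param model genetic model for the correlations (`"additive"`,
#'   `"recessive"`, `"dominant"`).
#' @param chromosome `"autosome"` or `"X"` (additive only).
#' @param p risk-allele frequency, required for recessive/dominant.
#' @param history_for `"cases"` (default): only genotyped cases receive
#'   augmentation, mirroring designs that attach family history to cases;
#'   `"all"`: every genotyped individual does.
#' @return A list of class `"phenotype_weights"`: `y_star` (named by
#'   genotyped id), `y_n`, `y_star_mean`, `n_relatives_used`.
#' @export
history_weights <- function(ped, genotyped_ids,
                            model = c("additive", "recessive", "dominant"),
                            chromosome = c("autosome", "X"), p = NULL,
                            history_for = c("cases", "all")) {
  model <- match.arg(model)
  chromosome <- match.arg(chromosome)
  history_for <- match.arg(history_for)
  gidx <- .ped_index(ped, genotyped_ids)
  y_n <- ped$affection[gidx]
  if (anyNA(y_n)) stop("genotyped individuals must have a phenotype")
  y_star <- y_n
  un_idx <- setdiff(seq_len(nrow(ped)), gidx)
  used <- 0L
  if (length(un_idx)) {
    y_m <- ped$affection[un_idx]
    y_m[is.na(y_m)] <- 0
    contrib <- which(y_m != 0)
    if (length(contrib)) {
      kc <- .kin_calc(ped)
      kc$check_not_inbred()
      if (chromosome == "X" && model != "additive")
        stop("X-linked testing supports the additive model only")
      if (model != "additive" && is.null(p))
        stop("allele frequency p is required for the ", model, " model")
      pp <- if (identical(model, "dominant")) 1 - p else p
      for (k in contrib) {
        m <- un_idx[k]
        rec <- which(ped$fid[gidx] == ped$fid[m] &
                     (history_for == "all" | y_n == 1))
        for (gpos in rec) {
          gi <- gidx[gpos]
          rho <- if (chromosome == "X") {
            if (is.na(ped$sex[gi]) || is.na(ped$sex[m]))
              stop("sex must be known for X-linked correlations")
            cf <- ifelse(c(ped$sex[gi], ped$sex[m]) == "male", 1 / sqrt(2), 1)
            2 * kc$phiX(gi, m) * cf[1] * cf[2]
          } else if (model == "additive") {
            2 * kc$phi(gi, m)
          } else {
            phi <- kc$phi(gi, m)
            pi2 <- kc$phi22(kc$fidx[gi], kc$fidx[m], kc$midx[gi],
                            kc$midx[m]) +
                   kc$phi22(kc$fidx[gi], kc$midx[m], kc$midx[gi],
                            kc$fidx[m])
            pi1 <- 4 * phi - 2 * pi2
            if (pi1 == 0 && pi2 == 0) 0 else pi2 + pi1 * pp / (1 + pp)
          }
          if (rho != 0) {
            y_star[gpos] <- y_star[gpos] + rho * y_m[k]
            used <- used + 1L
          }
        }
      }
    }
  }
  names(y_star) <- genotyped_ids
  structure(list(y_star = y_star, y_n = stats::setNames(y_n, genotyped_ids),
                 y_star_mean = mean(y_star), n_relatives_used = used),
            class = "phenotype_weights")
}

#' Score test with family-history weights
#'
#' Runs [run_score_test()] with the phenotype vector replaced by the
#' family-history weights \eqn{Y^*} computed per marker from the
#' marker-level missingness pattern. When no un-genotyped relative carries
#' a nonzero phenotype the result is identical to the unweighted test.
#'
#' @inheritParams run_score_test
#' @param history_for see [history_weights()].
#' @return A `"score_test_result"`; `r2T` and the frequency columns are
#'   computed exactly as in the unweighted test.
#' @export
weighted_score_test <- function(ped, genotypes, marker,
                                model = c("additive", "recessive",
                                          "dominant"),
                                chromosome = NULL,
                                freq_source = c("pooled", "controls"),
                                history_for = c("cases", "all")) {
  model <- match.arg(model)
  freq_source <- match.arg(freq_source)
  gm <- genotypes
  mrow <- match(marker, gm$markers$marker)
  if (is.na(mrow)) stop("marker '", marker, "' not found")
  chrom <- if (!is.null(chromosome)) chromosome
           else if (isTRUE(gm$markers$is_x[mrow])) "X" else "autosome"
  g <- gm$dosage[mrow, ]
  genotyped <- gm$samples[!is.na(g)]
  pidx <- .ped_index(ped, genotyped)
  genotyped <- genotyped[!is.na(ped$affection[pidx])]

  p_hat <- if (model != "additive") {
    gk <- !is.na(g)
    estimate_frequencies(g[gk], sex = ped$sex[.ped_index(ped, gm$samples[gk])],
                         chromosome = chrom)$p_hat
  } else NULL

  w <- history_weights(ped, genotyped, model = model, chromosome = chrom,
                       p = p_hat, history_for = match.arg(history_for))
  run_score_test(ped, genotypes, marker, model = model,
                 chromosome = chrom, freq_source = freq_source,
                 weights = w$y_star)
}
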