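# Score testing with imputed genotypes: the hard genotype is replaced by
# its posterior expected dosage, and the variance of the score is penalized
# by the information lost to imputation uncertainty (a missing-data /
# observed-information argument). The ratio of penalized to unpenalized
# variance is the post-analysis efficiency measure R^2_T.

#' Expected dosage from a genotype posterior
#'
#' \eqn{\tilde X = \varpi_1 + 2\varpi_2} for posteriors
#' \eqn{(\varpi_0,\varpi_1,\varpi_2)} over genotypes 0/1/2.
#'
#' @param w numeric length-3 vector, or an n x 3 matrix of posteriors
#'   (rows renormalized; a row sum deviating from 1 by more than 0.01 is an
#'   error).
#' @return Expected dosage(s) in `[0, 2]`.
#' @export
expected_dosage <- function(w) {
  w <- .check_posterior(w)
  unname(w[, 2] + 2 * w[, 3])
}

#' Per-individual information loss of an imputed genotype
#'
#' \eqn{l_i = \varpi_1(1-\varpi_1) + 4\varpi_2(1-\varpi_2) -
#' 4\varpi_1\varpi_2}: the posterior variance of the dosage, zero exactly
#' when the posterior is degenerate on one genotype (a hard call).
#'
#' @inheritParams expected_dosage
#' @return Loss value(s) \eqn{l_i \ge 0}.
#' @export
individual_loss <- function(w) {
  w <- .check_posterior(w)
  l <- w[, 2] * (1 - w[, 2]) + 4 * w[, 3] * (1 - w[, 3]) -
    4 * w[, 2] * w[, 3]
  unname(pmax(l, 0))
}

.check_posterior <- function(w) {
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  if (ncol(w) != 3) stop("posteriors must have three genotype classes")
  if (any(w < 0)) stop("negative posterior probabilities")
  s <- rowSums(w)
  if (any(abs(s - 1) > 1e-2))
    stop("posterior probabilities must sum to 1 (tolerance 0.01)")
  w / s
}

#' Information-loss matrix for a set of imputed genotypes
#'
#' \eqn{\Sigma_{\mathrm{loss};ii} = l_i} and
#' \eqn{\Sigma_{\mathrm{loss};ij} = \sqrt{l_i l_j}}: the outer product of
#' \eqn{\sqrt{l}}, a rank-one positive-semidefinite matrix.
#'
#' @param loss vector of per-individual losses (see [individual_loss()]).
#' @return The n x n loss matrix.
#' @export
loss_matrix <- function(loss) {
  s <- sqrt(pmax(loss, 0))
  tcrossprod(s)
}

#' Observed-data variance of the score with imputed genotypes
#'
#' \eqn{(Y-\bar Y)^\top [K \circ (\Sigma - \Sigma_{\mathrm{loss}})]
#' (Y-\bar Y)}; with zero loss this equals [score_variance()] exactly.
#'
#' @inheritParams score_variance
#' @param loss per-individual information losses.
#' @return The penalized variance (may be non-positive for an
#'   uninformative marker; the caller should then flag the test degenerate).
#' @export
observed_variance <- function(y, K, sigma, loss) {
  n <- length(y)
  if (length(loss) != n) stop("loss must match y in length")
  sigma <- rep_len(sigma, n)
  yc <- y - mean(y)
  M <- K * (tcrossprod(sigma) - loss_matrix(loss))
  drop(crossprod(yc, M %*% yc))
}

#' Post-analysis efficiency measure R^2_T
#'
#' Ratio of the loss-penalized to the unpenalized variance of the score:
#' 1 for hard genotypes, decreasing towards 0 as imputation uncertainty
#' destroys the information the test relies on. Marker- and
#' phenotype-specific.
#'
#' @inheritParams observed_variance
#' @return Efficiency in `[0, 1]`, or `NA` if the unpenalized variance is
#'   not positive.
#' @export
r2_T <- function(y, K, sigma, loss) {
  V <- score_variance(y, K, sigma)
  if (!is.finite(V) || V <= 0) return(NA_real_)
  max(0, min(1, observed_variance(y, K, sigma, loss) / V))
}
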