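#' Median-of-ratios size factors
#'
#' The library-size normalization native to count-based DE analysis:
#' each sample's factor is the median, over genes with nonzero counts in
#' every sample, of the ratio of its count to the gene's geometric mean
#' across samples.
#'
#' @param counts Nonnegative integer genes x samples matrix.
#' @param use_pseudo_reference If no gene is nonzero in all samples,
#'   fall back to a pseudo-reference computed on positive counts only
#'   (default `FALSE`, in which case the condition is an error).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, use_pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!use_pseudo_reference)
      stop("no gene has nonzero counts in all samples; ",
           "set use_pseudo_reference = TRUE to fall back", call. = FALSE)
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    keep <- is.finite(ref) & ref > 0
    sf <- apply(counts[keep, , drop = FALSE], 2L, function(col) {
      r <- col / ref[keep]
      median(r[col > 0])
    })
  } else {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    sf <- apply(counts[all_pos, , drop = FALSE], 2L, function(col)
      median(col / ref))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor estimated", call. = FALSE)
  sf
}

#' Pooled method-of-moments dispersion estimates
#'
#' Per-gene NB dispersion alpha under `Var = mu + alpha mu^2`, estimated
#' on size-factor-normalized counts by pooling squared deviations from
#' group means across all replicated groups, then solving the moment
#' identity for alpha and clamping at a floor.
#'
#' Raw per-gene estimates are noisy at a few replicates per group;
#' genes whose dispersion is underestimated become anti-conservative in
#' downstream tests and overestimated ones lose power. `shrink = TRUE`
#' therefore moderates each estimate toward the across-gene median
#' (the trend for a panel of comparable means) with a prior weight of
#' `prior_df` pseudo-degrees of freedom, the information-sharing idea
#' of the count-based DE packages. The default leaves estimates
#' unmoderated.
#'
#' @param counts Genes x samples count matrix.
#' @param design Design table aligned with the columns of `counts`;
#'   groups are stage-compartment cells (MT pools form their own group).
#' @param factors Size factors (default recomputed).
#' @param floor Lower clamp for alpha (default 1e-8).
#' @param shrink Moderate per-gene estimates toward the across-gene
#'   trend (default `FALSE`).
#' @param prior_df Prior weight (pseudo-df) of the trend when
#'   shrinking.
#' @return Named vector of per-gene alpha (>= floor).
#' @export
estimate_dispersion <- function(counts, design, factors = NULL,
                                floor = 1e-8, shrink = FALSE,
                                prior_df = 20) {
  design <- validate_design(design)
  stopifnot(identical(colnames(counts), design$sample_id))
  if (is.null(factors)) factors <- size_factors(counts)
  group <- interaction(design$stage, design$compartment, drop = TRUE)
  reps <- table(group)
  if (all(reps < 2L))
    stop("dispersion needs >= 2 replicates in at least one group",
         call. = FALSE)
  norm <- sweep(counts, 2L, factors, "/")

  ss <- numeric(nrow(counts))      # pooled squared deviations
  shot <- numeric(nrow(counts))    # pooled Poisson (shot-noise) part
  mu2 <- numeric(nrow(counts))     # pooled squared means
  df <- 0L
  for (g in levels(group)) {
    j <- which(group == g)
    if (length(j) < 2L) next
    n_j <- length(j)
    m <- rowMeans(norm[, j, drop = FALSE])
    ss_j <- rowSums((norm[, j, drop = FALSE] - m)^2)
    ss <- ss + ss_j
    # E[normalized count variance] = mu * mean(1/s_j) + alpha * mu^2;
    # m^2 overestimates mu^2 by Var(m), so use m^2 - s^2/n
    shot <- shot + (n_j - 1L) * m * mean(1 / factors[j])
    mu2 <- mu2 + (n_j - 1L) * pmax(m^2 - ss_j / (n_j * (n_j - 1L)), 0)
    df <- df + n_j - 1L
  }
  alpha <- (ss - shot) / mu2
  alpha[!is.finite(alpha)] <- floor
  if (shrink) {
    trend <- median(alpha[is.finite(alpha) & alpha > 0])
    if (is.finite(trend) && trend > 0)
      alpha <- (df * alpha + prior_df * trend) / (df + prior_df)
  }
  pmax(alpha, floor)
}

# NB(mu, alpha) log density that degrades gracefully to Poisson.
dnb_alpha <- function(x, mu, alpha, log = FALSE) {
  if (alpha <= 1e-12) dpois(x, lambda = mu, log = log)
  else dnbinom(x, size = 1 / alpha, mu = mu, log = log)
}

#' Exact conditional negative-binomial test for two groups
#'
#' Two-sided test of equal expression between groups A and B for one
#' gene, conditional on the total count. Each group's sum is modelled as
#' a single NB whose mean is the pooled per-unit expression times the
#' group's total size factor and whose variance matches the
#' size-factor-adjusted NB convolution
#' (`Var = q S + alpha q^2 sum(s_j^2)`). The p-value is the probability,
#' under the conditional distribution of the partition of the total,
#' of all partitions at most as probable as the observed one — a
#' mode-anchored two-sided rule rather than tail doubling.
#'
#' @param counts_A,counts_B Integer count vectors for the two groups.
#' @param factors_A,factors_B Size factors matched to the counts.
#' @param alpha NB dispersion (0 gives the Poisson/binomial branch).
#' @param tie_tol Relative slack when comparing partition probabilities
#'   to the observed one (numerical tie handling).
#' @return Two-sided p-value in (0, 1]; 1 when the total is zero.
#' @export
nb_exact_test <- function(counts_A, counts_B, factors_A = NULL,
                          factors_B = NULL, alpha = 0, tie_tol = 1e-10) {
  if (!length(counts_A) || !length(counts_B))
    stop("both groups must be nonempty", call. = FALSE)
  if (is.null(factors_A)) factors_A <- rep(1, length(counts_A))
  if (is.null(factors_B)) factors_B <- rep(1, length(counts_B))
  kA <- sum(counts_A); kB <- sum(counts_B); K <- kA + kB
  if (K == 0L) return(1)
  SA <- sum(factors_A); SB <- sum(factors_B)
  q <- K / (SA + SB)

  a <- 0:K
  if (alpha <= 1e-12) {
    # Poisson convolution: conditional law of kA | K is binomial
    lpA <- dbinom(a, K, SA / (SA + SB), log = TRUE)
    lp <- lpA  # conditional probabilities directly
    lobs <- dbinom(kA, K, SA / (SA + SB), log = TRUE)
  } else {
    muA <- q * SA; muB <- q * SB
    sizeA <- SA^2 / (alpha * sum(factors_A^2))
    sizeB <- SB^2 / (alpha * sum(factors_B^2))
    lp <- dnbinom(a, size = sizeA, mu = muA, log = TRUE) +
      dnbinom(K - a, size = sizeB, mu = muB, log = TRUE)
    lobs <- dnbinom(kA, size = sizeA, mu = muA, log = TRUE) +
      dnbinom(kB, size = sizeB, mu = muB, log = TRUE)
  }
  m <- max(lp)
  p_all <- exp(lp - m)
  keep <- lp <= lobs + log1p(tie_tol)
  min(1, sum(p_all[keep]) / sum(p_all))
}
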