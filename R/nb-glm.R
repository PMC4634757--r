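# NB log-link regression with fixed dispersion, by IRLS with
# step-halving. Returns coefficients, fitted means and the maximized
# log-likelihood; used by the stage-vs-null likelihood-ratio test.
nb_glm_fit <- function(y, X, alpha, offset = NULL, max_iter = 50L,
                       tol = 1e-8) {
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  loglik <- function(mu) sum(dnb_alpha(y, mu, alpha, log = TRUE))
  beta <- qr.solve(X, log(y + 0.5) - offset)
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  ll <- loglik(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- pmin(pmax(drop(X %*% beta_try) + offset, -30), 30)
      ll_try <- loglik(exp(eta_try))
      if (is.finite(ll_try) && ll_try >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-6) { beta_try <- beta; eta_try <- eta; ll_try <- ll; break }
    }
    moved <- abs(ll_try - ll)
    beta <- beta_try; eta <- eta_try; mu <- exp(eta); ll <- ll_try
    if (moved < tol) { converged <- TRUE; break }
  }
  list(beta = beta, mu = mu, loglik = ll, converged = converged)
}

#' Likelihood-ratio test of a stage effect for one gene
#'
#' Fits two negative-binomial log-link regressions to one gene's counts
#' with fixed dispersion and size-factor offsets: the stage model
#' (`count ~ stage`) and the reduced model (`count ~ 1`), and compares
#' them by a likelihood-ratio statistic against a chi-square with
#' (number of stages - 1) degrees of freedom. Intended to be run on the
#' samples of a single compartment, testing whether expression moves at
#' any point across early follicular development.
#'
#' @param counts_gene Integer counts for one gene.
#' @param stage Stage factor aligned with the counts (>= 2 levels
#'   present).
#' @param alpha Fixed NB dispersion for this gene.
#' @param factors Size factors (default all 1).
#' @return List with `p_value`, `stat`, `df`, `loglik_full`,
#'   `loglik_null`, `converged`. `p_value` is `NA` (flagged) if either
#'   fit failed to converge.
#' @export
nb_glm_lrt <- function(counts_gene, stage, alpha, factors = NULL) {
  stage <- droplevels(factor(stage))
  if (nlevels(stage) < 2L)
    stop("need >= 2 stages present for the stage model", call. = FALSE)
  if (length(counts_gene) != length(stage))
    stop("counts and stage factor must be aligned", call. = FALSE)
  if (is.null(factors)) factors <- rep(1, length(counts_gene))
  offset <- log(factors)
  X1 <- stats::model.matrix(~stage)
  X0 <- matrix(1, length(counts_gene), 1L)
  f1 <- nb_glm_fit(counts_gene, X1, alpha, offset)
  f0 <- nb_glm_fit(counts_gene, X0, alpha, offset)
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  df <- ncol(X1) - 1L
  ok <- f1$converged && f0$converged
  list(p_value = if (ok) pchisq(stat, df, lower.tail = FALSE) else NA_real_,
       stat = stat, df = df, loglik_full = f1$loglik,
       loglik_null = f0$loglik, converged = ok)
}
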