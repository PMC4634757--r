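# Independent oracles used across the suite. These recompute expected
# values by brute force or closed form, never through the package's
# own code paths.

# Naive enumeration of the conditional two-sided exact NB test:
# loops over every partition of the total with plain dnbinom/dpois
# products (no log-space arithmetic, no vectorized shortcuts).
oracle_exact_test <- function(counts_A, counts_B, factors_A = NULL,
                              factors_B = NULL, alpha = 0) {
  if (is.null(factors_A)) factors_A <- rep(1, length(counts_A))
  if (is.null(factors_B)) factors_B <- rep(1, length(counts_B))
  kA <- sum(counts_A); kB <- sum(counts_B); K <- kA + kB
  if (K == 0) return(1)
  SA <- sum(factors_A); SB <- sum(factors_B)
  q <- K / (SA + SB)
  dens <- function(x, S, fac) {
    if (alpha <= 1e-12) return(dpois(x, q * S))
    dnbinom(x, size = S^2 / (alpha * sum(fac^2)), mu = q * S)
  }
  p_obs <- dens(kA, SA, factors_A) * dens(kB, SB, factors_B)
  num <- 0; den <- 0
  for (a in 0:K) {
    p <- dens(a, SA, factors_A) * dens(K - a, SB, factors_B)
    den <- den + p
    if (p <= p_obs * (1 + 1e-10)) num <- num + p
  }
  min(1, num / den)
}

# Brute-force Bayes for the stage posterior: explicit likelihood
# products in plain arithmetic (no log space).
oracle_posterior <- function(fit, obs, prior = rep(1 / 4, 4),
                             use_level = TRUE) {
  stages <- foll_stages()
  ci <- match(obs$compartment, foll_compartments())
  genes <- names(obs$z)
  lik <- numeric(4)
  for (s in 1:4) {
    L <- 1
    for (g in genes) {
      gi <- match(g, fit$genes)
      eta <- fit$presence$beta[s, ci] +
        fit$presence$modes_stage[gi, s] + fit$presence$modes_cell[gi, ci]
      p <- 1 / (1 + exp(-eta))
      L <- L * if (obs$z[[g]] == 1) p else (1 - p)
      if (use_level && obs$z[[g]] == 1) {
        mu <- fit$level$beta[s, ci] +
          fit$level$modes_stage[gi, s] + fit$level$modes_cell[gi, ci]
        L <- L * dnorm(obs$y[[g]]^(1 / 4), mu, fit$level$resid_sd)
      }
    }
    lik[s] <- L
  }
  w <- prior * lik
  setNames(w / sum(w), stages)
}

# Hand-built hurdle_fit with prescribed parameters (additive
# structure), for exact posterior checks.
make_toy_fit <- function(genes, beta_logit, beta_mean,
                         modes_b_bin = NULL, modes_u_bin = NULL,
                         modes_b_lvl = NULL, modes_u_lvl = NULL,
                         resid_sd = 0.5) {
  G <- length(genes)
  zed <- function(m, q) if (is.null(m)) matrix(0, G, q) else m
  part <- function(beta, b, u, family, resid = NA_real_) {
    structure(list(beta = beta, modes_stage = zed(b, 4L),
                   modes_cell = zed(u, 2L), structure = "additive",
                   genes = genes, family = family, resid_sd = resid),
              class = c(if (family == "binomial") "presence_fit"
                        else "level_fit", "glmm_part"))
  }
  structure(list(
    presence = part(beta_logit, modes_b_bin, modes_u_bin, "binomial"),
    level = part(beta_mean, modes_b_lvl, modes_u_lvl, "gaussian",
                 resid_sd),
    genes = genes, transformation = "fourth-root"),
    class = "hurdle_fit")
}

beta_mat <- function(values_by_stage, stages = foll_stages()) {
  matrix(values_by_stage, 4, 2,
         dimnames = list(stages, foll_compartments()))
}

# Midpoint-rule numeric integration of a 2-D integrand on a grid, used
# as the quadrature oracle for tiny mixed-model instances.
quad2d <- function(f, lim = 6, n = 201) {
  x <- seq(-lim, lim, length.out = n)
  h <- x[2] - x[1]
  vals <- outer(x, x, Vectorize(f))
  sum(vals) * h * h
}

# Multivariate normal log density (closed form), the exact marginal
# likelihood oracle for the Gaussian part.
mvn_logdens <- function(y, mean, V) {
  k <- length(y)
  r <- y - mean
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            drop(r %*% solve(V) %*% r))
}
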