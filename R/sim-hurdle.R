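# Matrix square root tolerant of semidefinite input (chol fails on
# boundary cases such as an all-zero covariance).
mat_sqrt <- function(S) {
  if (length(S) == 1L) return(matrix(sqrt(max(S, 0)), 1L, 1L))
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance matrix is not positive semidefinite", call. = FALSE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

rmvn <- function(n, Sigma) {
  q <- nrow(Sigma)
  matrix(rnorm(n * q), n, q) %*% mat_sqrt(Sigma)
}

check_psd <- function(S, name) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(name, " must be positive semidefinite", call. = FALSE)
  invisible(S)
}

#' Single-factor stage correlation matrix
#'
#' Convenience constructor for a valid 4x4 stage correlation matrix with
#' a prescribed first row, built from a one-factor structure
#' `corr = lambda lambda' + diag(1 - lambda^2)` with
#' `lambda = (1, rho_pm, rho_sc, rho_sa)`. Guaranteed positive
#' semidefinite for loadings in `[-1, 1]`. The default mirrors the kind
#' of structure seen across early folliculogenesis: expression behaviour
#' at PD, PM and SC strongly aligned, and anti-correlated with SA.
#'
#' @param rho_pm,rho_sc,rho_sa Correlation of PM, SC, SA with PD.
#' @param sd Common standard deviation applied to all four stages;
#'   the result is a covariance matrix `sd^2 * corr`.
#' @return A 4x4 covariance matrix with stage dimnames.
#' @export
stage_cov_onefactor <- function(rho_pm = 0.95, rho_sc = 0.9, rho_sa = -0.9,
                                sd = 1) {
  lambda <- c(1, rho_pm, rho_sc, rho_sa)
  stopifnot(all(abs(lambda) <= 1))
  R <- tcrossprod(lambda) + diag(1 - lambda^2)
  S <- sd^2 * R
  dimnames(S) <- list(STAGES, STAGES)
  S
}

#' Parameters for the hurdle expression-panel simulator
#'
#' Describes a synthetic biomarker panel in the form produced by the
#' qPCR arm of the study: a binary detected/undetected response and,
#' where detected, a quantitative relative expression whose fourth root
#' is Gaussian. Gene-level stage random effects are correlated across
#' stages (4x4 covariance) and compartment random effects across the two
#' compartments (2x2); the binary and level parts draw independent
#' random vectors from the same covariances.
#'
#' @param n_genes Number of panel genes (default 24, the size of the
#'   biomarker signature).
#' @param fixed_logit 4x2 matrix (stage x compartment) of detection
#'   logits, or a single number recycled.
#' @param fixed_mean 4x2 matrix (stage x compartment) of fourth-root
#'   scale level means, or a single number recycled.
#' @param stage_cov 4x4 PSD covariance of per-gene stage random effects.
#' @param cell_cov 2x2 PSD covariance of per-gene compartment effects.
#' @param resid_sd Residual SD of the level part (fourth-root scale).
#' @param seed Integer seed.
#' @return An object of class `hurdle_sim_params`.
#' @export
hurdle_sim_params <- function(n_genes = 24L,
                              fixed_logit = matrix(c(2, 1, 0, -1), 4, 2,
                                                   dimnames = list(STAGES, COMPARTMENTS)),
                              fixed_mean = matrix(c(1.5, 2, 2.5, 3), 4, 2,
                                                  dimnames = list(STAGES, COMPARTMENTS)),
                              stage_cov = stage_cov_onefactor(sd = 0.8),
                              cell_cov = 0.3^2 * (diag(0.5, 2) + 0.5),
                              resid_sd = 0.25, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (length(fixed_logit) == 1L) fixed_logit <- matrix(fixed_logit, 4, 2)
  if (length(fixed_mean) == 1L) fixed_mean <- matrix(fixed_mean, 4, 2)
  stopifnot(all(dim(fixed_logit) == c(4, 2)), all(dim(fixed_mean) == c(4, 2)))
  dimnames(fixed_logit) <- dimnames(fixed_mean) <- list(STAGES, COMPARTMENTS)
  check_psd(stage_cov, "stage_cov")
  check_psd(cell_cov, "cell_cov")
  stopifnot(nrow(stage_cov) == 4L, nrow(cell_cov) == 2L)
  if (resid_sd <= 0) stop("resid_sd must be > 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), fixed_logit = fixed_logit,
                 fixed_mean = fixed_mean, stage_cov = stage_cov,
                 cell_cov = cell_cov, resid_sd = resid_sd,
                 seed = as.integer(seed)),
            class = "hurdle_sim_params")
}

#' Simulate a detected/level biomarker panel with known random effects
#'
#' For each gene, draws a stage random vector (length 4) and a
#' compartment random vector (length 2) from multivariate normals —
#' independently for the binary and level parts — then simulates, for
#' every LCM sample in the design (multi-tissue pools carry no stage and
#' are excluded from the panel), a Bernoulli detection indicator on the
#' logit scale and, where detected, a fourth-root-scale Gaussian level.
#' Undetected wells are recorded as absent (`NA`), never as numeric
#' zeros. The returned truth object carries every drawn effect and the
#' linear predictors, so a noiseless rerun is reconstructible.
#'
#' @param design Design table; only non-MT rows are used.
#' @param params A [hurdle_sim_params()] object.
#' @param noiseless If `TRUE`, skip the random draws at the observation
#'   level and return only the linear predictors (`eta`, `mu4`) implied
#'   by freshly drawn random effects.
#' @return A list of class `hurdle_sim` with `rel` (genes x samples
#'   relative expression, `NA` where undetected), `det` (0/1 matrix),
#'   `design` (LCM rows only), `truth` (fixed effects, all random
#'   effects, `eta`, `mu4`, truncation count), `params`.
#' @export
simulate_hurdle_panel <- function(design, params, noiseless = FALSE) {
  design <- validate_design(design)
  stopifnot(inherits(params, "hurdle_sim_params"))
  lcm <- design[design$compartment != "MT", , drop = FALSE]
  if (nrow(lcm) == 0L) stop("design has no LCM (O/GC) samples", call. = FALSE)
  set.seed(params$seed)

  G <- params$n_genes
  genes <- sprintf("bm_%02d", seq_len(G))
  s_idx <- match(as.character(lcm$stage), STAGES)
  c_idx <- match(as.character(lcm$compartment), COMPARTMENTS)

  b_bin <- rmvn(G, params$stage_cov); colnames(b_bin) <- STAGES
  c_bin <- rmvn(G, params$cell_cov);  colnames(c_bin) <- COMPARTMENTS
  b_lvl <- rmvn(G, params$stage_cov); colnames(b_lvl) <- STAGES
  c_lvl <- rmvn(G, params$cell_cov);  colnames(c_lvl) <- COMPARTMENTS
  rownames(b_bin) <- rownames(c_bin) <- rownames(b_lvl) <- rownames(c_lvl) <- genes

  n <- nrow(lcm)
  eta <- params$fixed_logit[cbind(rep(s_idx, each = G), rep(c_idx, each = G))]
  eta <- matrix(eta, G, n) + b_bin[, s_idx, drop = FALSE] +
    c_bin[, c_idx, drop = FALSE]
  mu4 <- params$fixed_mean[cbind(rep(s_idx, each = G), rep(c_idx, each = G))]
  mu4 <- matrix(mu4, G, n) + b_lvl[, s_idx, drop = FALSE] +
    c_lvl[, c_idx, drop = FALSE]
  dimnames(eta) <- dimnames(mu4) <- list(genes, lcm$sample_id)

  truth <- list(fixed_logit = params$fixed_logit,
                fixed_mean = params$fixed_mean,
                b_bin = b_bin, c_bin = c_bin, b_lvl = b_lvl, c_lvl = c_lvl,
                resid_sd = params$resid_sd, eta = eta, mu4 = mu4,
                n_truncated = 0L)

  if (noiseless) {
    return(structure(list(rel = NULL, det = NULL, design = lcm,
                          truth = truth, params = params),
                     class = "hurdle_sim"))
  }

  z <- matrix(rbinom(G * n, 1L, plogis(eta)), G, n,
              dimnames = dimnames(eta))
  y4 <- mu4 + matrix(rnorm(G * n, sd = params$resid_sd), G, n)
  # fourth-root levels must be positive for level = (y^(1/4))^4 to round-trip
  n_trunc <- sum(y4 <= 0 & z == 1L)
  y4 <- pmax(y4, 1e-6)
  rel <- y4^4
  rel[z == 0L] <- NA_real_
  truth$n_truncated <- n_trunc

  structure(list(rel = rel, det = z, design = lcm, truth = truth,
                 params = params),
            class = "hurdle_sim")
}
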