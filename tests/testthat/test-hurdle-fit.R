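lcm_design <- function(n_rep = 4L) {
  d <- generate_design(n_rep, n_rep, 0)
  d
}

test_that("null-expression augmentation adds exactly one record per silent cell", {
  d <- lcm_design()
  genes <- c("g1", "g2")
  det <- matrix(1L, 2, nrow(d), dimnames = list(genes, d$sample_id))
  rel <- matrix(2, 2, nrow(d), dimnames = list(genes, d$sample_id))
  # g1: half the PD.O replicates undetected -> no augmentation there
  pdo <- which(d$stage == "PD" & d$compartment == "O")
  det["g1", pdo[1:2]] <- 0L; rel["g1", pdo[1:2]] <- NA
  # g2: all SA.GC replicates undetected -> exactly one zero record
  sagc <- which(d$stage == "SA" & d$compartment == "GC")
  det["g2", sagc] <- 0L; rel["g2", sagc] <- NA
  aug <- augment_null_expression(rel, det, d)
  added <- aug[aug$augmented, ]
  expect_equal(nrow(added), 1L)
  expect_equal(added$gene, "g2")
  expect_equal(added$stage, "SA")
  expect_equal(added$compartment, "GC")
  expect_equal(added$level, 0)
  # detected records pass through unchanged
  expect_equal(sum(!aug$augmented), sum(det == 1L))
  # fully detected panel: no augmentation at all
  det2 <- matrix(1L, 2, nrow(d), dimnames = dimnames(det))
  rel2 <- matrix(2, 2, nrow(d), dimnames = dimnames(rel))
  aug2 <- augment_null_expression(rel2, det2, d)
  expect_false(any(aug2$augmented))
})

test_that("constant levels collapse to fixed means with vanishing noise", {
  d <- lcm_design()
  genes <- paste0("g", 1:3)
  q <- 16  # constant raw level, fourth root 2
  lv <- data.frame(gene = rep(genes, each = nrow(d)),
                   stage = rep(as.character(d$stage), 3),
                   compartment = rep(as.character(d$compartment), 3),
                   level = q, stringsAsFactors = FALSE)
  fit <- fit_level_model(lv, genes)
  expect_equal(unname(as.vector(fit$beta)), rep(2, 8), tolerance = 1e-3)
  expect_lt(fit$resid_sd, 1e-3)
  expect_lt(max(abs(fit$modes_stage)), 1e-2)
})

test_that("level fit is equivariant to scaling the raw expression", {
  d <- lcm_design()
  sim <- simulate_hurdle_panel(d, hurdle_sim_params(n_genes = 8, seed = 2,
                                                    fixed_logit = 5))
  aug <- augment_null_expression(sim$rel, sim$det, sim$design)
  ctl <- hurdle_control(em_tol = 1e-9, max_em = 500L)
  f1 <- fit_level_model(aug, rownames(sim$rel), ctl)
  aug16 <- aug; aug16$level <- aug16$level * 16
  f2 <- fit_level_model(aug16, rownames(sim$rel), ctl)
  expect_equal(2 * f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(2 * f1$resid_sd, f2$resid_sd, tolerance = 1e-6)
  # the covariance EM approaches its optimum slowly, so the scaled
  # covariances agree to ~1% rather than machine precision
  expect_equal(4 * f1$Sigma_stage, f2$Sigma_stage, tolerance = 0.01)
})

test_that("refitting identical data reproduces identical parameters", {
  d <- lcm_design()
  sim <- simulate_hurdle_panel(d, hurdle_sim_params(n_genes = 10, seed = 6))
  f1 <- fit_hurdle(sim$det, sim$rel, sim$design)
  f2 <- fit_hurdle(sim$det, sim$rel, sim$design)
  expect_identical(f1$presence$beta, f2$presence$beta)
  expect_identical(f1$level$Sigma_stage, f2$level$Sigma_stage)
  expect_identical(f1$presence$modes_stage, f2$presence$modes_stage)
})

test_that("disjoint gene panels are rejected", {
  d <- lcm_design()
  det <- matrix(1L, 2, nrow(d), dimnames = list(c("a", "b"), d$sample_id))
  rel <- matrix(1, 2, nrow(d), dimnames = list(c("c", "d"), d$sample_id))
  expect_error(fit_hurdle(det, rel, d), "no genes shared")
})

test_that("all-detected data trips the separation flag with a penalized fit", {
  d <- lcm_design()
  genes <- paste0("g", 1:4)
  det <- matrix(1L, 4, nrow(d), dimnames = list(genes, d$sample_id))
  fit <- fit_presence_model(det, d)
  expect_true(fit$separated)
  expect_gt(fit$ridge, 0)
  expect_true(all(fit$beta > 3))  # logits pushed to the penalty ceiling
})

test_that("balanced unstructured detection gives near-zero logits", {
  d <- lcm_design(8L)
  set.seed(31)
  det <- matrix(rbinom(40 * nrow(d), 1, 0.5), 40, nrow(d),
                dimnames = list(paste0("g", 1:40), d$sample_id))
  fit <- fit_presence_model(det, d)
  expect_true(all(abs(fit$beta) < 2 * pmax(fit$se_beta, 0.2)))
  expect_lt(mean(abs(fit$beta)), 0.4)
})

test_that("EM trace of the exact Gaussian likelihood is non-decreasing", {
  d <- lcm_design()
  sim <- simulate_hurdle_panel(d, hurdle_sim_params(n_genes = 12, seed = 9))
  aug <- augment_null_expression(sim$rel, sim$det, sim$design)
  fit <- fit_level_model(aug, rownames(sim$rel))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-6))
})

test_that("Laplace likelihood matches quadrature on a tiny instance", {
  # 2 genes x 2 stages x 2 replicates, one compartment, fixed Sigma:
  # only the PD and PM stage slots carry data; with the compartment
  # variance made negligible, the marginal likelihood per gene is a
  # 2-D integral over (b_PD, b_PM).
  d <- generate_design(2, 2, 0)
  keep <- d$compartment == "O" & d$stage %in% c("PD", "PM")
  d2 <- d[keep, ]
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Sig_stage <- diag(4); Sig_stage[1:2, 1:2] <- S2
  Sig_cell <- diag(1e-8, 2)
  beta_fix <- matrix(0.3, 4, 2,
                     dimnames = list(foll_stages(), foll_compartments()))
  ctl <- hurdle_control(max_em = 1L,
                        init = list(Sigma_stage = Sig_stage,
                                    Sigma_cell = Sig_cell,
                                    sigma2 = 0.25),
                        fix_beta = beta_fix)

  # ---- binary part
  zmat <- matrix(c(1L, 0L, 1L, 1L,
                   0L, 0L, 1L, 0L), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), d2$sample_id))
  fitb <- fit_presence_model(zmat, d2, ctl)
  stage_of <- match(as.character(d2$stage), foll_stages())
  S2_det <- S2[1, 1] * S2[2, 2] - S2[1, 2] * S2[2, 1]
  ll_quad <- 0
  for (g in 1:2) {
    integrand <- function(b1, b2) {
      eta <- 0.3 + c(b1, b2)[stage_of]
      p <- plogis(eta)
      lik <- prod(ifelse(zmat[g, ] == 1L, p, 1 - p))
      dens <- exp(-0.5 * drop(c(b1, b2) %*% solve(S2) %*% c(b1, b2))) /
        (2 * pi * sqrt(S2_det))
      lik * dens
    }
    ll_quad <- ll_quad + log(quad2d(integrand, lim = 8, n = 161))
  }
  # Laplace approximates the Bernoulli integral; agreement is close
  # but not exact (the level part below is exact)
  expect_equal(fitb$loglik, ll_quad, tolerance = 0.02)

  # ---- level part: Laplace is exact for the Gaussian model
  lv <- data.frame(gene = rep(c("g1", "g2"), each = 4),
                   stage = rep(as.character(d2$stage), 2),
                   compartment = "O",
                   level = c(1.2, 0.8, 5.0, 4.2, 0.3, 0.5, 2.0, 2.5),
                   stringsAsFactors = FALSE)
  fitl <- fit_level_model(lv, c("g1", "g2"), ctl)
  y4 <- matrix(lv$level^(1 / 4), 2, 4, byrow = TRUE)
  Z <- outer(stage_of, 1:2, "==") * 1  # 4 obs x 2 slots
  V <- Z %*% S2 %*% t(Z) + diag(0.25, 4) + 1e-8
  ll_exact <- sum(vapply(1:2, function(g)
    mvn_logdens(y4[g, ], rep(0.3, 4), V), 0))
  expect_equal(fitl$loglik, ll_exact, tolerance = 1e-6)
})

test_that("stage correlations are recovered from simulated panels", {
  d <- lcm_design()
  S <- stage_cov_onefactor(rho_pm = 0.9, rho_sc = 0.6, rho_sa = -0.6,
                           sd = 1)
  cors_lvl <- matrix(NA_real_, 5, 2)
  for (i in 1:5) {
    sim <- simulate_hurdle_panel(d, hurdle_sim_params(
      n_genes = 24, stage_cov = S, fixed_logit = 2.5,
      fixed_mean = matrix(c(2.5, 3, 3.5, 4), 4, 2), seed = 100 + i))
    fit <- fit_hurdle(sim$det, sim$rel, sim$design)
    sc <- stage_effect_correlations(fit)
    cors_lvl[i, ] <- c(sc$level$model["PD", "PM"],
                       sc$level$model["PD", "SA"])
  }
  expect_lt(abs(mean(cors_lvl[, 1]) - 0.9), 0.15)
  expect_lt(abs(mean(cors_lvl[, 2]) + 0.6), 0.2)
})

test_that("degenerate variance components report undefined correlations", {
  S <- diag(c(1, 1, 1, 0))  # SA variance zero
  dimnames(S) <- list(foll_stages(), foll_stages())
  fitlike <- structure(list(
    presence = list(Sigma_stage = S, structure = "additive",
                    modes_stage = matrix(rnorm(40), 10, 4,
                                         dimnames = list(NULL, foll_stages())),
                    modes_cell = matrix(0, 10, 2)),
    level = list(Sigma_stage = diag(4), structure = "additive",
                 modes_stage = matrix(rnorm(40), 10, 4,
                                      dimnames = list(NULL, foll_stages())),
                 modes_cell = matrix(0, 10, 2))),
    class = "hurdle_fit")
  rep_ <- stage_effect_correlations(fitlike)
  expect_true(all(is.na(rep_$binary$model["SA", 1:3])))
  expect_equal(rep_$binary$model["PD", "PD"], 1)
})
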