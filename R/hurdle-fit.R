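#' Control parameters for the hurdle model optimizer
#'
#' @param max_em Maximum EM (covariance-update) iterations.
#' @param em_tol Convergence tolerance on the change in the Laplace
#'   marginal log-likelihood between EM iterations.
#' @param max_newton Maximum inner Newton iterations per EM step.
#' @param newton_tol Gradient-norm tolerance for the inner joint Newton
#'   solve over fixed effects and conditional modes.
#' @param ridge Logistic ridge penalty on fixed-effect logits, engaged
#'   only when separation is detected (default 1e-4).
#' @param jitter Diagonal jitter added before inverting covariance
#'   blocks.
#' @param sigma_floor Lower floor on the residual SD of the level part.
#' @param structure Random-effect architecture: `"additive"` (a
#'   4-vector of stage effects plus a 2-vector of compartment effects
#'   per gene, the default, identifiable on a 24-gene panel) or
#'   `"cell8"` (one unstructured 8-vector per gene over the
#'   stage-compartment cells).
#' @param init Optional list overriding initial values: any of
#'   `Sigma_stage`, `Sigma_cell`, `sigma2`. With `max_em = 1` this
#'   evaluates the model at fixed covariances (no update is applied to
#'   the reported likelihood).
#' @param fix_beta Optional fixed-effect matrix (stage x compartment);
#'   when given, fixed effects are frozen and only the conditional
#'   modes are optimized.
#' @return A list of class `hurdle_control`.
#' @export
hurdle_control <- function(max_em = 200L, em_tol = 1e-6, max_newton = 50L,
                           newton_tol = 1e-8, ridge = 1e-4, jitter = 1e-8,
                           sigma_floor = 1e-6,
                           structure = c("additive", "cell8"),
                           init = NULL, fix_beta = NULL) {
  structure(list(max_em = max_em, em_tol = em_tol, max_newton = max_newton,
                 newton_tol = newton_tol, ridge = ridge, jitter = jitter,
                 sigma_floor = sigma_floor,
                 structure = match.arg(structure),
                 init = init, fix_beta = fix_beta),
            class = "hurdle_control")
}

# cell index 1..8 from stage index (1..4) and compartment index (1..2)
cell_index <- function(s, c) (c - 1L) * 4L + s

solve_psd <- function(S, jitter) solve(S + jitter * diag(nrow(S)))

logdet_psd <- function(S) {
  d <- determinant(S, logarithm = TRUE)
  as.numeric(d$modulus)
}

# Joint Laplace/EM fit of one part of the hurdle model.
#
# obs: list with integer vectors g (gene 1..G), s (stage 1..4),
# comp (1..2) and response y (0/1 for binomial, fourth-root level for
# gaussian). Model: link(E y) = beta[cell(s,comp)] + z' v_g with v_g a
# per-gene MVN random vector (additive: (b_g, u_g), q = 6; cell8:
# unstructured q = 8), estimated by penalized joint Newton over
# (beta, v) given the covariances and EM updates of the covariances
# from conditional modes + conditional covariances (gene-block Hessian
# inverse). The Laplace marginal log-likelihood (exact for gaussian) is
# tracked across EM iterations.
fit_glmm_part <- function(obs, G, family = c("binomial", "gaussian"),
                          control = hurdle_control()) {
  family <- match.arg(family)
  structure_kind <- control$structure
  q <- if (structure_kind == "additive") 6L else 8L
  n_beta <- 8L
  cells <- cell_index(obs$s, obs$comp)
  n_obs <- length(obs$y)
  stopifnot(n_obs > 0L, all(obs$g >= 1L), all(obs$g <= G))

  # per-gene observation rows and dense design blocks
  rows <- split(seq_len(n_obs), factor(obs$g, levels = seq_len(G)))
  Zg <- Xg <- vector("list", G)
  for (g in seq_len(G)) {
    idx <- rows[[g]]
    Z <- matrix(0, length(idx), q)
    if (structure_kind == "additive") {
      Z[cbind(seq_along(idx), obs$s[idx])] <- 1
      Z[cbind(seq_along(idx), 4L + obs$comp[idx])] <- 1
    } else {
      Z[cbind(seq_along(idx), cells[idx])] <- 1
    }
    X <- matrix(0, length(idx), n_beta)
    X[cbind(seq_along(idx), cells[idx])] <- 1
    Zg[[g]] <- Z; Xg[[g]] <- X
  }

  y <- obs$y
  cell_n <- tabulate(cells, n_beta)
  cell_sum <- vapply(seq_len(n_beta), function(k) sum(y[cells == k]), 0)
  cell_mean <- ifelse(cell_n > 0, cell_sum / pmax(cell_n, 1L), mean(y))

  # separation screen for the binary part: a fixed-effect cell whose
  # observations are all 0 or all 1 has no finite MLE
  separated <- FALSE
  ridge_lambda <- 0
  if (family == "binomial" &&
      any(cell_n > 0 & (cell_mean <= 0 | cell_mean >= 1))) {
    separated <- TRUE
    ridge_lambda <- control$ridge
  }

  beta <- if (family == "binomial") {
    qlogis(pmin(pmax(cell_mean, 0.02), 0.98))
  } else cell_mean
  beta_fixed <- !is.null(control$fix_beta)
  if (beta_fixed) beta <- as.vector(control$fix_beta)
  v <- matrix(0, G, q)
  sigma2 <- if (family == "gaussian") {
    max(var(y - beta[cells]), control$sigma_floor^2)
  } else NA_real_
  if (structure_kind == "additive") {
    Sig_s <- diag(0.5, 4L); Sig_c <- diag(0.25, 2L)
  } else {
    Sig_s <- diag(0.5, 8L); Sig_c <- NULL
  }
  if (!is.null(control$init)) {
    if (!is.null(control$init$Sigma_stage)) Sig_s <- control$init$Sigma_stage
    if (!is.null(control$init$Sigma_cell)) Sig_c <- control$init$Sigma_cell
    if (!is.null(control$init$sigma2)) sigma2 <- control$init$sigma2
  }

  eta_of <- function(beta, v) {
    e <- beta[cells]
    if (structure_kind == "additive") {
      e + v[cbind(obs$g, obs$s)] + v[cbind(obs$g, 4L + obs$comp)]
    } else {
      e + v[cbind(obs$g, cells)]
    }
  }
  pen_obj <- function(eta, v, beta, Omega) {
    ll <- if (family == "binomial") sum(y * eta - log1p(exp(eta)))
          else sum(dnorm(y, eta, sqrt(sigma2), log = TRUE))
    ll - 0.5 * sum(vapply(seq_len(G), function(g)
      drop(v[g, ] %*% Omega %*% v[g, ]), 0)) -
      0.5 * ridge_lambda * sum(beta^2)
  }

  trace_ll <- numeric(0)
  converged <- FALSE
  A_inv <- vector("list", G)
  S_mat <- NULL
  ll_old <- -Inf

  for (em in seq_len(control$max_em)) {
    Omega <- if (structure_kind == "additive") {
      Om <- matrix(0, 6L, 6L)
      Om[1:4, 1:4] <- solve_psd(Sig_s, control$jitter)
      Om[5:6, 5:6] <- solve_psd(Sig_c, control$jitter)
      Om
    } else solve_psd(Sig_s, control$jitter)

    # inner joint Newton over (beta, v)
    eta <- eta_of(beta, v)
    obj <- pen_obj(eta, v, beta, Omega)
    for (it in seq_len(control$max_newton)) {
      if (family == "binomial") {
        p <- plogis(eta)
        score <- y - p
        w <- pmax(p * (1 - p), 1e-10)
      } else {
        score <- (y - eta) / sigma2
        w <- rep(1 / sigma2, n_obs)
      }
      g_beta <- vapply(seq_len(n_beta), function(k)
        sum(score[cells == k]), 0) - ridge_lambda * beta
      H_bb <- diag(vapply(seq_len(n_beta), function(k)
        sum(w[cells == k]), 0) + ridge_lambda + 1e-10)

      S_schur <- H_bb
      rhs <- g_beta
      gv <- Av <- vector("list", G)
      for (g in seq_len(G)) {
        idx <- rows[[g]]
        Z <- Zg[[g]]; X <- Xg[[g]]
        wZ <- w[idx] * Z
        A <- crossprod(Z, wZ) + Omega
        B <- crossprod(X, wZ)                       # n_beta x q
        gvec <- drop(crossprod(Z, score[idx])) - drop(Omega %*% v[g, ])
        Ai <- solve(A)
        S_schur <- S_schur - B %*% Ai %*% t(B)
        rhs <- rhs - drop(B %*% Ai %*% gvec)
        gv[[g]] <- gvec; Av[[g]] <- Ai
        A_inv[[g]] <- Ai
      }
      d_beta <- if (beta_fixed) rep(0, n_beta) else solve(S_schur, rhs)
      d_v <- matrix(0, G, q)
      for (g in seq_len(G)) {
        idx <- rows[[g]]
        Bt_db <- drop(crossprod(w[idx] * Zg[[g]], Xg[[g]] %*% d_beta))
        d_v[g, ] <- drop(Av[[g]] %*% (gv[[g]] - Bt_db))
      }
      grad_norm <- if (beta_fixed) max(abs(unlist(gv)))
                   else max(abs(g_beta), abs(unlist(gv)))
      step <- 1
      repeat {
        beta_try <- beta + step * d_beta
        v_try <- v + step * d_v
        eta_try <- eta_of(beta_try, v_try)
        obj_try <- pen_obj(eta_try, v_try, beta_try, Omega)
        if (is.finite(obj_try) && obj_try >= obj - 1e-10) break
        step <- step / 2
        if (step < 1e-8) {
          beta_try <- beta; v_try <- v; eta_try <- eta; obj_try <- obj
          break
        }
      }
      beta <- beta_try; v <- v_try; eta <- eta_try
      moved <- obj_try - obj
      obj <- obj_try
      S_mat <- S_schur
      if (grad_norm < control$newton_tol || abs(moved) < 1e-12) break
    }
    if (is.null(S_mat)) S_mat <- diag(1, n_beta)

    # post-hoc separation check: runaway logits under no penalty
    if (family == "binomial" && ridge_lambda == 0 &&
        max(abs(eta)) > 15) {
      separated <- TRUE
      ridge_lambda <- control$ridge
      next
    }

    # Laplace marginal log-likelihood at current covariances
    ld_Sigma <- if (structure_kind == "additive")
      logdet_psd(Sig_s + control$jitter * diag(4)) +
        logdet_psd(Sig_c + control$jitter * diag(2))
    else logdet_psd(Sig_s + control$jitter * diag(8))
    ll <- 0
    for (g in seq_len(G)) {
      idx <- rows[[g]]
      llg <- if (family == "binomial")
        sum(y[idx] * eta[idx] - log1p(exp(eta[idx])))
      else sum(dnorm(y[idx], eta[idx], sqrt(sigma2), log = TRUE))
      ll <- ll + llg - 0.5 * drop(v[g, ] %*% Omega %*% v[g, ]) -
        0.5 * ld_Sigma + 0.5 * determinant(A_inv[[g]])$modulus
    }
    ll <- as.numeric(ll)
    trace_ll <- c(trace_ll, ll)

    # EM updates of the covariances (and residual variance)
    M <- matrix(0, q, q)
    for (g in seq_len(G)) M <- M + tcrossprod(v[g, ]) + A_inv[[g]]
    M <- M / G
    if (structure_kind == "additive") {
      Sig_s_new <- (M[1:4, 1:4] + t(M[1:4, 1:4])) / 2
      Sig_c_new <- (M[5:6, 5:6] + t(M[5:6, 5:6])) / 2
    } else {
      Sig_s_new <- (M + t(M)) / 2
      Sig_c_new <- NULL
    }
    if (family == "gaussian") {
      quad <- 0
      for (g in seq_len(G)) {
        Z <- Zg[[g]]
        quad <- quad + sum((Z %*% A_inv[[g]]) * Z)
      }
      sigma2 <- max(sum((y - eta)^2) / n_obs + quad / n_obs,
                    control$sigma_floor^2)
    }
    Sig_s <- Sig_s_new
    if (!is.null(Sig_c_new)) Sig_c <- Sig_c_new

    if (em > 1L && abs(ll - ll_old) < control$em_tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }

  se_beta <- sqrt(pmax(diag(solve(S_mat)), 0))
  beta_mat <- matrix(beta, 4L, 2L, dimnames = list(STAGES, COMPARTMENTS))
  se_mat <- matrix(se_beta, 4L, 2L, dimnames = list(STAGES, COMPARTMENTS))
  if (structure_kind == "additive") {
    dimnames(Sig_s) <- list(STAGES, STAGES)
    dimnames(Sig_c) <- list(COMPARTMENTS, COMPARTMENTS)
    modes_b <- v[, 1:4, drop = FALSE]; colnames(modes_b) <- STAGES
    modes_u <- v[, 5:6, drop = FALSE]; colnames(modes_u) <- COMPARTMENTS
  } else {
    cn <- as.vector(outer(STAGES, COMPARTMENTS, paste0))
    dimnames(Sig_s) <- list(cn, cn)
    modes_b <- v; colnames(modes_b) <- cn
    modes_u <- NULL
  }
  list(beta = beta_mat, se_beta = se_mat, Sigma_stage = Sig_s,
       Sigma_cell = Sig_c, modes_stage = modes_b, modes_cell = modes_u,
       cond_cov = A_inv, sigma2 = sigma2,
       resid_sd = if (family == "gaussian") sqrt(sigma2) else NA_real_,
       loglik = ll_old, trace = trace_ll, converged = converged,
       separated = separated, ridge = ridge_lambda, family = family,
       structure = structure_kind, n_obs = n_obs, n_genes = G)
}

# Long-format observations from detection / level matrices.
obs_from_matrix <- function(mat, design, keep = NULL) {
  s_idx <- match(as.character(design$stage), STAGES)
  c_idx <- match(as.character(design$compartment), COMPARTMENTS)
  G <- nrow(mat); n <- ncol(mat)
  g <- rep(seq_len(G), times = n)
  j <- rep(seq_len(n), each = G)
  ok <- if (is.null(keep)) !is.na(as.vector(mat)) else as.vector(keep)
  list(g = g[ok], s = s_idx[j[ok]], comp = c_idx[j[ok]],
       y = as.vector(mat)[ok])
}

#' Augment fully-undetected cells with a single null observation
#'
#' Builds the level-part dataset: every detected (gene, sample)
#' measurement passes through unchanged, and for each (gene, stage,
#' compartment) cell in which no replicate at all was detected, exactly
#' one record with zero expression is appended, so the level model sees
#' that the gene is silent there rather than having no information.
#' Cells with at least one detected replicate are never augmented.
#'
#' @param rel Relative-expression matrix (genes x samples, `NA` where
#'   undetected).
#' @param det Matching 0/1 detection matrix.
#' @param design Design table for the columns (LCM samples).
#' @return data.frame with columns `gene`, `stage`, `compartment`,
#'   `level` (raw relative expression; 0 for augmented records) and
#'   `augmented` (logical).
#' @export
augment_null_expression <- function(rel, det, design) {
  design <- validate_design(design)
  stopifnot(is.matrix(rel), is.matrix(det), all(dim(rel) == dim(det)),
            identical(colnames(rel), design$sample_id))
  genes <- rownames(rel)
  stage_ch <- as.character(design$stage)
  comp_ch <- as.character(design$compartment)

  out <- list()
  det_idx <- which(det == 1L, arr.ind = TRUE)
  if (nrow(det_idx)) {
    out[[1L]] <- data.frame(
      gene = genes[det_idx[, 1L]], stage = stage_ch[det_idx[, 2L]],
      compartment = comp_ch[det_idx[, 2L]],
      level = rel[det_idx], augmented = FALSE, stringsAsFactors = FALSE)
  }
  cells <- unique(data.frame(stage = stage_ch, compartment = comp_ch,
                             stringsAsFactors = FALSE))
  aug <- list()
  for (i in seq_len(nrow(cells))) {
    cols <- which(stage_ch == cells$stage[i] &
                    comp_ch == cells$compartment[i])
    none <- rowSums(det[, cols, drop = FALSE] == 1L) == 0L
    if (any(none)) {
      aug[[length(aug) + 1L]] <- data.frame(
        gene = genes[none], stage = cells$stage[i],
        compartment = cells$compartment[i], level = 0,
        augmented = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, aug))
  rownames(res) <- NULL
  res
}

#' Fit the presence/absence part of the hurdle model
#'
#' Hierarchical logistic regression of the detection indicator on
#' stage and compartment fixed effects with correlated per-gene stage
#' random effects (4x4 covariance) and compartment random effects (2x2),
#' estimated by Laplace-approximated maximum likelihood: a penalized
#' joint Newton solve for fixed effects and conditional modes, with EM
#' updates of the covariances. Complete separation (a cell all detected
#' or all undetected) engages a small ridge on the logits and is
#' flagged.
#'
#' @param det 0/1 detection matrix (genes x samples).
#' @param design Design table for the columns.
#' @param control A [hurdle_control()] object.
#' @return A list of class `presence_fit` (see [fit_glmm_part] fields):
#'   fixed-effect logits `beta` (stage x compartment), `Sigma_stage`,
#'   `Sigma_cell`, conditional modes, Laplace log-likelihood trace and
#'   convergence/separation flags.
#' @export
fit_presence_model <- function(det, design, control = hurdle_control()) {
  design <- validate_design(design)
  stopifnot(is.matrix(det), identical(colnames(det), design$sample_id))
  if (nrow(det) < 2L) stop("need >= 2 genes", call. = FALSE)
  if (length(unique(design$stage[design$stage != "NONE"])) < 2L)
    stop("need >= 2 stages", call. = FALSE)
  if (all(det == det[1L])) {
    # still fittable, but warn that one outcome class may be absent
  }
  obs <- obs_from_matrix(det, design, keep = !is.na(det))
  fit <- fit_glmm_part(obs, G = nrow(det), family = "binomial",
                       control = control)
  fit$genes <- rownames(det)
  rownames(fit$modes_stage) <- rownames(det)
  if (!is.null(fit$modes_cell)) rownames(fit$modes_cell) <- rownames(det)
  class(fit) <- c("presence_fit", "glmm_part")
  fit
}

#' Fit the quantitative (level) part of the hurdle model
#'
#' Linear mixed model on the fourth root of relative expression for
#' detected observations plus the single-null-observation augmentation
#' of silent cells, with the same correlated random-effect architecture
#' as the presence part. The Gaussian marginal likelihood is exact, so
#' the EM trace is monotone.
#'
#' @param levels Augmented level dataset from
#'   [augment_null_expression()] (columns gene, stage, compartment,
#'   level).
#' @param genes Optional character vector fixing the gene order of the
#'   random-effect matrices (default: order of appearance).
#' @param control A [hurdle_control()] object.
#' @return A list of class `level_fit`: fixed fourth-root-scale means
#'   `beta`, covariances, conditional modes, `resid_sd`, log-likelihood
#'   trace, convergence flag.
#' @export
fit_level_model <- function(levels, genes = NULL,
                            control = hurdle_control()) {
  stopifnot(is.data.frame(levels),
            all(c("gene", "stage", "compartment", "level") %in% names(levels)))
  if (is.null(genes)) genes <- unique(levels$gene)
  g <- match(levels$gene, genes)
  if (anyNA(g)) stop("levels contain genes not in `genes`", call. = FALSE)
  s <- match(levels$stage, STAGES)
  comp <- match(levels$compartment, COMPARTMENTS)
  if (anyNA(s) || anyNA(comp))
    stop("unknown stage or compartment in level data", call. = FALSE)
  if (nrow(levels) < 8L)
    stop("fewer observations than fixed effects", call. = FALSE)
  obs <- list(g = g, s = s, comp = comp, y = levels$level^(1 / 4))
  fit <- fit_glmm_part(obs, G = length(genes), family = "gaussian",
                       control = control)
  fit$genes <- genes
  rownames(fit$modes_stage) <- genes
  if (!is.null(fit$modes_cell)) rownames(fit$modes_cell) <- genes
  fit$transformation <- "fourth-root"
  class(fit) <- c("level_fit", "glmm_part")
  fit
}

#' Fit the full two-part hurdle model
#'
#' Bundles the independently estimated presence and level parts (they
#' share no parameters) over the common gene panel.
#'
#' @param det Detection matrix (genes x samples).
#' @param rel Relative-expression matrix, `NA` where undetected.
#' @param design Design table for the columns.
#' @param control A [hurdle_control()] object.
#' @return A list of class `hurdle_fit` with elements `presence`,
#'   `level`, `genes`, `transformation`.
#' @export
fit_hurdle <- function(det, rel, design, control = hurdle_control()) {
  stopifnot(is.matrix(det), is.matrix(rel))
  common <- intersect(rownames(det), rownames(rel))
  if (!length(common))
    stop("no genes shared between detection and level tables",
         call. = FALSE)
  det <- det[common, , drop = FALSE]
  rel <- rel[common, , drop = FALSE]
  presence <- fit_presence_model(det, design, control)
  aug <- augment_null_expression(rel, det, design)
  level <- fit_level_model(aug, genes = common, control)
  structure(list(presence = presence, level = level, genes = common,
                 transformation = "fourth-root"),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Two-part hurdle fit:", length(x$genes), "genes\n")
  cat("  presence part: loglik", format(x$presence$loglik),
      if (x$presence$separated) "(separation; ridge engaged)" else "",
      "\n")
  cat("  level part:    loglik", format(x$level$loglik),
      " resid_sd", format(x$level$resid_sd), "\n")
  invisible(x)
}

# Correlation matrix with undefined entries (zero variance) marked NA.
safe_cor <- function(S) {
  d <- sqrt(diag(S))
  R <- S / tcrossprod(d)
  R[!is.finite(R)] <- NA_real_
  diag(R)[is.finite(diag(R))] <- 1
  R
}

#' Stage correlation report for a hurdle fit
#'
#' Converts the estimated stage covariance of each part to a
#' correlation matrix, and additionally reports the empirical
#' correlations of the per-gene conditional modes — overall and within
#' each compartment (the within-cell-type view adds the compartment
#' mode, constant across stages for a gene, before correlating).
#' Entries whose variance component is zero are reported as `NA`
#' (undefined), never as 0.
#'
#' @param fit A `hurdle_fit` object.
#' @return A list of class `stage_correlation_report`: per part
#'   (`binary`, `level`) the model correlation matrix (`model`), the
#'   empirical mode correlation (`modes`), and per-compartment mode
#'   correlations (`within`).
#' @export
stage_effect_correlations <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  one_part <- function(part) {
    if (part$structure != "additive")
      stop("correlation report requires the additive structure",
           call. = FALSE)
    within <- lapply(setNames(1:2, COMPARTMENTS), function(ci) {
      eff <- part$modes_stage + part$modes_cell[, ci]
      safe_cor(stats::cov(eff))
    })
    list(model = safe_cor(part$Sigma_stage),
         modes = safe_cor(stats::cov(part$modes_stage)),
         within = within)
  }
  structure(list(binary = one_part(fit$presence),
                 level = one_part(fit$level)),
            class = "stage_correlation_report")
}
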