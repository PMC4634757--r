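#' Construct a new observation vector for stage prediction
#'
#' One follicle's worth of panel data: for each gene a binary detected
#' indicator and, where detected, a nonnegative expression level.
#'
#' @param compartment `"O"` or `"GC"`.
#' @param z Named 0/1 vector over genes.
#' @param y Named nonnegative levels; must be present exactly for the
#'   genes with `z = 1`.
#' @return An object of class `obs_vector`.
#' @export
obs_vector <- function(compartment, z, y) {
  if (!compartment %in% COMPARTMENTS)
    stop("compartment must be O or GC", call. = FALSE)
  stopifnot(!is.null(names(z)))
  det_genes <- names(z)[z == 1L]
  if (!setequal(names(y), det_genes))
    stop("levels must be present exactly for detected genes",
         call. = FALSE)
  if (any(y < 0)) stop("levels must be nonnegative", call. = FALSE)
  structure(list(compartment = compartment, z = z, y = y[det_genes]),
            class = "obs_vector")
}

# Per-gene linear predictor of one part for (stage s, compartment c),
# fixed effects plus empirical-Bayes conditional modes.
part_linpred <- function(part, genes, s, ci) {
  gi <- match(genes, part$genes)
  if (part$structure == "additive") {
    part$beta[s, ci] + part$modes_stage[gi, s] + part$modes_cell[gi, ci]
  } else {
    cell <- cell_index(s, ci)
    part$beta[s, ci] + part$modes_stage[gi, cell]
  }
}

posterior_core <- function(fit, obs, prior, use_level) {
  stopifnot(inherits(fit, "hurdle_fit"), inherits(obs, "obs_vector"))
  if (is.null(prior)) prior <- rep(1 / 4, 4L)
  stopifnot(length(prior) == 4L, all(prior >= 0), sum(prior) > 0)
  genes <- names(obs$z)
  known <- genes %in% fit$genes
  if (any(!known)) {
    warning("skipping gene(s) absent from the fitted panel: ",
            paste(genes[!known], collapse = ", "), call. = FALSE)
    genes <- genes[known]
  }
  ci <- match(obs$compartment, COMPARTMENTS)
  z <- obs$z[genes]
  y4 <- obs$y[names(obs$y) %in% genes]^(1 / 4)

  ll <- vapply(1:4, function(s) {
    eta <- part_linpred(fit$presence, genes, s, ci)
    lp <- sum(plogis(eta[z == 1L], log.p = TRUE)) +
      sum(plogis(-eta[z == 0L], log.p = TRUE))
    if (use_level && length(y4)) {
      mu <- part_linpred(fit$level, names(y4), s, ci)
      lp <- lp + sum(dnorm(y4, mu, fit$level$resid_sd, log = TRUE))
    }
    lp
  }, 0)
  lp <- log(prior / sum(prior)) + ll
  m <- max(lp)
  log_evidence <- m + log(sum(exp(lp - m)))
  probs <- exp(lp - log_evidence)
  structure(list(probabilities = setNames(probs, STAGES),
                 prior = prior, log_evidence = log_evidence,
                 compartment = obs$compartment,
                 variant = if (use_level) "full" else "binary"),
            class = "stage_posterior")
}

#' Posterior probability of each follicular stage
#'
#' The predictive equations of the two-part model: for a new
#' observation vector of one compartment, the posterior over stages
#' \{PD, PM, SC, SA\} is proportional to the prior times the Bernoulli
#' likelihood of the detection pattern times, for detected genes, the
#' Gaussian likelihood of the fourth-root level. Per-gene detection
#' probabilities and level means are the empirical-Bayes plug-ins
#' (fixed effects plus conditional modes). Computed in log space and
#' normalized over the four stages.
#'
#' @param fit A `hurdle_fit`.
#' @param obs An [obs_vector()].
#' @param prior Prior over the four stages (default uniform).
#' @return A `stage_posterior`: probabilities (sum to 1), prior,
#'   log-evidence, variant tag.
#' @export
posterior_stage <- function(fit, obs, prior = NULL)
  posterior_core(fit, obs, prior, use_level = TRUE)

#' Posterior stage probabilities from the detection pattern only
#'
#' The degraded predictor that discards the quantitative level and
#' keeps only presence/absence information.
#'
#' @inheritParams posterior_stage
#' @export
posterior_stage_binary_only <- function(fit, obs, prior = NULL)
  posterior_core(fit, obs, prior, use_level = FALSE)

#' @export
print.stage_posterior <- function(x, ...) {
  cat("Stage posterior (", x$variant, " model, compartment ",
      x$compartment, "):\n", sep = "")
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Resample new observation vectors from a stage-compartment cell
#'
#' Generates synthetic observation vectors by drawing, independently
#' for each gene, one replicate's (detected, level) pair uniformly at
#' random from the observed replicates of that gene in the chosen cell.
#' The pair is drawn jointly — a vector never mixes one replicate's
#' detection call with another's level.
#'
#' @param rel,det Relative-expression and detection matrices.
#' @param design Design table for the columns.
#' @param stage,compartment The cell to resample from.
#' @param n Number of vectors (default 100).
#' @param seed Optional seed set before drawing.
#' @return List of `n` [obs_vector()] objects.
#' @export
resample_vectors <- function(rel, det, design, stage, compartment,
                             n = 100L, seed = NULL) {
  design <- validate_design(design)
  stopifnot(identical(colnames(rel), design$sample_id),
            identical(colnames(det), design$sample_id))
  cols <- which(design$stage == stage & design$compartment == compartment)
  if (!length(cols))
    stop("no samples in cell (", stage, ", ", compartment, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(rel)
  G <- length(genes)
  lapply(seq_len(n), function(i) {
    pick <- cols[sample.int(length(cols), G, replace = TRUE)]
    z <- det[cbind(seq_len(G), pick)]
    y <- rel[cbind(seq_len(G), pick)]
    names(z) <- genes
    obs_vector(compartment, z, setNames(y[z == 1L], genes[z == 1L]))
  })
}

#' Evaluate predictive ability on resampled vectors
#'
#' Applies the chosen predictor to every vector of every (stage,
#' compartment) set, and aggregates the posterior panels, the mean
#' posterior assigned to the true stage, and an argmax confusion
#' matrix. Argmax ties are broken toward the earlier stage and counted.
#'
#' @param fit A `hurdle_fit`.
#' @param vector_sets List of sets, each a list with fields `stage`,
#'   `compartment` and `vectors` (a list of [obs_vector()]s).
#' @param variant `"full"` (presence + level) or `"binary"`.
#' @param prior Prior over stages (default uniform).
#' @return A list of class `resample_report`: `summary` (data.frame
#'   with compartment, stage, n, mean_posterior_true, n_ties),
#'   `posteriors` (one n x 4 matrix per set), `confusion` (list per
#'   compartment of 4 x 4 true-by-predicted count matrices).
#' @export
evaluate_predictions <- function(fit, vector_sets,
                                 variant = c("full", "binary"),
                                 prior = NULL) {
  variant <- match.arg(variant)
  predictor <- if (variant == "full") posterior_stage
               else posterior_stage_binary_only
  confusion <- lapply(setNames(COMPARTMENTS, COMPARTMENTS), function(cc)
    matrix(0L, 4L, 4L, dimnames = list(true = STAGES, predicted = STAGES)))
  summary_rows <- list()
  posteriors <- list()
  for (set in vector_sets) {
    n <- length(set$vectors)
    P <- matrix(NA_real_, n, 4L, dimnames = list(NULL, STAGES))
    ties <- 0L
    for (i in seq_len(n)) {
      P[i, ] <- predictor(fit, set$vectors[[i]], prior)$probabilities
      top <- which(P[i, ] == max(P[i, ]))
      if (length(top) > 1L) ties <- ties + 1L
      confusion[[set$compartment]][set$stage, STAGES[top[1L]]] <-
        confusion[[set$compartment]][set$stage, STAGES[top[1L]]] + 1L
    }
    key <- paste(set$stage, set$compartment, sep = ".")
    posteriors[[key]] <- P
    summary_rows[[key]] <- data.frame(
      compartment = set$compartment, stage = set$stage, n = n,
      mean_posterior_true = if (n) mean(P[, set$stage]) else NA_real_,
      n_ties = ties, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 posteriors = posteriors, confusion = confusion,
                 variant = variant),
            class = "resample_report")
}

#' Run the full resampling predictive-ability study
#'
#' For every stage-compartment cell present in the design, draws `n`
#' resampled observation vectors and evaluates the chosen predictor,
#' mirroring the study's 100-resample validation of the biomarker
#' panel.
#'
#' @inheritParams resample_vectors
#' @inheritParams evaluate_predictions
#' @param fit A `hurdle_fit` on the same panel.
#' @param seed Seed governing all resampling draws.
#' @return A `resample_report`.
#' @export
resample_study <- function(fit, rel, det, design, n = 100L, seed = 1L,
                           variant = c("full", "binary"), prior = NULL) {
  design <- validate_design(design)
  variant <- match.arg(variant)
  set.seed(seed)
  lcm <- design[design$compartment != "MT", , drop = FALSE]
  cells <- unique(data.frame(stage = as.character(lcm$stage),
                             compartment = as.character(lcm$compartment),
                             stringsAsFactors = FALSE))
  cells <- cells[order(match(cells$compartment, COMPARTMENTS),
                       match(cells$stage, STAGES)), ]
  sets <- lapply(seq_len(nrow(cells)), function(i) {
    list(stage = cells$stage[i], compartment = cells$compartment[i],
         vectors = resample_vectors(rel, det, design, cells$stage[i],
                                    cells$compartment[i], n))
  })
  evaluate_predictions(fit, sets, variant, prior)
}

#' Strip plot of posterior panels from a resampling study
#'
#' One panel per true stage and compartment, showing the posterior
#' probability assigned to each candidate stage across resampled
#' vectors.
#'
#' @param report A `resample_report`.
#' @return A ggplot object.
#' @export
plot_posterior_panels <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  stopifnot(inherits(report, "resample_report"))
  dfs <- lapply(names(report$posteriors), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    P <- report$posteriors[[key]]
    data.frame(true_stage = factor(parts[1L], STAGES),
               compartment = parts[2L],
               candidate = factor(rep(STAGES, each = nrow(P)), STAGES),
               posterior = as.vector(P))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate,
                                   y = .data$posterior)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.5,
                         alpha = 0.5) +
    ggplot2::facet_grid(compartment ~ true_stage) +
    ggplot2::labs(x = "candidate stage", y = "posterior probability") +
    ggplot2::theme_bw()
}
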