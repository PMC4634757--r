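#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegating to [stats::p.adjust()]), kept as a
#' named operation so selection rules read as the procedure they
#' implement. `NA` p-values propagate as `NA`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

# Normalized group means for fold changes.
norm_group_means <- function(counts, factors, idx) {
  rowMeans(sweep(counts[, idx, drop = FALSE], 2L, factors[idx], "/"))
}

# Ratio with the x/0 -> Inf and 0/0 -> NA conventions used by the
# selection gates.
fc_ratio <- function(num, den) {
  fc <- num / den
  fc[num == 0 & den == 0] <- NA_real_
  fc
}

#' Stage-wise differential expression within one compartment
#'
#' Runs the two DE designs on the samples of one compartment: the
#' global stage test (NB likelihood-ratio of `count ~ stage` against
#' `count ~ 1`, per gene, BH-adjusted across genes) and the exact
#' conditional NB test for every pair of stages, with fold changes as
#' ratios of normalized group means oriented later/earlier stage.
#'
#' @param counts Genes x samples count matrix (all samples; the
#'   compartment's columns are selected internally).
#' @param design Matching design table.
#' @param compartment `"O"` or `"GC"`.
#' @param factors Size factors for all samples (default: median-of-
#'   ratios on the full matrix).
#' @param alpha Per-gene dispersions (default: pooled method-of-moments
#'   estimates on the full matrix).
#' @return A list of class `stage_de`: `compartment`, `glm`
#'   (gene, p_value, padj), `pairwise` (one data.frame per stage pair
#'   `A_B` with mean_A, mean_B, fc = mean_B/mean_A, log2fc, p_value),
#'   `factors`, `alpha`.
#' @export
de_stage_analysis <- function(counts, design, compartment,
                              factors = NULL, alpha = NULL) {
  design <- validate_design(design)
  stopifnot(identical(colnames(counts), design$sample_id))
  if (!compartment %in% COMPARTMENTS)
    stop("compartment must be O or GC", call. = FALSE)
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(alpha)) alpha <- estimate_dispersion(counts, design, factors)

  sel <- design$compartment == compartment
  sub <- counts[, sel, drop = FALSE]
  sub_fac <- factors[sel]
  sub_stage <- droplevels(design$stage[sel])
  genes <- rownames(counts)

  glm_p <- vapply(seq_len(nrow(sub)), function(g)
    nb_glm_lrt(sub[g, ], sub_stage, alpha[g], sub_fac)$p_value, 0)
  glm <- data.frame(gene = genes, p_value = glm_p, padj = bh_adjust(glm_p),
                    stringsAsFactors = FALSE)

  stages_here <- STAGES[STAGES %in% levels(sub_stage)]
  pairs <- utils::combn(stages_here, 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr) {
    iA <- which(sub_stage == pr[1L]); iB <- which(sub_stage == pr[2L])
    mA <- norm_group_means(sub, sub_fac, iA)
    mB <- norm_group_means(sub, sub_fac, iB)
    p <- vapply(seq_len(nrow(sub)), function(g)
      nb_exact_test(sub[g, iA], sub[g, iB], sub_fac[iA], sub_fac[iB],
                    alpha[g]), 0)
    data.frame(gene = genes, mean_A = mA, mean_B = mB,
               fc = fc_ratio(mB, mA), log2fc = log2(fc_ratio(mB, mA)),
               p_value = p, stringsAsFactors = FALSE)
  })
  names(pairwise) <- vapply(pairs, paste, "", collapse = "_")

  structure(list(compartment = compartment, glm = glm, pairwise = pairwise,
                 factors = factors, alpha = alpha),
            class = "stage_de")
}

#' Select stage-regulated genes by the combined filter
#'
#' A gene is kept iff its global stage test is significant at the FDR
#' threshold AND at least one pairwise stage comparison passes both the
#' raw p-value gate and the fold-change gate (ratio above `fc` or below
#' `1/fc` in either direction). Defaults are the study thresholds:
#' FDR < 5%, pairwise p < 1%, fold change > 2.
#'
#' @param de A `stage_de` result from [de_stage_analysis()].
#' @param glm_fdr FDR threshold on the adjusted global test (0.05).
#' @param pairwise_p Raw p threshold on the pairwise exact test (0.01).
#' @param fc Fold-change threshold (> 1; 2 by default).
#' @return data.frame of selected genes with the strongest qualifying
#'   pair, its fold change and direction (`up` if the later stage is
#'   higher).
#' @export
select_stage_de <- function(de, glm_fdr = 0.05, pairwise_p = 0.01, fc = 2) {
  stopifnot(inherits(de, "stage_de"), fc > 1)
  genes <- de$glm$gene
  pass_glm <- !is.na(de$glm$padj) & de$glm$padj < glm_fdr

  best_pair <- rep(NA_character_, length(genes))
  best_fc <- rep(NA_real_, length(genes))
  best_p <- rep(NA_real_, length(genes))
  any_pass <- rep(FALSE, length(genes))
  for (nm in names(de$pairwise)) {
    pw <- de$pairwise[[nm]]
    ok <- !is.na(pw$p_value) & pw$p_value < pairwise_p &
      !is.na(pw$fc) & (pw$fc > fc | pw$fc < 1 / fc)
    better <- ok & (!any_pass | pw$p_value < best_p)
    best_pair[better] <- nm
    best_fc[better] <- pw$fc[better]
    best_p[better] <- pw$p_value[better]
    any_pass <- any_pass | ok
  }
  keep <- pass_glm & any_pass
  data.frame(gene = genes[keep], glm_padj = de$glm$padj[keep],
             pair = best_pair[keep], pair_p = best_p[keep],
             fc = best_fc[keep],
             direction = ifelse(best_fc[keep] > 1, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Select stage- and compartment-specific biomarkers
#'
#' For one target stage-compartment group, tests every gene with the
#' exact conditional NB test of the target samples against all
#' remaining samples pooled as a single group — multi-tissue pools
#' included, so tissue-ubiquitous genes cannot pass. Genes are kept at
#' BH FDR < `fdr` with fold change (target over rest) above the
#' threshold: by convention 3 for granulosa targets and 10 for oocyte
#' targets. A gene silent everywhere except the target group has
#' infinite fold change and passes any threshold; 0/0 is excluded.
#'
#' @param counts Genes x samples count matrix.
#' @param design Matching design table (should include MT pools).
#' @param target_stage,target_compartment The group whose markers are
#'   sought.
#' @param fc_threshold Fold-change gate; default 10 for oocyte targets,
#'   3 for granulosa targets.
#' @param fdr BH FDR threshold (0.05).
#' @param factors,alpha As in [de_stage_analysis()].
#' @return data.frame of selected genes (gene, mean_target, mean_rest,
#'   fc, p_value, padj), ordered by padj.
#' @export
select_biomarkers <- function(counts, design, target_stage,
                              target_compartment, fc_threshold = NULL,
                              fdr = 0.05, factors = NULL, alpha = NULL) {
  design <- validate_design(design)
  stopifnot(identical(colnames(counts), design$sample_id))
  if (is.null(fc_threshold))
    fc_threshold <- if (target_compartment == "O") 10 else 3
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(alpha)) alpha <- estimate_dispersion(counts, design, factors)

  tgt <- which(design$stage == target_stage &
                 design$compartment == target_compartment)
  if (!length(tgt)) stop("target group is empty", call. = FALSE)
  rest <- setdiff(seq_len(nrow(design)), tgt)

  m_t <- norm_group_means(counts, factors, tgt)
  m_r <- norm_group_means(counts, factors, rest)
  p <- vapply(seq_len(nrow(counts)), function(g)
    nb_exact_test(counts[g, tgt], counts[g, rest], factors[tgt],
                  factors[rest], alpha[g]), 0)
  fc <- fc_ratio(m_t, m_r)
  padj <- bh_adjust(p)
  keep <- !is.na(padj) & padj < fdr & !is.na(fc) & fc > fc_threshold
  out <- data.frame(gene = rownames(counts)[keep], mean_target = m_t[keep],
                    mean_rest = m_r[keep], fc = fc[keep], p_value = p[keep],
                    padj = padj[keep], stringsAsFactors = FALSE)
  out[order(out$padj, out$p_value, out$gene), , drop = FALSE]
}

#' Count regulated genes at each consecutive stage transition
#'
#' Summarizes pairwise results at the three consecutive transitions
#' (PD to PM, PM to SC, SC to SA) per compartment: a gene counts as up
#' if its pairwise p is below `pairwise_p` and the later-over-earlier
#' fold change exceeds `fc`, as down if the fold change is below `1/fc`.
#'
#' @param de_list A list of `stage_de` results (one per compartment).
#' @param pairwise_p,fc Gates, defaulting to the study's p < 0.01 and
#'   fold change > 2.
#' @return data.frame with compartment, transition, up, down.
#' @export
transition_summary <- function(de_list, pairwise_p = 0.01, fc = 2) {
  if (inherits(de_list, "stage_de")) de_list <- list(de_list)
  transitions <- c("PD_PM", "PM_SC", "SC_SA")
  rows <- list()
  for (de in de_list) {
    for (tr in transitions) {
      pw <- de$pairwise[[tr]]
      if (is.null(pw)) next
      sig <- !is.na(pw$p_value) & pw$p_value < pairwise_p & !is.na(pw$fc)
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = de$compartment, transition = tr,
        up = sum(sig & pw$fc > fc), down = sum(sig & pw$fc < 1 / fc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
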