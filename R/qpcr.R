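#' Fit PCR amplification efficiency from a serial dilution series
#'
#' Regresses threshold cycle (Ct) on log10 relative input for a serial
#' dilution of a calibrator pool and converts the slope to a per-cycle
#' amplification efficiency `E = 10^(-1/slope)`. A perfectly doubling
#' assay has slope -3.3219 and E = 2.
#'
#' @param dilutions Strictly positive relative input amounts (e.g.
#'   `c(1, 1/3, 1/9, 1/18, 1/36)` for a 1, 1:3, 1:3, 1:2, 1:2 series).
#' @param cts Observed Ct values, same length.
#' @param gene Optional gene label carried through.
#' @return An object of class `efficiency_curve`: list with `gene`,
#'   `dilution_factors`, `ct_values`, `slope` (cycles per log10
#'   dilution), `efficiency`, `r_squared`.
#' @examples
#' fit_efficiency(c(1, 0.1, 0.01), c(20, 23.3219, 26.6439))$efficiency
#' @export
fit_efficiency <- function(dilutions, cts, gene = NA_character_) {
  if (length(dilutions) < 3L || length(cts) != length(dilutions))
    stop("need >= 3 matched (dilution, Ct) points", call. = FALSE)
  if (any(dilutions <= 0)) stop("dilutions must be > 0", call. = FALSE)
  fit <- lm(cts ~ log10(dilutions))
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("non-amplifying dilution series: slope >= 0 (quality failure)",
         call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cts - mean(cts))^2)
  structure(list(gene = gene, dilution_factors = dilutions,
                 ct_values = cts, slope = slope,
                 efficiency = 10^(-1 / slope),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "efficiency_curve")
}

#' Efficiency-corrected relative quantity (Pfaffl)
#'
#' Converts a Ct to a relative quantity against a calibrator Ct with a
#' gene-specific amplification efficiency: `quantity = E^(calibrator -
#' ct)`. Undetected (NA) Cts give an absent (`NA`) quantity; no number
#' is fabricated.
#'
#' @param ct Ct value(s); `NA` marks undetected wells.
#' @param calibrator_ct Calibrator Ct (scalar or matched vector).
#' @param efficiency Amplification efficiency E (> 1).
#' @return Nonnegative relative quantity (vectorized), `NA` where
#'   undetected.
#' @export
pfaffl_quantity <- function(ct, calibrator_ct, efficiency) {
  if (any(efficiency <= 1)) stop("efficiency must exceed 1", call. = FALSE)
  efficiency^(calibrator_ct - ct)
}

#' Invert the Pfaffl relation to a Ct
#'
#' Given a relative quantity and an efficiency, returns the Ct that
#' [pfaffl_quantity()] maps back to that quantity:
#' `ct = calibrator - log(q)/log(E)`. Used to forward-simulate Ct tables
#' from known quantities in round-trip checks and the pipeline.
#'
#' @inheritParams pfaffl_quantity
#' @param quantity Relative quantity (> 0), `NA` for undetected.
#' @export
ct_from_quantity <- function(quantity, calibrator_ct, efficiency) {
  if (any(efficiency <= 1)) stop("efficiency must exceed 1", call. = FALSE)
  calibrator_ct - log(quantity) / log(efficiency)
}

#' Quantify a whole Ct table with per-gene efficiencies
#'
#' Applies [pfaffl_quantity()] row-wise to a genes-by-samples Ct matrix.
#' The calibrator defaults to each gene's mean Ct across its detected
#' samples; alternatively a named sample may serve as calibrator.
#'
#' @param ct Numeric genes x samples matrix, `NA` = undetected.
#' @param efficiencies Named vector of per-gene efficiencies (names must
#'   cover the rows of `ct`), or a single value recycled.
#' @param calibrator Either `"mean"` (per-gene mean detected Ct) or a
#'   sample id present in `colnames(ct)`.
#' @return Relative-expression matrix, `NA` where undetected, with
#'   attribute `normalized = FALSE`.
#' @export
pfaffl_table <- function(ct, efficiencies, calibrator = "mean") {
  stopifnot(is.matrix(ct))
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- setNames(rep(efficiencies, nrow(ct)), rownames(ct))
  if (!all(rownames(ct) %in% names(efficiencies)))
    stop("efficiencies missing for some genes", call. = FALSE)
  E <- efficiencies[rownames(ct)]
  cal <- if (identical(calibrator, "mean")) {
    rowMeans(ct, na.rm = TRUE)
  } else {
    if (!calibrator %in% colnames(ct))
      stop("calibrator sample not found: ", calibrator, call. = FALSE)
    ct[, calibrator]
  }
  rel <- E^(cal - ct)
  dimnames(rel) <- dimnames(ct)
  attr(rel, "normalized") <- FALSE
  rel
}

#' Normalize target quantities by the geometric mean of reference genes
#'
#' Per sample, the normalization factor is the geometric mean of the
#' reference genes' relative quantities; every quantity in the sample
#' (references included) is divided by it. Samples in which any
#' reference is undetected cannot be normalized: they are dropped with a
#' warning and listed in the `excluded_samples` attribute.
#'
#' @param rel Relative-expression matrix (genes x samples).
#' @param reference_genes Character vector of reference gene rows
#'   (typically three, e.g. beta-actin, TMED4 and RPL19 in the ovine
#'   panel).
#' @return Normalized matrix (possibly with fewer columns), attributes
#'   `normalized = TRUE`, `excluded_samples`, `norm_factors`.
#' @export
normalize_by_references <- function(rel, reference_genes) {
  stopifnot(is.matrix(rel))
  missing_ref <- setdiff(reference_genes, rownames(rel))
  if (length(missing_ref))
    stop("reference genes absent from table: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  refs <- rel[reference_genes, , drop = FALSE]
  bad <- colnames(rel)[colSums(is.na(refs) | refs <= 0) > 0L]
  if (length(bad)) {
    warning("excluding sample(s) with undetected reference gene: ",
            paste(bad, collapse = ", "), call. = FALSE)
    rel <- rel[, setdiff(colnames(rel), bad), drop = FALSE]
    refs <- refs[, setdiff(colnames(refs), bad), drop = FALSE]
  }
  nf <- exp(colMeans(log(refs)))
  out <- sweep(rel, 2L, nf, "/")
  attr(out, "normalized") <- TRUE
  attr(out, "excluded_samples") <- bad
  attr(out, "norm_factors") <- nf
  out
}

#' geNorm-style reference gene stability
#'
#' For each candidate reference gene j, the stability measure M_j is the
#' mean over the other candidates k of the standard deviation across
#' samples of `log2(rel_j / rel_k)`; a perfectly co-regulated pair has
#' constant log-ratio and contributes 0. Only samples in which every
#' candidate is detected enter the computation. The exclusion ranking
#' removes the least stable (largest M) gene iteratively, recomputing M
#' among the survivors, until two genes remain.
#'
#' @param rel Relative-expression matrix.
#' @param candidates >= 3 candidate reference gene names.
#' @return List with `M` (named vector over all candidates, computed on
#'   the full candidate set), `exclusion_order` (genes in removal order,
#'   least stable first) and `most_stable` (the final pair).
#' @export
genorm_stability <- function(rel, candidates) {
  stopifnot(is.matrix(rel))
  if (length(candidates) < 3L)
    stop("need >= 3 candidate reference genes", call. = FALSE)
  if (!all(candidates %in% rownames(rel)))
    stop("candidates absent from expression table", call. = FALSE)
  sub <- rel[candidates, , drop = FALSE]
  ok <- colSums(is.na(sub) | sub <= 0) == 0L
  if (sum(ok) < 2L)
    stop("need >= 2 samples with all candidates detected", call. = FALSE)
  lg <- log2(sub[, ok, drop = FALSE])

  m_values <- function(genes) {
    vapply(genes, function(j) {
      others <- setdiff(genes, j)
      mean(vapply(others, function(k) sd(lg[j, ] - lg[k, ]), 0))
    }, 0)
  }

  M_full <- m_values(candidates)
  remaining <- candidates
  excl <- character(0)
  while (length(remaining) > 2L) {
    M <- m_values(remaining)
    worst <- names(which.max(M))
    excl <- c(excl, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(M = M_full, exclusion_order = excl, most_stable = remaining)
}

#' Call detection from a Ct table
#'
#' A well is called detected (z = 1) iff its Ct is numeric, below the
#' cycle cutoff, and — when a matched negative control exists for the
#' gene — at least `margin` cycles below the control's Ct. The cutoff
#' and margin default to 40 cycles and 3 cycles, standard qPCR practice;
#' the calling rule is configurable because assays differ.
#'
#' @param ct Genes x samples Ct matrix, `NA` = undetected.
#' @param cycle_cutoff Maximum Ct considered detected (default 40).
#' @param negative_controls Optional named per-gene vector of negative
#'   control Cts (`NA` entries mean the control itself did not amplify
#'   and impose no constraint).
#' @param margin Minimum separation (cycles) from the negative control.
#' @return Integer 0/1 matrix shaped like `ct`.
#' @export
call_detection <- function(ct, cycle_cutoff = 40, negative_controls = NULL,
                           margin = 3) {
  stopifnot(is.matrix(ct))
  z <- !is.na(ct) & ct < cycle_cutoff
  if (!is.null(negative_controls)) {
    ctrl <- negative_controls[rownames(ct)]
    has_ctrl <- !is.na(ctrl)
    if (any(has_ctrl)) {
      lim <- matrix(ctrl - margin, nrow(ct), ncol(ct))
      z <- z & (is.na(lim) | ct <= lim)
    }
  }
  z[is.na(z)] <- FALSE
  storage.mode(z) <- "integer"
  dimnames(z) <- dimnames(ct)
  z
}
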