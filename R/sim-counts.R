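#' Parameters for the negative-binomial count simulator
#'
#' Describes a synthetic RNA-seq experiment with group-specific
#' negative-binomial counts, a planted fraction of differentially
#' expressed genes, and optionally a set of group-specific marker genes
#' used to exercise biomarker selection.
#'
#' The NB parameterization is `Var = mu + alpha * mu^2` (the convention
#' of the count-based DE packages), so `dispersion = 0` is the Poisson
#' limit.
#'
#' @param n_genes Number of genes.
#' @param baseline_mean Expected count of a non-DE gene in every group.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param de_fraction Fraction of genes carrying a planted stage effect.
#' @param log2_effect Absolute log2 fold change planted in DE genes.
#' @param seed Integer seed; identical parameters + seed give identical
#'   output.
#' @param markers Optional `data.frame` with columns `stage`,
#'   `compartment`, `n`, `fold`: plants `n` genes whose mean is
#'   `baseline_mean * fold` in that single stage-compartment group and
#'   `baseline_mean` everywhere else (including MT pools).
#' @return An object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 2000L, baseline_mean = 100,
                             dispersion = 0.2, de_fraction = 0.05,
                             log2_effect = 2, seed = 1L,
                             markers = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers),
              all(c("stage", "compartment", "n", "fold") %in% names(markers)))
    if (any(markers$fold <= 0) || any(markers$n < 0))
      stop("marker folds must be > 0 and counts >= 0", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion, de_fraction = de_fraction,
                 log2_effect = log2_effect, seed = as.integer(seed),
                 markers = markers),
            class = "count_sim_params")
}

# Expected-count matrix (genes x samples) implied by params + truth.
count_sim_means <- function(design, params, truth) {
  n_genes <- params$n_genes
  mu <- matrix(params$baseline_mean, n_genes, nrow(design),
               dimnames = list(truth$gene, design$sample_id))
  de <- which(truth$is_de)
  stage_idx <- match(as.character(design$stage), STAGES)  # NA for MT
  for (g in de) {
    onset <- match(truth$onset_stage[g], STAGES)
    cols <- which(as.character(design$compartment) == truth$de_compartment[g] &
                    !is.na(stage_idx) & stage_idx >= onset)
    mu[g, cols] <- params$baseline_mean *
      2^(truth$direction[g] * params$log2_effect)
  }
  mk <- which(!is.na(truth$marker_stage))
  for (g in mk) {
    cols <- which(as.character(design$stage) == truth$marker_stage[g] &
                    as.character(design$compartment) == truth$marker_compartment[g])
    mu[g, cols] <- params$baseline_mean * truth$marker_fold[g]
  }
  mu
}

#' Simulate a stage-by-compartment count matrix with known truth
#'
#' Draws nonnegative integer counts gene-by-sample from a negative
#' binomial with group-specific means. A planted fraction of genes
#' carries a signed log2 effect that switches on at a randomly chosen
#' stage (PM, SC or SA) in one compartment and persists through later
#' stages, so consecutive-stage transitions accumulate the way staged
#' expression programmes do. Multi-tissue samples are simulated from the
#' baseline with no stage effects. Optional marker genes are elevated in
#' exactly one stage-compartment group.
#'
#' @param design A design table from [generate_design()].
#' @param params A [count_sim_params()] object.
#' @param noiseless If `TRUE`, return the expected-count matrix instead
#'   of drawing counts (the simulator's linear predictors).
#' @return A list of class `count_sim` with elements `counts` (integer
#'   matrix, genes x samples), `mu` (expected counts), `truth` (per-gene
#'   DE flag, affected compartment, onset stage, signed effect, marker
#'   annotation), `design`, `params`.
#' @export
simulate_counts <- function(design, params, noiseless = FALSE) {
  design <- validate_design(design)
  if (nrow(design) == 0L) stop("design is empty", call. = FALSE)
  stopifnot(inherits(params, "count_sim_params"))
  set.seed(params$seed)
  n_genes <- params$n_genes
  genes <- sprintf("gene_%04d", seq_len(n_genes))

  truth <- data.frame(gene = genes, is_de = FALSE,
                      de_compartment = NA_character_,
                      onset_stage = NA_character_, direction = NA_integer_,
                      log2_effect = NA_real_, marker_stage = NA_character_,
                      marker_compartment = NA_character_,
                      marker_fold = NA_real_, stringsAsFactors = FALSE)

  n_marker <- if (is.null(params$markers)) 0L else sum(params$markers$n)
  n_de <- round(params$de_fraction * n_genes)
  if (n_de + n_marker > n_genes)
    stop("more planted genes than genes available", call. = FALSE)

  avail <- seq_len(n_genes)
  if (n_de > 0L) {
    de_idx <- sort(sample(avail, n_de))
    avail <- setdiff(avail, de_idx)
    truth$is_de[de_idx] <- TRUE
    truth$de_compartment[de_idx] <- sample(COMPARTMENTS, n_de, replace = TRUE)
    truth$onset_stage[de_idx] <- sample(STAGES[-1L], n_de, replace = TRUE)
    truth$direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    truth$log2_effect[de_idx] <- params$log2_effect
  }
  if (n_marker > 0L) {
    for (i in seq_len(nrow(params$markers))) {
      mk <- params$markers[i, ]
      if (mk$n == 0) next
      idx <- sort(sample(avail, mk$n))
      avail <- setdiff(avail, idx)
      truth$marker_stage[idx] <- as.character(mk$stage)
      truth$marker_compartment[idx] <- as.character(mk$compartment)
      truth$marker_fold[idx] <- mk$fold
    }
  }

  mu <- count_sim_means(design, params, truth)
  if (noiseless) {
    return(structure(list(counts = NULL, mu = mu, truth = truth,
                          design = design, params = params),
                     class = "count_sim"))
  }
  alpha <- params$dispersion
  counts <- if (alpha <= 1e-12) {
    matrix(rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), size = 1 / alpha, mu = mu), nrow(mu), ncol(mu))
  }
  dimnames(counts) <- dimnames(mu)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, mu = mu, truth = truth, design = design,
                 params = params),
            class = "count_sim")
}
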