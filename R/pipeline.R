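#' Default pipeline configuration
#'
#' The study thresholds: stage-regulation selection at global FDR <
#' 0.05, pairwise p < 0.01 and fold change > 2; biomarker selection at
#' FDR < 0.05 with fold change > 3 (granulosa) / > 10 (oocyte);
#' detection cutoff 40 cycles; 100 resampled vectors per stage.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_genes = 500L, baseline_mean = 100, dispersion = 0.2,
    de_fraction = 0.05, log2_effect = 2,
    panel_genes = 24L,
    glm_fdr = 0.05, pairwise_p = 0.01, fc = 2,
    biomarker_fdr = 0.05, fc_gc = 3, fc_oocyte = 10,
    detection_cutoff = 40, control_margin = 3,
    reference_genes = c("ACTB", "TMED4", "RPL19"),
    resample_n = 100L, predictor = "full",
    shrink_dispersion = TRUE, dispersion_prior_df = 50,
    efficiency = 1.9
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for missing keys, rejects invalid values, and keeps
#' (with a warning) unknown keys so they appear in the run manifest.
#' All errors are aggregated into one message.
#'
#' @param config Named list of overrides (possibly empty).
#' @return Normalized config list with attribute `unknown_keys`.
#' @export
validate_config <- function(config = list()) {
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) preserved in manifest: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- modifyList(defaults, config)

  errs <- character(0)
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a number")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(cfg$glm_fdr > 0 && cfg$glm_fdr <= 1, "glm_fdr must be in (0, 1]")
  chk(cfg$pairwise_p > 0 && cfg$pairwise_p <= 1,
      "pairwise_p must be in (0, 1]")
  chk(cfg$fc > 1, "fc must exceed 1")
  chk(cfg$biomarker_fdr > 0 && cfg$biomarker_fdr <= 1,
      "biomarker_fdr must be in (0, 1]")
  chk(cfg$fc_gc > 0, "fc_gc must be > 0")
  chk(cfg$fc_oocyte > 0, "fc_oocyte must be > 0")
  chk(cfg$resample_n >= 0, "resample_n must be >= 0")
  chk(cfg$predictor %in% c("full", "binary"),
      "predictor must be 'full' or 'binary'")
  chk(cfg$detection_cutoff > 0, "detection_cutoff must be > 0")
  chk(cfg$efficiency > 1, "efficiency must exceed 1")
  chk(cfg$dispersion_prior_df > 0, "dispersion_prior_df must be > 0")
  if (length(errs))
    stop("invalid configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  attr(cfg, "unknown_keys") <- unknown
  cfg
}

#' Run the whole synthetic analysis pipeline
#'
#' Executes the stages in dependency order on synthetic data shaped
#' like the study: simulate (design, counts, biomarker panel), qpcr
#' (Ct round trip: relative quantities to Ct and back through
#' efficiency-corrected quantification), de (global + pairwise stage
#' tests, combined selection, transition summary per compartment),
#' biomarkers (group-specific selection for every stage-compartment
#' cell), fit (two-part hurdle model), predict (resampling study).
#' Every table is written as TSV under `out_dir`, and a YAML manifest
#' records the config, seed, package version and the files produced.
#' Rerunning with an identical config and seed reproduces identical
#' artifacts.
#'
#' @param config Configuration list (see [validate_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("follrun")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  manifest <- list(config = cfg[order(names(cfg))],
                   unknown_keys = attr(cfg, "unknown_keys"),
                   package_version = as.character(utils::packageVersion("follsig")),
                   stages = character(0), files = character(0))
  add_file <- function(p) manifest$files <<- c(manifest$files, basename(p))

  # -- simulate ------------------------------------------------------
  design <- generate_design()
  markers <- data.frame(stage = rep(STAGES, 2L),
                        compartment = rep(COMPARTMENTS, each = 4L),
                        n = 2L, fold = 50, stringsAsFactors = FALSE)
  csim <- simulate_counts(design, count_sim_params(
    n_genes = cfg$n_genes, baseline_mean = cfg$baseline_mean,
    dispersion = cfg$dispersion, de_fraction = cfg$de_fraction,
    log2_effect = cfg$log2_effect, seed = cfg$seed, markers = markers))
  hsim <- simulate_hurdle_panel(design, hurdle_sim_params(
    n_genes = cfg$panel_genes, seed = cfg$seed + 1L))
  write_design_tsv(design, path("design.tsv")); add_file(path("design.tsv"))
  write_matrix_tsv(csim$counts, path("counts.tsv"))
  add_file(path("counts.tsv"))
  write_tsv(csim$truth, path("counts_truth.tsv"))
  add_file(path("counts_truth.tsv"))
  manifest$stages <- c(manifest$stages, "simulate")

  # -- qpcr: quantities -> Ct -> efficiency-corrected quantities -----
  E <- cfg$efficiency
  cal_ct <- 25
  ct <- ct_from_quantity(hsim$rel, cal_ct, E)
  write_ct_tsv(ct, path("ct.tsv")); add_file(path("ct.tsv"))
  dil <- c(1, 1 / 3, 1 / 9, 1 / 18, 1 / 36)
  eff <- fit_efficiency(dil, cal_ct - log(dil) / log(E))
  det <- call_detection(ct, cfg$detection_cutoff,
                        margin = cfg$control_margin)
  det[is.na(ct)] <- 0L
  rel <- pfaffl_table(ct, eff$efficiency)
  rel[det == 0L] <- NA_real_
  write_ct_tsv(rel, path("rel_expr.tsv")); add_file(path("rel_expr.tsv"))
  manifest$stages <- c(manifest$stages, "qpcr")
  manifest$efficiency <- eff$efficiency

  # -- de ------------------------------------------------------------
  factors <- size_factors(csim$counts)
  alpha <- estimate_dispersion(csim$counts, design, factors,
                               shrink = isTRUE(cfg$shrink_dispersion),
                               prior_df = cfg$dispersion_prior_df)
  de_list <- lapply(COMPARTMENTS, function(cc)
    de_stage_analysis(csim$counts, design, cc, factors, alpha))
  names(de_list) <- COMPARTMENTS
  for (cc in COMPARTMENTS) {
    sel <- select_stage_de(de_list[[cc]], cfg$glm_fdr, cfg$pairwise_p,
                           cfg$fc)
    write_tsv(sel, path(sprintf("de_selected_%s.tsv", cc)))
    add_file(path(sprintf("de_selected_%s.tsv", cc)))
  }
  ts <- transition_summary(de_list, cfg$pairwise_p, cfg$fc)
  write_tsv(ts, path("transition_summary.tsv"))
  add_file(path("transition_summary.tsv"))
  manifest$stages <- c(manifest$stages, "de")

  # -- biomarkers ----------------------------------------------------
  bm <- list()
  for (cc in COMPARTMENTS) {
    for (st in STAGES) {
      thr <- if (cc == "O") cfg$fc_oocyte else cfg$fc_gc
      b <- select_biomarkers(csim$counts, design, st, cc, thr,
                             cfg$biomarker_fdr, factors, alpha)
      if (nrow(b)) b <- cbind(stage = st, compartment = cc, b)
      bm[[paste(st, cc)]] <- b
    }
  }
  bm_keep <- bm[vapply(bm, nrow, 0L) > 0L]
  bm_all <- if (length(bm_keep))
    do.call(rbind, c(bm_keep, make.row.names = FALSE)) else NULL
  if (is.null(bm_all))
    bm_all <- data.frame(stage = character(0), compartment = character(0),
                         gene = character(0))
  write_tsv(bm_all, path("biomarkers.tsv")); add_file(path("biomarkers.tsv"))
  manifest$stages <- c(manifest$stages, "biomarkers")

  # -- fit -----------------------------------------------------------
  fit <- fit_hurdle(det, rel, hsim$design)
  write_hurdle_fit(fit, path("hurdle_fit.yaml"))
  add_file(path("hurdle_fit.yaml"))
  manifest$stages <- c(manifest$stages, "fit")

  # -- predict -------------------------------------------------------
  report <- resample_study(fit, rel, det, hsim$design,
                           n = cfg$resample_n, seed = cfg$seed + 2L,
                           variant = cfg$predictor)
  write_tsv(report$summary, path("prediction_summary.tsv"))
  add_file(path("prediction_summary.tsv"))
  conf <- do.call(rbind, lapply(COMPARTMENTS, function(cc) {
    data.frame(compartment = cc, true_stage = rep(STAGES, each = 4L),
               predicted_stage = rep(STAGES, 4L),
               n = as.vector(t(report$confusion[[cc]])),
               stringsAsFactors = FALSE)
  }))
  write_tsv(conf, path("confusion.tsv")); add_file(path("confusion.tsv"))
  manifest$stages <- c(manifest$stages, "predict")

  manifest$thresholds <- list(
    glm_fdr = cfg$glm_fdr, pairwise_p = cfg$pairwise_p, fc = cfg$fc,
    biomarker_fdr = cfg$biomarker_fdr, fc_gc = cfg$fc_gc,
    fc_oocyte = cfg$fc_oocyte, detection_cutoff = cfg$detection_cutoff,
    resample_n = cfg$resample_n)
  yaml::write_yaml(manifest, path("manifest.yaml"))

  invisible(list(design = design, counts = csim, panel = hsim,
                 de = de_list, transition = ts, biomarkers = bm_all,
                 fit = fit, report = report, manifest = manifest,
                 out_dir = out_dir))
}
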