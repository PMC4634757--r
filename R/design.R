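#' Generate the stage-by-compartment sample design
#'
#' Builds the factorial backbone of the experiment: every combination of
#' follicular stage (PD, PM, SC, SA) and compartment (oocyte O, granulosa
#' GC) with a fixed number of biological replicates, plus optional
#' multi-tissue (MT) pool samples used as a specificity background.
#' The default layout reproduces the 31-sample laser-capture design:
#' 3 replicates for the primordial oocyte group, 4 for the seven other
#' stage-compartment groups, and 3 MT pools.
#'
#' @param n_rep_default Replicates per stage-compartment group (default 4).
#' @param pdo_rep Replicates for the (PD, O) group, which is harder to
#'   capture (default 3).
#' @param n_mt Number of multi-tissue pool samples (default 3). May be 0,
#'   in which case no MT samples are emitted.
#' @return A `data.frame` with columns `sample_id`, `compartment`
#'   (factor: O, GC, MT), `stage` (factor: PD, PM, SC, SA, NONE) and
#'   `replicate` (integer), in deterministic order (compartment, then
#'   stage, then replicate; MT last).
#' @examples
#' d <- generate_design()
#' nrow(d)  # 31
#' table(d$compartment, d$stage)
#' @export
generate_design <- function(n_rep_default = 4L, pdo_rep = 3L, n_mt = 3L) {
  if (length(n_rep_default) != 1L || is.na(n_rep_default) || n_rep_default < 1)
    stop("`n_rep_default` must be a single integer >= 1", call. = FALSE)
  if (length(pdo_rep) != 1L || is.na(pdo_rep) || pdo_rep < 1)
    stop("`pdo_rep` must be a single integer >= 1", call. = FALSE)
  if (length(n_mt) != 1L || is.na(n_mt) || n_mt < 0)
    stop("`n_mt` must be a single integer >= 0", call. = FALSE)
  n_rep_default <- as.integer(n_rep_default)
  pdo_rep <- as.integer(pdo_rep)
  n_mt <- as.integer(n_mt)

  rows <- list()
  for (comp in COMPARTMENTS) {
    for (st in STAGES) {
      n <- if (comp == "O" && st == "PD") pdo_rep else n_rep_default
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s%s_%d", st, comp, seq_len(n)),
        compartment = comp, stage = st, replicate = seq_len(n),
        stringsAsFactors = FALSE)
    }
  }
  if (n_mt > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("MT_%d", seq_len(n_mt)),
      compartment = "MT", stage = "NONE", replicate = seq_len(n_mt),
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$compartment <- factor(design$compartment, c(COMPARTMENTS, "MT"))
  design$stage <- factor(design$stage, c(STAGES, "NONE"))
  rownames(design) <- NULL
  validate_design(design)
}

#' Validate a sample design table
#'
#' Checks the invariants of a design table: unique sample ids, stage NONE
#' if and only if compartment MT, and factor levels drawn from the known
#' stage and compartment sets.
#'
#' @param design A data.frame with columns `sample_id`, `compartment`,
#'   `stage`, `replicate`.
#' @return The design, invisibly coerced to canonical factor levels.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "compartment", "stage", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("sample_ids must be unique", call. = FALSE)
  design$compartment <- factor(as.character(design$compartment),
                               c(COMPARTMENTS, "MT"))
  design$stage <- factor(as.character(design$stage), c(STAGES, "NONE"))
  if (anyNA(design$compartment) || anyNA(design$stage))
    stop("unknown compartment or stage label in design", call. = FALSE)
  is_mt <- design$compartment == "MT"
  if (any(xor(is_mt, design$stage == "NONE")))
    stop("stage must be NONE exactly for MT samples", call. = FALSE)
  design
}

# Samples of one stage-by-compartment cell, in design order.
design_cell <- function(design, stage, compartment) {
  design[design$stage == stage & design$compartment == compartment, ,
         drop = FALSE]
}
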