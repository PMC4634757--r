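# Doubles are serialized with 17 significant digits so every table
# round-trips losslessly through the readers.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
  out
}

#' Write a data frame as TSV
#'
#' Tab-separated, no quoting, no row names; numeric columns serialized
#' at full precision so reading the file back reproduces the values
#' bit-for-bit.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a genes-by-samples matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in columns with the
#' sample ids as header.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene
  mat
}

#' Write / read a sample design table
#' @param design Design data.frame.
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  df <- data.frame(sample_id = design$sample_id,
                   compartment = as.character(design$compartment),
                   stage = as.character(design$stage),
                   replicate = design$replicate, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) validate_design(read_tsv(path))

#' Write / read a long-format Ct table
#'
#' Columns `gene`, `sample_id`, `ct`; undetected wells are `NA`.
#'
#' @param ct Genes x samples Ct matrix.
#' @param path File path.
#' @export
write_ct_tsv <- function(ct, path) {
  df <- data.frame(gene = rep(rownames(ct), times = ncol(ct)),
                   sample_id = rep(colnames(ct), each = nrow(ct)),
                   ct = as.vector(ct), stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  df <- read_tsv(path)
  genes <- unique(df$gene); samples <- unique(df$sample_id)
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(df$gene, genes), match(df$sample_id, samples))] <- df$ct
  mat
}

#' Serialize a fitted hurdle model to YAML
#'
#' All parameters, covariances, conditional modes and convergence
#' metadata are written to a structured text file; [read_hurdle_fit()]
#' reproduces a fit whose predictions match bit-for-bit.
#'
#' @param fit A `hurdle_fit`.
#' @param path Output YAML path.
#' @export
write_hurdle_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hurdle_fit"))
  # doubles go through %.17g strings so the reload is bit-for-bit
  part_out <- function(p) {
    list(beta = fmt_num(as.vector(p$beta)),
         se_beta = fmt_num(as.vector(p$se_beta)),
         Sigma_stage = fmt_num(as.vector(p$Sigma_stage)),
         Sigma_stage_dim = nrow(p$Sigma_stage),
         Sigma_cell = if (!is.null(p$Sigma_cell))
           fmt_num(as.vector(p$Sigma_cell)),
         modes_stage = fmt_num(as.vector(p$modes_stage)),
         modes_cell = if (!is.null(p$modes_cell))
           fmt_num(as.vector(p$modes_cell)),
         resid_sd = fmt_num(p$resid_sd), loglik = fmt_num(p$loglik),
         converged = p$converged, separated = p$separated,
         ridge = fmt_num(p$ridge), structure = p$structure,
         family = p$family, n_obs = p$n_obs, n_genes = p$n_genes)
  }
  obj <- list(genes = fit$genes, transformation = fit$transformation,
              presence = part_out(fit$presence),
              level = part_out(fit$level))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_hurdle_fit
#' @export
read_hurdle_fit <- function(path) {
  obj <- yaml::read_yaml(path)
  genes <- obj$genes
  G <- length(genes)
  part_in <- function(p, family) {
    q <- p$Sigma_stage_dim
    num <- function(x) {
      if (is.null(x)) return(NULL)
      x[x == "NA"] <- NA
      as.numeric(x)
    }
    stage_names <- if (q == 4L) STAGES
                   else as.vector(outer(STAGES, COMPARTMENTS, paste0))
    out <- list(
      beta = matrix(num(p$beta), 4L, 2L,
                    dimnames = list(STAGES, COMPARTMENTS)),
      se_beta = matrix(num(p$se_beta), 4L, 2L,
                       dimnames = list(STAGES, COMPARTMENTS)),
      Sigma_stage = matrix(num(p$Sigma_stage), q, q,
                           dimnames = list(stage_names, stage_names)),
      Sigma_cell = if (!is.null(p$Sigma_cell))
        matrix(num(p$Sigma_cell), 2L, 2L,
               dimnames = list(COMPARTMENTS, COMPARTMENTS)),
      modes_stage = matrix(num(p$modes_stage), G, q,
                           dimnames = list(genes, stage_names)),
      modes_cell = if (!is.null(p$modes_cell))
        matrix(num(p$modes_cell), G, 2L,
               dimnames = list(genes, COMPARTMENTS)),
      resid_sd = if (is.null(p$resid_sd)) NA_real_ else num(p$resid_sd),
      loglik = num(p$loglik), converged = p$converged,
      separated = p$separated, ridge = num(p$ridge),
      structure = p$structure, family = p$family,
      n_obs = p$n_obs, n_genes = p$n_genes, genes = genes)
    class(out) <- c(if (family == "binomial") "presence_fit"
                    else "level_fit", "glmm_part")
    out
  }
  structure(list(presence = part_in(obj$presence, "binomial"),
                 level = part_in(obj$level, "gaussian"),
                 genes = genes, transformation = obj$transformation),
            class = "hurdle_fit")
}
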