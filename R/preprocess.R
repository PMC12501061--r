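#' Drop transcripts with too many zero values
#'
#' Removes gene rows whose fraction of zero FPKM values is at or above
#' `max_zero_frac` (the >= 50% missingness rule by default). Row order of
#' survivors is preserved.
#'
#' @param expr raw-scale [expression_matrix()].
#' @param max_zero_frac inclusive zero-fraction threshold (default 0.5).
#' @return filtered [expression_matrix()].
#' @export
filter_missing_transcripts <- function(expr, max_zero_frac = 0.5) {
  if (expr_scale(expr) != "raw")
    stop("zero filtering applies to raw-scale expression")
  zf <- rowMeans(unclass(expr) == 0)
  keep <- zf < max_zero_frac
  if (!any(keep)) stop("no transcripts survive the zero-fraction filter")
  expr_subset(expr, which(keep))
}

#' Log2-transform raw expression
#'
#' @param expr raw-scale [expression_matrix()].
#' @param pseudocount added before the log (default 1, so zeros map to 0).
#' @return log2-scale [expression_matrix()].
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) != "raw") stop("log2_transform expects raw scale")
  if (any(unclass(expr) < 0)) stop("negative values in raw expression")
  expression_matrix(log2(unclass(expr) + pseudocount), "log2")
}

#' Remove outlier samples by standardized connectivity
#'
#' Sample connectivity is the row sum of the inter-sample Pearson correlation
#' matrix (self-correlation excluded), computed on log2 expression. Samples
#' whose standardized connectivity exceeds `z_thresh` in absolute value (or
#' only above, with `upper_only`) are removed in a single pass.
#'
#' @param expr log2-scale [expression_matrix()], >= 4 samples.
#' @param z_thresh standardized-connectivity threshold (default 3).
#' @param upper_only remove only samples above the mean (literal one-sided
#'   reading); default FALSE uses |z|.
#' @return list with `expr` (filtered matrix) and `removed` (sample IDs).
#' @export
remove_outlier_samples <- function(expr, z_thresh = 3, upper_only = FALSE) {
  if (expr_scale(expr) != "log2")
    stop("outlier removal expects log2-scale expression")
  if (ncol(expr) < 4) stop("need >= 4 samples")
  cc <- stats::cor(unclass(expr))
  k <- rowSums(cc) - 1
  if (stats::sd(k) == 0) {
    warning("zero variance in sample connectivity; no outliers removed")
    return(list(expr = expr, removed = character(0)))
  }
  z <- (k - mean(k)) / stats::sd(k)
  out <- if (upper_only) z > z_thresh else abs(z) > z_thresh
  list(expr = expr_subset(expr, j = which(!out)),
       removed = colnames(expr)[out])
}

#' Drop samples with incomplete clinical annotation and align tables
#'
#' Removes samples missing stage, age, sex or T-stage, drops samples present
#' in only one of the two tables, and returns both restricted to the shared
#' samples in expression column order.
#'
#' @param expr an [expression_matrix()].
#' @param clinical a [clinical_table()].
#' @return list with aligned `expr` and `clinical`.
#' @export
clean_clinical_samples <- function(expr, clinical) {
  complete <- !is.na(clinical$stage) & !is.na(clinical$age) &
    !is.na(clinical$sex) & !is.na(clinical$t_stage)
  keep_ids <- intersect(colnames(expr), clinical$sample_id[complete])
  if (length(keep_ids) == 0)
    stop("no samples shared between expression and complete clinical records")
  cl <- clinical[match(keep_ids, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  class(cl) <- c("clinical_table", "data.frame")
  list(expr = expr_subset(expr, j = keep_ids), clinical = cl)
}

#' Regress covariates out of expression
#'
#' Per gene, ordinary least squares of log2 expression on the given clinical
#' covariates; returns residuals plus the gene mean, so per-gene means (and
#' the log2 scale tag) are preserved. Constant covariates are dropped with a
#' warning.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param clinical aligned [clinical_table()].
#' @param covariates column names of `clinical` to regress out.
#' @return adjusted log2 [expression_matrix()].
#' @export
regress_covariates <- function(expr, clinical, covariates = c("age", "sex")) {
  if (expr_scale(expr) != "log2")
    stop("covariate regression expects log2-scale expression")
  if (!identical(colnames(expr), clinical$sample_id))
    stop("expression and clinical samples are not aligned")
  keep <- character(0)
  for (cv in covariates) {
    v <- clinical[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (length(unique(v[!is.na(v)])) < 2)
      warning("dropping constant covariate: ", cv)
    else keep <- c(keep, cv)
  }
  if (length(keep) == 0) return(expr)
  mm <- stats::model.matrix(
    stats::reformulate(keep),
    data = as.data.frame(clinical[, keep, drop = FALSE]))
  qr_x <- qr(mm)
  res <- t(qr.resid(qr_x, t(unclass(expr))))
  expression_matrix(res + rowMeans(unclass(expr)), "log2")
}

#' Encode clinical traits as a numeric matrix
#'
#' Emits the numeric trait columns used for module-trait correlation: per-stage
#' binary indicators, the 3/4-collapsed stage codes (stage 3 and 4 pooled as
#' 3.5), N- and T-stage indicators, metastasis, overall survival event and
#' time, age and sex (female = 1). Traits not derivable from available columns
#' come back as NA columns.
#'
#' @param clinical a [clinical_table()].
#' @return numeric matrix, samples x traits, rownames = sample IDs.
#' @export
encode_traits <- function(clinical) {
  s <- clinical$stage; t_ <- clinical$t_stage; n_ <- clinical$n_stage
  bin <- function(x) as.numeric(x)
  traits <- cbind(
    `Pathologic stage`       = as.numeric(s),
    `Pathologic stage 3.5`   = ifelse(is.na(s), NA, ifelse(s >= 3, 3.5, s)),
    `Stage 1`                = bin(s == 1),
    `Stage 2`                = bin(s == 2),
    `Stage 3`                = bin(s == 3),
    `Stage 4`                = bin(s == 4),
    `Stage 3.5`              = bin(s >= 3),
    `Pathologic T`           = as.numeric(t_),
    `Stage T1`               = bin(t_ == 1),
    `Stage T2`               = bin(t_ == 2),
    `Stage T3`               = bin(t_ == 3),
    `Stage T4`               = bin(t_ == 4),
    `Stage T3.5`             = bin(t_ >= 3),
    `Pathologic N`           = as.numeric(n_),
    `Stage N0`               = bin(n_ == 0),
    `Stage N1`               = bin(n_ == 1),
    `Stage N2`               = bin(n_ == 2),
    `Pathologic M`           = as.numeric(clinical$m_stage),
    `OS`                     = as.numeric(clinical$os_event),
    `OS.time`                = as.numeric(clinical$os_time_days),
    `Age`                    = as.numeric(clinical$age),
    `Sex`                    = bin(clinical$sex == "female"))
  rownames(traits) <- clinical$sample_id
  traits
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running the cleaning steps in their canonical order:
#' zero-fraction filter, clinical completeness/alignment, log2 transform,
#' connectivity outlier removal, covariate regression.
#'
#' @param expr raw [expression_matrix()].
#' @param clinical [clinical_table()].
#' @param max_zero_frac,z_thresh,covariates,pseudocount stage parameters.
#' @return list with `expr` (log2, adjusted), `clinical` (aligned), `traits`
#'   (encoded trait matrix) and `log` (per-step removal counts).
#' @export
preprocess_pipeline <- function(expr, clinical, max_zero_frac = 0.5,
                                z_thresh = 3, covariates = c("age", "sex"),
                                pseudocount = 1) {
  log <- list(genes_in = nrow(expr), samples_in = ncol(expr))
  expr <- filter_missing_transcripts(expr, max_zero_frac)
  log$genes_removed_zero_filter <- log$genes_in - nrow(expr)
  al <- clean_clinical_samples(expr, clinical)
  log$samples_removed_clinical <- log$samples_in - ncol(al$expr)
  lg <- log2_transform(al$expr, pseudocount)
  ro <- remove_outlier_samples(lg, z_thresh)
  log$samples_removed_outlier <- length(ro$removed)
  al2 <- list(expr = ro$expr,
              clinical = al$clinical[match(colnames(ro$expr),
                                           al$clinical$sample_id), ,
                                     drop = FALSE])
  rownames(al2$clinical) <- NULL
  class(al2$clinical) <- c("clinical_table", "data.frame")
  adj <- regress_covariates(al2$expr, al2$clinical, covariates)
  list(expr = adj, clinical = al2$clinical,
       traits = encode_traits(al2$clinical), log = log)
}
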