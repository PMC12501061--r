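#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes as rows and
#' samples as columns, carrying a `scale` attribute recording where in the
#' pipeline it sits: `"raw"` (FPKM-like, non-negative), `"log2"`
#' (log2-transformed) or `"normalized"` (median-centred, signed).
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param scale one of `"raw"`, `"log2"`, `"normalized"`.
#' @return the matrix with class `expr_matrix` and a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("raw", "log2", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression must be non-negative")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' Scale tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"raw"`, `"log2"` or `"normalized"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("matrix carries no scale tag; use expression_matrix()")
  s
}

# internal: subset while keeping the class/scale attributes
expr_subset <- function(x, i = NULL, j = NULL) {
  s <- expr_scale(x)
  y <- unclass(x)
  if (!is.null(i)) y <- y[i, , drop = FALSE]
  if (!is.null(j)) y <- y[, j, drop = FALSE]
  expression_matrix(y, s)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Construct a clinical table
#'
#' Per-sample clinical data: pathologic stage (1-4, NA allowed), overall
#' survival time in days and event indicator (1 = death), plus optional
#' covariates (age, sex) and TNM components.
#'
#' @param sample_id character vector of unique sample IDs.
#' @param stage integer 1-4 or NA.
#' @param os_time_days non-negative numeric.
#' @param os_event 0/1.
#' @param age,sex,t_stage,n_stage,m_stage optional covariates (NA allowed).
#' @param substage optional raw substage code (e.g. "IA", "IIIB").
#' @return a `data.frame` with class `clinical_table`.
#' @export
clinical_table <- function(sample_id, stage = NA, os_time_days, os_event,
                           age = NA, sex = NA, t_stage = NA, n_stage = NA,
                           m_stage = NA, substage = NA) {
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in clinical table")
  if (any(!os_event[!is.na(os_event)] %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  if (any(os_time_days < 0, na.rm = TRUE)) stop("os_time_days must be >= 0")
  if (any(!is.na(stage) & !stage %in% 1:4)) stop("stage must be in 1..4 or NA")
  out <- data.frame(sample_id = as.character(sample_id),
                    stage = as.integer(stage),
                    substage = as.character(substage),
                    os_time_days = as.numeric(os_time_days),
                    os_event = as.integer(os_event),
                    age = as.numeric(age),
                    sex = as.character(sex),
                    t_stage = as.integer(t_stage),
                    n_stage = as.integer(n_stage),
                    m_stage = as.integer(m_stage),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Define a ratio signature
#'
#' A signature is a pair of disjoint gene lists: numerator genes whose high
#' expression marks good prognosis, and denominator genes whose high
#' expression marks poor prognosis. The per-sample score is
#' sum(numerator) / sum(denominator) of normalized abundances; `invert`
#' negates the score for signatures defined on the opposite convention.
#'
#' @param name signature name.
#' @param numerator,denominator character vectors of gene symbols.
#' @param invert negate the score (for poor-prognosis signatures).
#' @return an object of class `signature_def`.
#' @export
signature_def <- function(name, numerator, denominator, invert = FALSE) {
  numerator <- unique(as.character(numerator))
  denominator <- unique(as.character(denominator))
  if (length(intersect(numerator, denominator)) > 0)
    stop(sprintf("signature '%s': genes on both sides: %s", name,
                 paste(intersect(numerator, denominator), collapse = ", ")))
  if (length(numerator) == 0 || length(denominator) == 0)
    stop(sprintf("signature '%s': both sides must be non-empty", name))
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, invert = isTRUE(invert)),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("<signature_def> %s%s\n  num: %s\n  den: %s\n", x$name,
              if (x$invert) " (inverted)" else "",
              paste(x$numerator, collapse = " + "),
              paste(x$denominator, collapse = " + ")))
  invisible(x)
}
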