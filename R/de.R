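#' One-way ANOVA across stages, per gene
#'
#' Classical one-way F test of equal mean expression across stage groups,
#' vectorized over genes of a log2 expression matrix. Groups with fewer than
#' two samples are dropped with a warning; genes with zero within-group
#' variance get an NA record.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param stages per-sample group labels aligned to `colnames(expr)`.
#' @return data.frame with `gene`, `f`, `p`, `df1`, `df2`.
#' @export
stage_anova <- function(expr, stages) {
  x <- unclass(expr)
  g <- factor(stages)
  counts <- table(g)
  if (any(counts < 2)) {
    warning("dropping group(s) with < 2 samples: ",
            paste(names(counts)[counts < 2], collapse = ", "))
    keep <- g %in% names(counts)[counts >= 2]
    x <- x[, keep, drop = FALSE]
    g <- droplevels(g[keep])
  }
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 usable groups")
  n <- ncol(x)
  nj <- as.vector(table(g))
  gm <- rowsum(t(x), g) / nj              # k x genes group means
  grand <- colMeans(t(x))
  ssb <- colSums(nj * (t(t(gm) - grand))^2)
  sst <- rowSums((x - rowMeans(x))^2)
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  bad <- ssw <= .Machine$double.eps * sst | !is.finite(f)
  f[bad] <- NA; p[bad] <- NA
  data.frame(gene = rownames(x), f = f, p = p, df1 = k - 1, df2 = n - k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tukey HSD pairwise stage comparisons, per gene
#'
#' Studentized-range (Tukey-Kramer) adjusted p-values for every pair of stage
#' groups, using the pooled within-group mean square from the one-way ANOVA.
#'
#' @inheritParams stage_anova
#' @return list of data.frames, one per group pair (named `"1-2"`, ...), each
#'   with `gene`, `diff` (second minus first group mean), `p_adj`.
#' @export
tukey_pairwise <- function(expr, stages) {
  x <- unclass(expr)
  g <- factor(stages)
  counts <- table(g)
  if (any(counts < 2)) {
    keep <- g %in% names(counts)[counts >= 2]
    x <- x[, keep, drop = FALSE]
    g <- droplevels(g[keep])
  }
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 usable groups")
  n <- ncol(x)
  nj <- as.vector(table(g))
  gm <- rowsum(t(x), g) / nj
  grand <- rowMeans(x)
  ssb <- colSums(nj * (t(t(gm) - grand))^2)
  sst <- rowSums((x - grand)^2)
  mse <- (sst - ssb) / (n - k)
  out <- list()
  lev <- levels(g)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- gm[j, ] - gm[i, ]
    se <- sqrt(mse / 2 * (1 / nj[i] + 1 / nj[j]))
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
    p[!is.finite(q)] <- NA
    out[[paste(lev[i], lev[j], sep = "-")]] <-
      data.frame(gene = rownames(x), diff = diff, p_adj = p,
                 row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Welch two-sample t-test, vectorized over genes
#'
#' @param x numeric matrix (genes x samples) or vector.
#' @param groups logical or 0/1 vector; TRUE/1 = second group.
#' @return data.frame with `t` (second minus first group direction), `p`,
#'   `df`, `diff`.
#' @export
group_ttest <- function(x, groups) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  g <- as.logical(groups)
  if (sum(g) < 2 || sum(!g) < 2) stop("both groups need >= 2 samples")
  x1 <- x[, !g, drop = FALSE]; x2 <- x[, g, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[!is.finite(df) | df < 1] <- 1   # zero-variance guard
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- ifelse(m1[!is.finite(tt)] == m2[!is.finite(tt)], 1, 0)
  tt[is.nan(tt)] <- 0
  data.frame(gene = rownames(x), t = tt, p = p, df = df, diff = m2 - m1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1).
#'
#' @param pvals p-values in [0, 1] (NAs passed through).
#' @return adjusted values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its (BH-adjusted, by default) p-value passes 0.05 and
#' |log2 fold change| strictly exceeds the cutoff. The fold change is the
#' difference of group means on the log2 scale; direction follows its sign.
#'
#' @param gene gene IDs.
#' @param l2fc log2 fold changes (second group minus first).
#' @param p raw p-values.
#' @param comparison label stored with each record.
#' @param l2fc_cutoff strict |L2FC| threshold (default 0.5; 0.58 reproduces a
#'   50%-change cutoff).
#' @param p_cutoff significance threshold (default 0.05).
#' @param use_fdr apply the threshold to BH-adjusted values (default TRUE).
#' @param strict_p use strict `<` for the p threshold (default TRUE);
#'   FALSE uses `<=`.
#' @return data.frame of DEG records with `is_deg` and `direction`.
#' @export
call_degs <- function(gene, l2fc, p, comparison = "comparison",
                      l2fc_cutoff = 0.5, p_cutoff = 0.05, use_fdr = TRUE,
                      strict_p = TRUE) {
  fdr <- bh_adjust(p)
  crit <- if (use_fdr) fdr else p
  pass_p <- if (strict_p) crit < p_cutoff else crit <= p_cutoff
  is_deg <- !is.na(crit) & pass_p & abs(l2fc) > l2fc_cutoff
  data.frame(gene = gene, comparison = comparison, l2fc = l2fc, p = p,
             fdr = fdr, direction = ifelse(l2fc > 0, "up", "down"),
             is_deg = is_deg, row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-contrast differential expression
#'
#' Runs a two-group contrast defined on stages through a single shared code
#' path: grouping, Welch t (or Tukey-adjusted pairwise p from the full
#' one-way ANOVA), log2 fold change as difference of group means, BH FDR and
#' DEG calling.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param stages per-sample stage labels.
#' @param comparison `"stage1_vs_2"` (stage 1 vs stage 2 samples) or
#'   `"stage1_vs_rest"` (stage 1 vs all higher stages).
#' @param method `"welch"` (default) or `"tukey"` (only for stage1_vs_2).
#' @param ... thresholds passed to [call_degs()].
#' @return DEG record data.frame (see [call_degs()]).
#' @export
stage_de <- function(expr, stages, comparison = c("stage1_vs_2",
                                                  "stage1_vs_rest"),
                     method = c("welch", "tukey"), ...) {
  comparison <- match.arg(comparison)
  method <- match.arg(method)
  keep <- if (comparison == "stage1_vs_2") stages %in% c(1, 2)
          else !is.na(stages)
  x <- expr_subset(expr, j = which(keep))
  grp <- stages[keep] != 1      # second group = later stage(s)
  if (method == "welch" || comparison == "stage1_vs_rest") {
    tt <- group_ttest(unclass(x), grp)
    call_degs(tt$gene, tt$diff, tt$p, comparison, ...)
  } else {
    tk <- tukey_pairwise(expr, stages)[["1-2"]]
    call_degs(tk$gene, tk$diff, tk$p_adj, comparison, ...)
  }
}
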