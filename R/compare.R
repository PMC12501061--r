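#' Score a list of signatures on a normalized matrix
#'
#' Applies [ratio_score()] per signature, tolerating missing genes: up to
#' half of either side may be absent (dropped with a message); a signature
#' losing more than half of a side, or all of one side, is skipped with a
#' warning. Invert flags are honoured.
#'
#' @param norm normalized [expression_matrix()].
#' @param signatures list of [signature_def()] objects.
#' @param max_missing_frac per-side missing-gene tolerance (default 0.5).
#' @return samples x signatures score matrix (skipped signatures omitted).
#' @export
score_signatures <- function(norm, signatures, max_missing_frac = 0.5) {
  cols <- list()
  for (sig in signatures) {
    present_n <- intersect(sig$numerator, rownames(norm))
    present_d <- intersect(sig$denominator, rownames(norm))
    miss_n <- 1 - length(present_n) / length(sig$numerator)
    miss_d <- 1 - length(present_d) / length(sig$denominator)
    if (miss_n > max_missing_frac || miss_d > max_missing_frac ||
        length(present_n) == 0 || length(present_d) == 0) {
      warning(sprintf("skipping signature '%s': %.0f%%/%.0f%% of num/den missing",
                      sig$name, 100 * miss_n, 100 * miss_d))
      next
    }
    if (miss_n > 0 || miss_d > 0)
      message(sprintf("signature '%s': dropping %d absent gene(s)", sig$name,
                      length(sig$numerator) - length(present_n) +
                        length(sig$denominator) - length(present_d)))
    trimmed <- signature_def(sig$name, present_n, present_d, sig$invert)
    cols[[sig$name]] <- ratio_score(norm, trimmed)
  }
  if (length(cols) == 0) stop("no scorable signature")
  do.call(cbind, cols)
}

#' Signature-to-module correlation
#'
#' Pairwise-complete bicor (with Student p) of each signature score against
#' each module eigengene.
#'
#' @param scores samples x signatures matrix from [score_signatures()].
#' @param eigengenes samples x modules matrix.
#' @return list of matrices `r`, `p`, `n` (signatures x modules).
#' @export
signature_module_bicor <- function(scores, eigengenes) {
  res <- module_trait_correlation(scores, eigengenes)
  res
}

#' Signature-to-survival-trait correlation
#'
#' Bicor of each signature score against quantitative survival-time traits,
#' by default restricted to uncensored samples where the survival time is
#' fully observed.
#'
#' @param scores samples x signatures matrix.
#' @param traits samples x traits numeric matrix (e.g. from
#'   [encode_traits()]).
#' @param survival_traits trait columns to use (default `"OS.time"`).
#' @param event per-sample 0/1 event indicator used by the uncensored
#'   filter (optional).
#' @param uncensored_only restrict to event = 1 samples (default TRUE when
#'   `event` is supplied).
#' @return list of matrices `r`, `p`, `n` (signatures x traits).
#' @export
signature_survival_bicor <- function(scores, traits,
                                     survival_traits = "OS.time",
                                     event = NULL,
                                     uncensored_only = !is.null(event)) {
  tr <- traits[, survival_traits, drop = FALSE]
  if (uncensored_only) {
    if (is.null(event)) stop("event needed for uncensored_only")
    tr[event != 1, ] <- NA
  }
  module_trait_correlation(scores, tr)
}

#' Pearson correlation matrix among signature scores
#'
#' @param scores samples x signatures matrix.
#' @return list with `r` (pairwise-complete Pearson) and `p` (Student p).
#' @export
signature_cross_correlation <- function(scores) {
  r <- stats::cor(scores, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(scores))
  p <- matrix(correlation_student_p(as.vector(r), as.vector(n)),
              nrow(r), dimnames = dimnames(r))
  diag(p) <- 0
  list(r = r, p = p)
}

#' Paired DeLong test for two AUCs
#'
#' Compares the AUCs of two scores measured on the same samples and outcome,
#' using the paired DeLong placement-value covariance and a two-sided normal
#' p-value. Identical scores return p = 1 directly.
#'
#' @param score_a,score_b per-sample scores (same samples).
#' @param outcome binary 0/1 outcome.
#' @return list with `auc_a`, `auc_b`, `diff`, `se`, `p`.
#' @export
delong_paired_test <- function(score_a, score_b, outcome) {
  ok <- !is.na(score_a) & !is.na(score_b) & !is.na(outcome)
  a <- score_a[ok]; b <- score_b[ok]; y <- outcome[ok]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  pa <- delong_placements(a, y)
  pb <- delong_placements(b, y)
  if (identical(a, b) || (stats::sd(a) > 0 && stats::sd(b) > 0 &&
                          isTRUE(all.equal(stats::cor(a, b), 1))))
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = pa$auc - pb$auc,
                se = 0, p = 1))
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n0
  d <- pa$auc - pb$auc
  if (v <= 0) return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d,
                          se = 0, p = if (d == 0) 1 else NA_real_))
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, se = sqrt(v),
       p = 2 * stats::pnorm(-abs(d / sqrt(v))))
}

#' Compare signatures against a fitted network and survival outcome
#'
#' Runs the full comparison: scores, module bicor, survival-trait bicor,
#' inter-signature Pearson, and pairwise DeLong tests at each horizon.
#'
#' @param norm normalized [expression_matrix()].
#' @param signatures list of [signature_def()] objects.
#' @param eigengenes samples x modules matrix.
#' @param traits samples x traits matrix.
#' @param time,event survival outcome.
#' @param config a [ratio_config()].
#' @return list of class `signature_comparison`.
#' @export
compare_signatures <- function(norm, signatures, eigengenes, traits,
                               time, event, config = ratio_config()) {
  scores <- score_signatures(norm, signatures)
  mod <- signature_module_bicor(scores, eigengenes)
  surv <- signature_survival_bicor(scores, traits, event = event)
  cross <- signature_cross_correlation(scores)
  nm <- colnames(scores)
  delong <- list()
  for (t in config$timepoints_days) {
    o <- binarize_outcome(time, event, t)
    pm <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    if (sum(o == 1, na.rm = TRUE) > 0 && sum(o == 0, na.rm = TRUE) > 0) {
      for (i in seq_along(nm)) for (j in seq_along(nm)) {
        if (i < j) {
          dl <- delong_paired_test(scores[, i], scores[, j], o)
          pm[i, j] <- pm[j, i] <- dl$p
        }
      }
    }
    delong[[as.character(t)]] <- pm
  }
  structure(list(scores = scores, module_bicor = mod,
                 survival_bicor = surv, cross = cross, delong = delong),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("<signature_comparison> %d signatures x %d samples\n",
              ncol(x$scores), nrow(x$scores)))
  cat("inter-signature Pearson:\n")
  print(round(x$cross$r, 3))
  invisible(x)
}
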