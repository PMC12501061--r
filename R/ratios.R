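#' Ratio-search configuration
#'
#' @param timepoints_days survival horizons evaluated (default 12 months,
#'   18 months, 3, 5 and 10 years).
#' @param max_side_size largest per-side subset (default 4, the 1:1 to 4:4
#'   enumeration).
#' @param top_k_for_frequency ranked signatures scanned for gene frequency
#'   (default 100).
#' @param frequency_threshold frequency above which a gene is flagged for
#'   the next nomination round (default 0.2).
#' @return list of class `ratio_config`; the named timepoint subsets used for
#'   mean-AUC ranking (`all`, `no10y`, `no5y10y`) are derived from
#'   `timepoints_days`.
#' @export
ratio_config <- function(timepoints_days = c(365, 548, 1095, 1825, 3650),
                         max_side_size = 4, top_k_for_frequency = 100,
                         frequency_threshold = 0.2) {
  if (is.unsorted(timepoints_days, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (max_side_size < 1) stop("max_side_size must be >= 1")
  tp <- timepoints_days
  subsets <- list(all = tp,
                  no10y = tp[tp < 3650],
                  no5y10y = tp[tp < 1825])
  structure(list(timepoints_days = tp, max_side_size = max_side_size,
                 rank_subsets = subsets,
                 top_k_for_frequency = top_k_for_frequency,
                 frequency_threshold = frequency_threshold),
            class = "ratio_config")
}

#' Three-step normalization
#'
#' Step 1: log2(x + 1) on raw values; step 2: per-sample median centring;
#' step 3: per-sample scale normalization (each sample divided by its root
#' mean square), harmonizing dynamic range across samples and platforms.
#' Steps 2-3 are idempotent within 1e-9; the recipe is recorded in the
#' `recipe` attribute.
#'
#' Per-gene median centring is deliberately not part of the default recipe:
#' it would centre every gene's abundance at zero, making signature sums
#' cross zero and the ratio score sign-unstable. It is available via
#' `center_genes` for matrices consumed by correlation-based analyses only.
#'
#' @param expr raw-scale [expression_matrix()] (log2-scale input skips
#'   step 1).
#' @param center_genes additionally median-centre each gene (default FALSE;
#'   not suitable for ratio scoring).
#' @return normalized-scale [expression_matrix()].
#' @export
cluster3_normalize <- function(expr, center_genes = FALSE) {
  x <- unclass(expr)
  steps <- character(0)
  if (expr_scale(expr) == "raw") {
    x <- log2(x + 1)
    steps <- "log2(x+1)"
  } else if (expr_scale(expr) != "log2") {
    stop("cluster3_normalize expects raw or log2 input")
  }
  if (all(x == x[1])) warning("constant matrix; output is all zeros")
  x <- sweep(x, 2, apply(x, 2, stats::median))
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  x <- sweep(x, 2, rms, "/")
  steps <- c(steps, "sample median centring", "sample RMS scaling")
  if (center_genes) {
    x <- sweep(x, 1, apply(x, 1, stats::median))
    steps <- c(steps, "gene median centring")
  }
  out <- expression_matrix(x, "normalized")
  attr(out, "recipe") <- steps
  out
}

#' Per-sample ratio score of a signature
#'
#' `sum(numerator abundances) / sum(denominator abundances)` within each
#' sample of a normalized matrix. Samples whose denominator sum is within
#' 1e-9 of zero get NA and are excluded downstream; `invert` negates the
#' score.
#'
#' @param norm normalized [expression_matrix()].
#' @param sig a [signature_def()].
#' @return named per-sample score vector (NAs where guarded).
#' @export
ratio_score <- function(norm, sig) {
  missing <- setdiff(c(sig$numerator, sig$denominator), rownames(norm))
  if (length(missing) > 0)
    stop("signature genes absent from matrix: ",
         paste(missing, collapse = ", "))
  num <- colSums(unclass(norm)[sig$numerator, , drop = FALSE])
  den <- colSums(unclass(norm)[sig$denominator, , drop = FALSE])
  score <- num / den
  score[abs(den) < 1e-9] <- NA
  if (sig$invert) score <- -score
  score
}

#' Fixed-horizon binary survival outcome
#'
#' 1 = died by the horizon (event with time <= t); 0 = known to survive past
#' it (time >= t, censored or not); NA = censored before the horizon
#' (excluded).
#'
#' @param time,event survival outcome (days, 0/1).
#' @param t_days horizon (> 0).
#' @return integer vector of 1/0/NA.
#' @export
binarize_outcome <- function(time, event, t_days) {
  if (t_days <= 0) stop("t_days must be > 0")
  out <- rep(NA_integer_, length(time))
  out[event == 1 & time <= t_days] <- 1L
  out[is.na(out) & time >= t_days] <- 0L
  out
}

#' Single-covariate logistic fit
#'
#' Binomial GLM (logit link) of a binary outcome on a score, via IRLS.
#' Perfect separation is flagged; fitted probabilities are still returned
#' (they are a monotone transform of the score, so AUCs are unchanged).
#'
#' @param score per-sample predictor.
#' @param outcome binary 0/1 outcome (NAs dropped pairwise).
#' @return list with `fitted` (probabilities, NA where input was NA),
#'   `coef`, `separation` flag.
#' @export
fit_logistic <- function(score, outcome) {
  ok <- !is.na(score) & !is.na(outcome)
  y <- outcome[ok]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  w <- options(warn = -1); on.exit(options(w))
  fit <- stats::glm(y ~ score[ok], family = stats::binomial())
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 1e3)
  fitted <- rep(NA_real_, length(score))
  fitted[ok] <- stats::fitted(fit)
  list(fitted = fitted, coef = unname(stats::coef(fit)), separation = sep)
}

#' ROC AUC by pairwise concordance
#'
#' Mann-Whitney estimator: (concordant pairs + half the ties) over all
#' positive-negative pairs, computed via rank sums.
#'
#' @param score predictor (higher = more positive).
#' @param outcome binary 0/1 (NAs in either input dropped pairwise).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(score, outcome) {
  ok <- !is.na(score) & !is.na(outcome)
  s <- score[ok]; y <- outcome[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("need >= 1 positive and >= 1 negative")
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: list(auc, v10 (per positive), v01 (per negative))
delong_placements <- function(score, outcome) {
  x <- score[outcome == 1]; y <- score[outcome == 0]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  r_x <- rank(x); r_y <- rank(y)
  v10 <- (r_all[seq_len(n1)] - r_x) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1
  list(auc = mean(v10), v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' DeLong confidence interval and p-value for an AUC
#'
#' Normal-approximation CI from the DeLong variance (truncated to [0, 1])
#' and a two-sided p for H0: AUC = 0.5. Degenerate variance (e.g. AUC = 1 at
#' tiny n) falls back to the widest interval with a flag.
#'
#' @param score,outcome as [roc_auc()].
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `p`, `se`, `degenerate`.
#' @export
auc_ci <- function(score, outcome, level = 0.95) {
  ok <- !is.na(score) & !is.na(outcome)
  pl <- delong_placements(score[ok], outcome[ok])
  v <- stats::var(pl$v10) / pl$n1 + stats::var(pl$v01) / pl$n0
  if (!is.finite(v) || v <= 0)
    return(list(auc = pl$auc, ci_low = 0, ci_high = 1, p = NA_real_,
                se = NA_real_, degenerate = TRUE))
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = pl$auc, ci_low = max(0, pl$auc - z * se),
       ci_high = min(1, pl$auc + z * se),
       p = 2 * stats::pnorm(-abs((pl$auc - 0.5) / se)), se = se,
       degenerate = FALSE)
}

# confusion metrics at the Youden-optimal threshold (score oriented so
# higher predicts the positive class)
youden_metrics <- function(score, outcome) {
  ok <- !is.na(score) & !is.na(outcome)
  s <- score[ok]; y <- outcome[ok]
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[y == 0] < t), numeric(1))
  i <- which.max(sens + spec - 1)
  pred <- s >= thr[i]
  list(threshold = thr[i], sensitivity = sens[i], specificity = spec[i],
       accuracy = mean(pred == (y == 1)))
}

#' Enumerate equal-sided ratio combinations
#'
#' All unordered k-subsets of each candidate side, paired at equal k for
#' k = 1..`max_side_size` (the 1:1, 2:2, 3:3, 4:4 scheme), in deterministic
#' lexical order. The count equals `sum_k C(n,k) * C(m,k)`.
#'
#' @param num_candidates,den_candidates disjoint candidate gene vectors.
#' @param max_side_size largest k (ks exceeding a side's size are skipped).
#' @return data.frame with `k`, `num`, `den` ("+"-joined gene lists) and
#'   `name` ("num/den").
#' @export
enumerate_combinations <- function(num_candidates, den_candidates,
                                   max_side_size = 4) {
  if (length(intersect(num_candidates, den_candidates)) > 0)
    stop("candidate lists must be disjoint")
  num_candidates <- sort(unique(num_candidates))
  den_candidates <- sort(unique(den_candidates))
  rows <- list()
  for (k in seq_len(max_side_size)) {
    if (k > length(num_candidates) || k > length(den_candidates)) next
    ns <- apply(utils::combn(num_candidates, k), 2, paste, collapse = "+")
    ds <- apply(utils::combn(den_candidates, k), 2, paste, collapse = "+")
    rows[[k]] <- data.frame(k = k,
                            num = rep(ns, each = length(ds)),
                            den = rep(ds, times = length(ns)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no combinations possible")
  out$name <- paste(out$num, out$den, sep = "/")
  rownames(out) <- NULL
  out
}

# subset-sum matrices per k: list over k of (subsets x samples) sums and the
# "+"-joined subset labels
side_subset_sums <- function(norm, candidates, max_k) {
  x <- unclass(norm)[candidates, , drop = FALSE]
  out <- list()
  for (k in seq_len(max_k)) {
    if (k > length(candidates)) break
    cmb <- utils::combn(seq_along(candidates), k)
    ind <- matrix(0, ncol(cmb), length(candidates))
    ind[cbind(rep(seq_len(ncol(cmb)), each = k), as.vector(cmb))] <- 1
    s <- ind %*% x
    rownames(s) <- apply(cmb, 2, function(i)
      paste(candidates[i], collapse = "+"))
    out[[k]] <- s
  }
  out
}

# AUC for every row of a score matrix against one binary outcome; scores are
# orientation-free (max(a, 1-a)), matching in-sample logistic orientation
auc_rows <- function(scores, outcome) {
  ok_col <- !is.na(outcome)
  s <- scores[, ok_col, drop = FALSE]
  y <- outcome[ok_col]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(rep(NA_real_, nrow(s)))
  has_na <- rowSums(is.na(s)) > 0
  auc <- rep(NA_real_, nrow(s))
  if (any(!has_na)) {
    r <- apply(s[!has_na, , drop = FALSE], 1, rank)   # samples x combos
    if (is.null(dim(r))) r <- matrix(r, ncol = 1)
    auc[!has_na] <- (colSums(r[y == 1, , drop = FALSE]) -
                       n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  for (i in which(has_na)) {
    okr <- !is.na(s[i, ])
    if (sum(y[okr] == 1) > 0 && sum(y[okr] == 0) > 0)
      auc[i] <- roc_auc(s[i, okr], y[okr])
  }
  pmax(auc, 1 - auc)
}

#' Evaluate all equal-sided ratio combinations
#'
#' For every combination and survival horizon: per-sample ratio score,
#' fixed-horizon binarization, AUC (oriented as by the in-sample logistic
#' fit). With `metrics = "full"`, each combination additionally gets the
#' DeLong CI and p and Youden-threshold confusion metrics from an actual
#' logistic fit. Mean AUC per ranking subset is appended. Fully
#' deterministic.
#'
#' @param norm normalized [expression_matrix()].
#' @param time,event survival outcome aligned with `colnames(norm)`.
#' @param num_candidates,den_candidates disjoint candidate gene lists.
#' @param config a [ratio_config()].
#' @param metrics `"auc"` (fast, AUC only; default) or `"full"`.
#' @param chunk_size combinations processed per block.
#' @return data.frame of class `ratio_evaluation`: one row per combination
#'   with per-timepoint `auc_<days>` columns (plus CI/p/confusion columns
#'   under `"full"`) and `mean_all`, `mean_no10y`, `mean_no5y10y`.
#' @export
evaluate_all_ratios <- function(norm, time, event, num_candidates,
                                den_candidates, config = ratio_config(),
                                metrics = c("auc", "full"),
                                chunk_size = 5000) {
  metrics <- match.arg(metrics)
  if (length(intersect(num_candidates, den_candidates)) > 0)
    stop("candidate lists must be disjoint")
  num_candidates <- sort(unique(num_candidates))
  den_candidates <- sort(unique(den_candidates))
  tp <- config$timepoints_days
  outcomes <- lapply(tp, function(t) binarize_outcome(time, event, t))
  usable <- vapply(outcomes, function(o)
    sum(o == 1, na.rm = TRUE) > 0 && sum(o == 0, na.rm = TRUE) > 0,
    logical(1))
  if (!any(usable)) stop("no timepoint has both outcome classes")
  sums_n <- side_subset_sums(norm, num_candidates, config$max_side_size)
  sums_d <- side_subset_sums(norm, den_candidates, config$max_side_size)
  blocks <- list()
  for (k in seq_len(min(length(sums_n), length(sums_d)))) {
    sn <- sums_n[[k]]; sd_ <- sums_d[[k]]
    a <- nrow(sn); b <- nrow(sd_)
    idx_n <- rep(seq_len(a), each = b)
    idx_d <- rep(seq_len(b), times = a)
    total <- a * b
    for (start in seq(1, total, by = chunk_size)) {
      sel <- start:min(start + chunk_size - 1, total)
      den <- sd_[idx_d[sel], , drop = FALSE]
      sc <- sn[idx_n[sel], , drop = FALSE] / den
      sc[abs(den) < 1e-9] <- NA
      am <- vapply(seq_along(tp), function(ti) {
        if (!usable[ti]) return(rep(NA_real_, nrow(sc)))
        auc_rows(sc, outcomes[[ti]])
      }, numeric(nrow(sc)))
      if (nrow(sc) == 1) am <- matrix(am, 1)
      colnames(am) <- paste0("auc_", tp)
      blocks[[length(blocks) + 1]] <-
        data.frame(k = k, num = rownames(sn)[idx_n[sel]],
                   den = rownames(sd_)[idx_d[sel]], am,
                   stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  out$name <- paste(out$num, out$den, sep = "/")
  for (sn in names(config$rank_subsets)) {
    cols <- paste0("auc_", config$rank_subsets[[sn]])
    out[[paste0("mean_", sn)]] <-
      rowMeans(out[, cols, drop = FALSE], na.rm = TRUE)
  }
  if (metrics == "full") {
    full <- lapply(seq_len(nrow(out)), function(i) {
      sig <- signature_def(out$name[i], strsplit(out$num[i], "+",
                                                 fixed = TRUE)[[1]],
                           strsplit(out$den[i], "+", fixed = TRUE)[[1]])
      fl <- evaluate_signature(norm, sig, time, event, config)$flat
      fl[, !startsWith(colnames(fl), "auc_"), drop = FALSE]
    })
    out <- cbind(out, do.call(rbind, full))
  }
  rownames(out) <- NULL
  class(out) <- c("ratio_evaluation", "data.frame")
  out
}

#' Full per-timepoint evaluation of one signature
#'
#' Score, binarize, logistic fit, ROC AUC with DeLong CI and p, and
#' Youden-threshold accuracy/sensitivity/specificity at each horizon.
#'
#' @param norm normalized [expression_matrix()].
#' @param sig a [signature_def()].
#' @param time,event survival outcome.
#' @param config a [ratio_config()].
#' @return list with `table` (one row per timepoint) and `flat` (one-row
#'   data.frame with suffixed columns).
#' @export
evaluate_signature <- function(norm, sig, time, event,
                               config = ratio_config()) {
  score <- ratio_score(norm, sig)
  rows <- lapply(config$timepoints_days, function(t) {
    o <- binarize_outcome(time, event, t)
    ok <- !is.na(score) & !is.na(o)
    if (sum(o[ok] == 1) == 0 || sum(o[ok] == 0) == 0)
      return(data.frame(t_days = t, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        accuracy = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, n_used = sum(ok),
                        n_events = sum(o[ok] == 1)))
    lf <- fit_logistic(score[ok], o[ok])
    ci <- auc_ci(lf$fitted[!is.na(lf$fitted)], o[ok])
    ym <- youden_metrics(lf$fitted[!is.na(lf$fitted)], o[ok])
    data.frame(t_days = t, auc = ci$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, p = ci$p, accuracy = ym$accuracy,
               sensitivity = ym$sensitivity, specificity = ym$specificity,
               n_used = sum(ok), n_events = sum(o[ok] == 1))
  })
  tab <- do.call(rbind, rows)
  flat <- as.data.frame(as.list(stats::setNames(
    as.vector(t(as.matrix(tab[, -1]))),
    as.vector(t(outer(tab$t_days, colnames(tab)[-1],
                      function(t, c) paste0(c, "_", t)))))))
  list(table = tab, flat = flat)
}

#' Rank evaluated ratios by mean AUC
#'
#' Descending by the named timepoint subset's mean AUC; ties broken by the
#' all-timepoints mean, then by signature name.
#'
#' @param evals a `ratio_evaluation` table.
#' @param subset_name `"all"`, `"no10y"` or `"no5y10y"`.
#' @return the table, sorted.
#' @export
rank_by_mean_auc <- function(evals, subset_name = "all") {
  col <- paste0("mean_", subset_name)
  if (!col %in% colnames(evals)) stop("unknown ranking subset: ", subset_name)
  evals[order(-evals[[col]], -evals$mean_all, evals$name), , drop = FALSE]
}

#' Gene frequency among top-ranked ratios
#'
#' Per-side frequency of each candidate gene among the top-k ranked
#' signatures; genes above the frequency threshold are flagged for the next
#' nomination round.
#'
#' @param ranked a ranked `ratio_evaluation` table (see
#'   [rank_by_mean_auc()]).
#' @param config a [ratio_config()] (top_k and threshold).
#' @return data.frame with `gene`, `side`, `frequency`, `flagged`.
#' @export
top_gene_frequency <- function(ranked, config = ratio_config()) {
  k <- config$top_k_for_frequency
  if (nrow(ranked) < k) {
    warning(sprintf("only %d evaluations; using all", nrow(ranked)))
    k <- nrow(ranked)
  }
  top <- ranked[seq_len(k), ]
  count_side <- function(col, side) {
    genes <- unlist(strsplit(top[[col]], "+", fixed = TRUE))
    tab <- table(genes) / k
    data.frame(gene = names(tab), side = side,
               frequency = as.vector(tab),
               flagged = as.vector(tab) > config$frequency_threshold,
               stringsAsFactors = FALSE)
  }
  out <- rbind(count_side("num", "num"), count_side("den", "den"))
  out[order(out$side, -out$frequency, out$gene), ]
}

#' Nominate candidates by survival-time correlation
#'
#' Bicor of each gene's normalized abundance with observed survival time;
#' the `top_n` most positively correlated genes become numerator candidates
#' (high expression, long survival) and the most negative the denominator.
#' By default only uncensored samples (observed deaths) are used, where
#' survival time is fully observed.
#'
#' @param norm normalized [expression_matrix()].
#' @param time,event survival outcome.
#' @param top_n genes per side.
#' @param uncensored_only restrict to event = 1 samples (default TRUE).
#' @return list with `numerator`, `denominator` (gene vectors), `cor`
#'   (all correlations) and `n_used`.
#' @export
select_survival_correlated <- function(norm, time, event, top_n = 10,
                                       uncensored_only = TRUE) {
  use <- if (uncensored_only) event == 1 else rep(TRUE, length(time))
  if (sum(use) < 3) stop("fewer than 3 usable samples")
  if (top_n > nrow(norm)) stop("top_n exceeds gene count")
  x <- t(unclass(norm)[, use, drop = FALSE])
  r <- drop(bicor_matrix(x, matrix(time[use])))
  names(r) <- rownames(norm)
  ord <- order(r, decreasing = TRUE)
  list(numerator = names(r)[ord][seq_len(top_n)],
       denominator = names(r)[rev(ord)][seq_len(top_n)],
       cor = r, n_used = sum(use))
}

#' Exhaustive ratio search
#'
#' End-to-end wrapper: enumerate, evaluate (AUC fast path), rank by the
#' requested subset, and compute full metrics for the top block.
#'
#' @inheritParams evaluate_all_ratios
#' @param rank_subset timepoint subset used for ranking (default "all").
#' @param full_top number of top-ranked combinations re-evaluated with full
#'   metrics (default 10).
#' @return object of class `ratio_search`: `ranked` (full ranked table),
#'   `top` (full metrics for the leaders), `frequency` (top-k gene
#'   frequencies), `config`.
#' @export
ratio_search <- function(norm, time, event, num_candidates, den_candidates,
                         config = ratio_config(), rank_subset = "all",
                         full_top = 10) {
  evals <- evaluate_all_ratios(norm, time, event, num_candidates,
                               den_candidates, config)
  ranked <- rank_by_mean_auc(evals, rank_subset)
  top <- ranked[seq_len(min(full_top, nrow(ranked))), ]
  tops <- lapply(seq_len(nrow(top)), function(i) {
    sig <- signature_def(top$name[i],
                         strsplit(top$num[i], "+", fixed = TRUE)[[1]],
                         strsplit(top$den[i], "+", fixed = TRUE)[[1]])
    evaluate_signature(norm, sig, time, event, config)$flat
  })
  structure(list(ranked = ranked, top = cbind(top, do.call(rbind, tops)),
                 frequency = suppressWarnings(
                   top_gene_frequency(ranked, config)),
                 rank_subset = rank_subset, config = config),
            class = "ratio_search")
}

#' @export
print.ratio_search <- function(x, n = 5, ...) {
  cat(sprintf("<ratio_search> %d combinations, ranked by mean AUC (%s)\n",
              nrow(x$ranked), x$rank_subset))
  top <- utils::head(x$ranked, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. %s  mean AUC = %.3f\n", i, top$name[i],
                top[[paste0("mean_", x$rank_subset)]][i]))
  invisible(x)
}

#' @export
summary.ratio_search <- function(object, ...) {
  cat(sprintf("combinations evaluated: %d\n", nrow(object$ranked)))
  cat(sprintf("ranking subset: %s (timepoints %s)\n", object$rank_subset,
              paste(object$config$rank_subsets[[object$rank_subset]],
                    collapse = ", ")))
  cat("top combination:", object$ranked$name[1], "\n")
  flagged <- object$frequency[object$frequency$flagged, ]
  if (nrow(flagged) > 0) {
    cat(sprintf("genes in > %.0f%% of top %d ratios:\n",
                100 * object$config$frequency_threshold,
                object$config$top_k_for_frequency))
    for (s in c("num", "den")) {
      g <- flagged$gene[flagged$side == s]
      if (length(g) > 0)
        cat(sprintf("  %s: %s\n", s, paste(g, collapse = ", ")))
    }
  }
  invisible(object)
}

#' Plot per-timepoint AUC profiles of top-ranked ratios
#'
#' @param x a `ratio_search`.
#' @param n number of leaders shown.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ratio_search <- function(x, n = 5, ...) {
  tp <- x$config$timepoints_days
  top <- utils::head(x$ranked, n)
  m <- t(as.matrix(top[, paste0("auc_", tp)]))
  graphics::matplot(tp, m, type = "b", pch = 19, lty = 1,
                    xlab = "horizon (days)", ylab = "AUC",
                    ylim = c(0.4, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topleft", legend = top$name, col = seq_len(nrow(top)),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(x)
}
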