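#' Co-expression network configuration
#'
#' @param beta soft-threshold power (default 6, the conventional unsigned
#'   choice); NULL selects it from the candidate grid via
#'   [pick_soft_threshold()]. Non-integer powers are accepted. Larger powers
#'   compress topological-overlap distances toward 1, so `cut_height` should
#'   be raised accordingly when overriding.
#' @param candidate_powers grid searched when `beta` is NULL.
#' @param scale_free_target minimum signed scale-free fit R^2 (default 0.8).
#' @param min_module_size smallest cluster kept as a module (default 100).
#' @param cut_height static dendrogram cut as a fraction of the maximum
#'   merge height, or NULL (default) to choose the cut adaptively as the
#'   height yielding the most clusters of at least `min_module_size` genes
#'   (ties resolved upward). The adaptive rule is robust to how strongly the
#'   soft-threshold power compresses topological-overlap distances.
#' @param merge_me_cor modules whose eigengenes correlate above this are
#'   merged, iterated to a fixpoint (default 0.75).
#' @param cor_method `"bicor"` (default) or `"pearson"`.
#' @param kme_min module members with own-module kME below this are
#'   reassigned to grey after cutting and merging (default 0.3, the usual
#'   membership-cleanup threshold).
#' @param signed adjacency type: `"hybrid"` (default; signed hybrid,
#'   `max(cor, 0)^beta`, which keeps anti-correlated modules apart while
#'   rejecting uncorrelated background as sharply as an unsigned network),
#'   `FALSE` (unsigned `|cor|^beta`) or `TRUE` (signed `((1+cor)/2)^beta`).
#' @return list of class `network_config`.
#' @export
network_config <- function(beta = 6,
                           candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                           scale_free_target = 0.8, min_module_size = 100,
                           cut_height = NULL, merge_me_cor = 0.75,
                           cor_method = c("bicor", "pearson"),
                           signed = "hybrid", kme_min = 0.3) {
  cor_method <- match.arg(cor_method)
  if (scale_free_target <= 0 || scale_free_target > 1)
    stop("scale_free_target must be in (0, 1]")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!is.null(beta) && beta <= 0) stop("beta must be > 0")
  structure(list(beta = beta, candidate_powers = candidate_powers,
                 scale_free_target = scale_free_target,
                 min_module_size = min_module_size, cut_height = cut_height,
                 merge_me_cor = merge_me_cor, cor_method = cor_method,
                 signed = signed, kme_min = kme_min),
            class = "network_config")
}

# gene-gene correlation matrix (genes in rows of expr)
gene_cor_matrix <- function(expr, cor_method = "bicor") {
  x <- t(unclass(expr))
  if (cor_method == "bicor") bicor_matrix(x) else stats::cor(x)
}

adjacency_from_cor <- function(cc, beta, signed = "hybrid") {
  a <- if (identical(signed, "hybrid")) pmax(cc, 0)^beta
       else if (isTRUE(signed)) ((1 + cc) / 2)^beta
       else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Signed scale-free topology fit
#'
#' R^2 of `log10 p(k)` on `log10 k` over equal-width connectivity bins
#' (empty bins dropped, at least `nbins` requested), signed by the slope so
#' a decreasing degree distribution scores positively.
#'
#' @param k connectivity values.
#' @param nbins number of histogram bins (default 10).
#' @return list with `fit` (signed R^2) and `slope`.
#' @export
scale_free_fit <- function(k, nbins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < nbins) return(list(fit = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(list(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(fit = -sign(slope) * r2, slope = unname(slope))
}

#' Select a soft-threshold power for scale-free topology
#'
#' For each candidate power the adjacency `|cor|^beta` is formed, per-gene
#' connectivity computed, and the signed scale-free fit evaluated; the
#' smallest power reaching `scale_free_target` is returned (or the best
#' fitting one, with a warning, if none reaches it).
#'
#' @param expr log2-scale [expression_matrix()] with >= 50 genes.
#' @param config a [network_config()].
#' @return list with `beta` and `fit_table` (power, fit, mean/median
#'   connectivity).
#' @export
pick_soft_threshold <- function(expr, config = network_config()) {
  if (nrow(expr) < 50) stop("need >= 50 genes to assess scale-free fit")
  cc <- gene_cor_matrix(expr, config$cor_method)
  rows <- lapply(config$candidate_powers, function(b) {
    a <- adjacency_from_cor(cc, b, config$signed)
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k)
    data.frame(power = b, fit = sf$fit, slope = sf$slope,
               mean_k = mean(k), median_k = stats::median(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$fit) & tab$fit >= config$scale_free_target)
  if (length(hit) > 0) {
    beta <- tab$power[hit[1]]
  } else {
    beta <- tab$power[which.max(tab$fit)]
    warning(sprintf("no candidate power reaches fit %.2f; best fit %.3f at %g",
                    config$scale_free_target, max(tab$fit, na.rm = TRUE), beta))
  }
  list(beta = beta, fit_table = tab)
}

# choose the static cut that maximizes the number of module-sized clusters
# (at least min_module_size genes but no more than half the network -- a
# cluster engulfing most genes is the unclustered remainder, not a module);
# ties resolved by the highest such cut, so modules are as inclusive as
# possible without merging across the gap
pick_static_cut <- function(tree, min_module_size, n_grid = 200) {
  n <- length(tree$order)
  hs <- sort(unique(tree$height))
  if (length(hs) > n_grid)
    hs <- stats::quantile(hs, seq(0, 1, length.out = n_grid), names = FALSE)
  grid <- hs - sqrt(.Machine$double.eps)
  cuts <- stats::cutree(tree, h = grid)
  counts <- apply(cuts, 2, function(cl) {
    sz <- table(cl)
    sum(sz >= min_module_size & sz <= n / 2)
  })
  best <- which(counts == max(counts))
  grid[best[length(best)]]
}

# TOM similarity from an adjacency matrix
tom_similarity <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Adjacency (`|cor|^beta`, bicor by default) -> topological overlap ->
#' average-linkage hierarchical clustering of `1 - TOM` -> static cut at
#' `cut_height` of the maximum merge height -> clusters below
#' `min_module_size` unassigned (label 0) -> modules with eigengene
#' correlation above `merge_me_cor` merged to a fixpoint -> labels renumbered
#' by decreasing size (M1 largest).
#'
#' @param expr log2-scale [expression_matrix()].
#' @param config a [network_config()]; `beta` must be set (see
#'   [pick_soft_threshold()]).
#' @return integer vector of module labels named by gene (0 = unassigned).
#' @export
detect_modules <- function(expr, config = network_config()) {
  if (is.null(config$beta)) stop("config$beta is not set")
  cc <- gene_cor_matrix(expr, config$cor_method)
  a <- adjacency_from_cor(cc, config$beta, config$signed)
  tom <- tom_similarity(a)
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  h <- if (is.null(config$cut_height)) {
    pick_static_cut(tree, config$min_module_size)
  } else {
    config$cut_height * max(tree$height)
  }
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  labels <- ifelse(sizes[as.character(raw)] >= config$min_module_size, raw, 0L)
  names(labels) <- rownames(expr)
  labels <- merge_close_modules(expr, labels, config)
  labels <- prune_low_kme(expr, labels, config)
  renumber_modules(labels)
}

# grey out module members whose own-module kME falls below kme_min, then
# re-apply the minimum module size; the standard membership cleanup that
# keeps loosely attached background genes out of modules
prune_low_kme <- function(expr, labels, config) {
  mods <- setdiff(unique(labels), 0L)
  if (length(mods) == 0) return(labels)
  me <- module_eigengenes(expr, labels)$eigengenes
  kme <- kme_table(expr, me, config$cor_method)
  for (m in mods) {
    members <- names(labels)[labels == m]
    weak <- members[kme[members, paste0("M", m)] < config$kme_min]
    labels[weak] <- 0L
    if (sum(labels == m) < config$min_module_size)
      labels[labels == m] <- 0L
  }
  labels
}

# iterate: merge the most correlated eigengene pair above the threshold
merge_close_modules <- function(expr, labels, config) {
  repeat {
    mods <- setdiff(unique(labels), 0L)
    if (length(mods) < 2) return(labels)
    me <- module_eigengenes(expr, labels)$eigengenes
    cm <- if (config$cor_method == "bicor") bicor_matrix(me) else stats::cor(me)
    diag(cm) <- 0
    if (max(cm) <= config$merge_me_cor) return(labels)
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    keep <- as.integer(sub("^M", "", colnames(me)[idx[1]]))
    drop <- as.integer(sub("^M", "", colnames(me)[idx[2]]))
    labels[labels == drop] <- keep
  }
}

renumber_modules <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- ifelse(labels == 0L, 0L, new[as.character(labels)])
  stats::setNames(as.integer(out), names(labels))
}

#' Module eigengenes
#'
#' Per module the member genes are standardized across samples and the first
#' right singular vector of the samples x genes matrix gives the eigengene,
#' rescaled to unit variance and sign-oriented so the mean correlation of
#' members to their eigengene (kME) is positive. Zero-variance genes are
#' dropped from the computation with a warning.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param labels module labels from [detect_modules()].
#' @return list with `eigengenes` (samples x modules matrix, columns "M1"...)
#'   and `variance_explained` (leading eigenvalue share per module).
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  if (length(mods) == 0) stop("no assigned modules")
  x <- unclass(expr)
  me <- matrix(NA_real_, ncol(x), length(mods),
               dimnames = list(colnames(x), paste0("M", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    sub <- x[members, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("module M%d: dropping %d zero-variance gene(s) from ME",
                      mods[i], sum(sds == 0)))
      sub <- sub[sds > 0, , drop = FALSE]
    }
    z <- t(scale(t(sub)))
    sv <- svd(t(z), nu = 1, nv = 0)
    v <- sv$u[, 1]
    v <- v / stats::sd(v)
    if (mean(stats::cor(v, t(sub))) < 0) v <- -v
    me[, i] <- v - mean(v)
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, variance_explained = ve)
}

#' Module membership (kME) table
#'
#' Correlation of every gene to every module eigengene.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param cor_method `"bicor"` or `"pearson"`.
#' @return genes x modules matrix of kME values.
#' @export
kme_table <- function(expr, eigengenes, cor_method = "bicor") {
  if (!identical(colnames(expr), rownames(eigengenes)))
    stop("expression and eigengene samples are not aligned")
  if (cor_method == "bicor") bicor_matrix(t(unclass(expr)), eigengenes)
  else stats::cor(t(unclass(expr)), eigengenes)
}

#' Hub genes per module
#'
#' Within each module, members ranked by own-module kME (descending, ties by
#' gene ID); the top `ceil(top_frac * size)` are hubs.
#'
#' @param kme genes x modules kME matrix.
#' @param labels module labels.
#' @param top_frac hub fraction (default 0.1, the top-10% rule).
#' @return named list of hub gene vectors, one per module ("M1", ...).
#' @export
hub_genes <- function(kme, labels, top_frac = 0.1) {
  mods <- sort(setdiff(unique(labels), 0L))
  out <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    km <- kme[members, paste0("M", m)]
    ord <- order(-km, members)
    n_hub <- ceiling(top_frac * length(members))
    out[[paste0("M", m)]] <- members[ord][seq_len(n_hub)]
  }
  out
}

#' Module-trait correlation
#'
#' Pairwise-complete bicor (or Pearson) of each module eigengene against each
#' numeric trait column, with Student p-values and the number of complete
#' pairs per cell. Cells with fewer than 3 complete pairs are NA.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits samples x traits numeric matrix (NAs allowed).
#' @param cor_method `"bicor"` or `"pearson"`.
#' @return list of modules x traits matrices `r`, `p`, `n`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     cor_method = "bicor") {
  shared <- intersect(rownames(eigengenes), rownames(traits))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  e <- eigengenes[shared, , drop = FALSE]
  tr <- traits[shared, , drop = FALSE]
  dims <- list(colnames(e), colnames(tr))
  r <- p <- nmat <- matrix(NA_real_, ncol(e), ncol(tr), dimnames = dims)
  for (i in seq_len(ncol(e))) for (j in seq_len(ncol(tr))) {
    x <- e[, i]; y <- tr[, j]
    ok <- is.finite(x) & is.finite(y)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) next
    r[i, j] <- if (cor_method == "bicor")
      suppressWarnings(bicor(x[ok], y[ok])) else stats::cor(x[ok], y[ok])
    p[i, j] <- correlation_student_p(r[i, j], sum(ok))
  }
  list(r = r, p = p, n = nmat)
}

#' Fisher overlap between two module assignments
#'
#' For every pair of modules from two labelings over the same gene universe,
#' the one-tailed (upper) hypergeometric p-value of the membership overlap,
#' plus BH adjustment across all cells. Used as a module-preservation
#' surrogate between networks.
#'
#' @param labels_a,labels_b module label vectors named by gene, identical
#'   universes.
#' @return list of matrices `p` (raw FET p), `fdr` (BH across cells),
#'   `overlap` (counts).
#' @export
module_overlap_fisher <- function(labels_a, labels_b) {
  if (!setequal(names(labels_a), names(labels_b)))
    stop("gene universes differ between the two labelings")
  labels_b <- labels_b[names(labels_a)]
  n_univ <- length(labels_a)
  ma <- sort(setdiff(unique(labels_a), 0L))
  mb <- sort(setdiff(unique(labels_b), 0L))
  dims <- list(paste0("A", ma), paste0("B", mb))
  p <- ov <- matrix(NA_real_, length(ma), length(mb), dimnames = dims)
  for (i in seq_along(ma)) for (j in seq_along(mb)) {
    in_a <- labels_a == ma[i]; in_b <- labels_b == mb[j]
    k <- sum(in_a & in_b)
    ov[i, j] <- k
    p[i, j] <- stats::phyper(k - 1, sum(in_a), n_univ - sum(in_a),
                             sum(in_b), lower.tail = FALSE)
  }
  fdr <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), dimnames = dims)
  list(p = p, fdr = fdr, overlap = ov)
}

#' Fit a co-expression network end to end
#'
#' Convenience wrapper: soft-threshold selection (unless `beta` is given),
#' module detection, eigengenes, kME and hubs, returned as one classed
#' object.
#'
#' @param expr log2-scale [expression_matrix()].
#' @param config a [network_config()].
#' @param top_frac hub fraction passed to [hub_genes()].
#' @return object of class `coexpression_network` with elements `labels`,
#'   `eigengenes`, `variance_explained`, `kme`, `hubs`, `beta`, `fit_table`.
#' @export
fit_network <- function(expr, config = network_config(), top_frac = 0.1) {
  fit_table <- NULL
  if (is.null(config$beta)) {
    st <- pick_soft_threshold(expr, config)
    config$beta <- st$beta
    fit_table <- st$fit_table
  }
  labels <- detect_modules(expr, config)
  if (all(labels == 0)) {
    warning("all genes unassigned; returning empty network")
    return(structure(list(labels = labels, eigengenes = NULL, kme = NULL,
                          hubs = list(), beta = config$beta,
                          fit_table = fit_table, config = config),
                     class = "coexpression_network"))
  }
  me <- module_eigengenes(expr, labels)
  kme <- kme_table(expr, me$eigengenes, config$cor_method)
  structure(list(labels = labels, eigengenes = me$eigengenes,
                 variance_explained = me$variance_explained, kme = kme,
                 hubs = hub_genes(kme, labels, top_frac), beta = config$beta,
                 fit_table = fit_table, config = config),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  mods <- setdiff(unique(x$labels), 0L)
  cat(sprintf("<coexpression_network> beta = %g, %d modules, %d/%d genes assigned\n",
              x$beta, length(mods), sum(x$labels != 0), length(x$labels)))
  if (length(mods) > 0) {
    sz <- sort(table(x$labels[x$labels != 0]), decreasing = TRUE)
    cat("  sizes:", paste(sprintf("M%s=%d", names(sz), sz), collapse = " "), "\n")
  }
  invisible(x)
}

#' Plot module-trait correlations as a heatmap
#'
#' @param x a `coexpression_network`.
#' @param traits samples x traits numeric matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot.coexpression_network <- function(x, traits = NULL, ...) {
  if (is.null(traits)) {
    graphics::barplot(sort(table(x$labels[x$labels != 0]), decreasing = TRUE),
                      xlab = "module", ylab = "genes", ...)
    return(invisible(x))
  }
  mt <- module_trait_correlation(x$eigengenes, traits, x$config$cor_method)
  r <- mt$r
  graphics::image(seq_len(ncol(r)), seq_len(nrow(r)), t(r),
                  zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(51, "Blue-Red"), ...)
  graphics::axis(1, seq_len(ncol(r)), colnames(r), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(r)), rownames(r), las = 2, cex.axis = 0.7)
  sig <- which(mt$p <= 0.05, arr.ind = TRUE)
  if (nrow(sig) > 0)
    graphics::text(sig[, 2], sig[, 1],
                   signif(mt$p[sig], 1), cex = 0.5)
  invisible(x)
}
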