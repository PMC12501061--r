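#' Full-run configuration
#'
#' @param sim a [sim_params()] object (synthetic input), or NULL when
#'   `expr`/`clinical` are supplied to [run_full_pipeline()] directly.
#' @param network a [network_config()].
#' @param ratio a [ratio_config()].
#' @param deg_comparison stage contrast used for candidate nomination.
#' @param rank_subset timepoint subset ranking the ratio search (default
#'   `"no5y10y"`: mean AUC over the 12-month, 18-month and 3-year horizons,
#'   where fixed-horizon outcomes are best populated; the 5- and 10-year
#'   AUCs rest on few long-term survivors).
#' @param max_candidates per-side cap on nominated candidates, kept in
#'   own-module kME order (default 8, twice the maximal ratio side so the
#'   enumeration stays at the scale of a first-round pool).
#' @param l2fc_cutoff,p_cutoff DEG thresholds.
#' @param out_dir optional directory for TSV outputs + manifest.
#' @param seed integer seed (also forwarded to `sim` when set there is NA).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_params(), network = network_config(),
                       ratio = ratio_config(),
                       deg_comparison = "stage1_vs_2",
                       rank_subset = "no5y10y", max_candidates = 8,
                       l2fc_cutoff = 0.5, p_cutoff = 0.05, out_dir = NULL,
                       seed = 1L) {
  structure(list(sim = sim, network = network, ratio = ratio,
                 deg_comparison = deg_comparison, rank_subset = rank_subset,
                 max_candidates = max_candidates,
                 l2fc_cutoff = l2fc_cutoff, p_cutoff = p_cutoff,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[setdiff(names(config), "out_dir")], file = f,
       control = c("all", "hexNumeric"))
  unname(tools::md5sum(f))
}

#' Run the discovery pipeline end to end
#'
#' Simulate (or accept) data, preprocess, fit the co-expression network,
#' compute stage differential expression, nominate ratio candidates as the
#' hub/DEG intersection of the most anti-correlated module pair (numerator
#' from the module whose eigengene is negatively correlated with death),
#' exhaustively rank ratio signatures, run median-split survival analysis of
#' the top signature, and correlate it back to the module eigengenes.
#'
#' @param config a [run_config()].
#' @param expr,clinical optional raw [expression_matrix()] and
#'   [clinical_table()] overriding the synthetic input.
#' @return object of class `pipeline_run` with every stage's output and, if
#'   `out_dir` is set, a manifest of written files with md5 checksums.
#' @export
run_full_pipeline <- function(config = run_config(), expr = NULL,
                              clinical = NULL) {
  truth <- NULL
  if (is.null(expr)) {
    sim <- generate_dataset(config$sim)
    expr <- sim$expr; clinical <- sim$clinical; truth <- sim$truth
  }
  pre <- preprocess_pipeline(expr, clinical)
  net <- fit_network(pre$expr, config$network)
  mods <- setdiff(unique(net$labels), 0L)
  if (length(mods) < 2) stop("pipeline stage 'network': fewer than 2 modules")
  deg <- stage_de(pre$expr, pre$clinical$stage, config$deg_comparison,
                  l2fc_cutoff = config$l2fc_cutoff,
                  p_cutoff = config$p_cutoff)
  nom <- nominate_candidates(net, deg, pre$traits, config$max_candidates)
  norm <- cluster3_normalize(expr_subset(expr, rownames(pre$expr),
                                         colnames(pre$expr)))
  search <- ratio_search(norm, pre$clinical$os_time_days,
                         pre$clinical$os_event, nom$numerator,
                         nom$denominator, config$ratio,
                         rank_subset = config$rank_subset)
  top_sig <- signature_def(search$ranked$name[1],
                           strsplit(search$ranked$num[1], "+",
                                    fixed = TRUE)[[1]],
                           strsplit(search$ranked$den[1], "+",
                                    fixed = TRUE)[[1]])
  surv_top <- survival_by_split(ratio_score(norm, top_sig),
                                pre$clinical$os_time_days,
                                pre$clinical$os_event)
  mt <- module_trait_correlation(net$eigengenes, pre$traits,
                                 config$network$cor_method)
  run <- structure(list(config = config, truth = truth, preprocess = pre,
                        network = net, module_trait = mt, deg = deg,
                        nomination = nom, normalized = norm, search = search,
                        top_signature = top_sig, survival_top = surv_top,
                        hash = config_hash(config)),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) run$manifest <- write_run(run, config$out_dir)
  run
}

# hub-and-DEG candidate nomination from the most anti-correlated module
# pair: differentially expressed hubs in own-module kME order (all hubs if
# the intersection is degenerate), capped at max_candidates per side
nominate_candidates <- function(net, deg, traits, max_candidates = 10) {
  me <- net$eigengenes
  cm <- bicor_matrix(me)
  diag(cm) <- 0
  idx <- which(cm == min(cm), arr.ind = TRUE)[1, ]
  pair <- colnames(me)[idx]
  os <- traits[rownames(me), "OS"]
  os_cor <- vapply(pair, function(m)
    suppressWarnings(bicor(me[, m], os)), numeric(1))
  protective <- pair[which.min(os_cor)]   # low death correlation
  adverse <- pair[which.max(os_cor)]
  degs <- deg$gene[deg$is_deg]
  pick <- function(mod) {
    hubs <- net$hubs[[mod]]
    hubs <- hubs[order(-net$kme[hubs, mod], hubs)]
    cand <- intersect(hubs, degs)
    # degenerate intersection: fall back to the minimal hub core that still
    # supports the largest (4:4) ratios
    if (length(cand) < 2) cand <- hubs[seq_len(min(4, length(hubs)))]
    cand[seq_len(min(max_candidates, length(cand)))]
  }
  list(numerator = pick(protective), denominator = pick(adverse),
       protective_module = protective, adverse_module = adverse,
       me_cor = cm[idx[1], idx[2]])
}

# write stage outputs as commented TSVs and return a checksum manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste("ratiosig", as.character(utils::packageVersion("ratiosig"))),
           paste("config", run$hash), paste("seed", run$config$seed))
  wtsv <- function(d, name, rn = FALSE) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(d, con, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
    close(con)
    path
  }
  files <- c(
    wtsv(data.frame(gene = names(run$network$labels),
                    module = run$network$labels), "module_labels.tsv"),
    wtsv(run$network$eigengenes, "module_eigengenes.tsv", rn = TRUE),
    wtsv(run$network$kme, "kme.tsv", rn = TRUE),
    wtsv(run$module_trait$r, "module_trait_bicor.tsv", rn = TRUE),
    wtsv(run$module_trait$p, "module_trait_p.tsv", rn = TRUE),
    wtsv(run$deg, "deg_records.tsv"),
    wtsv(utils::head(run$search$ranked, 1000), "ranked_ratios.tsv"),
    wtsv(run$search$frequency, "top_gene_frequency.tsv"))
  data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  genes/samples after preprocessing: %d x %d\n",
              nrow(x$preprocess$expr), ncol(x$preprocess$expr)))
  cat(sprintf("  modules: %d  DEGs (%s): %d\n",
              length(setdiff(unique(x$network$labels), 0L)),
              x$deg$comparison[1], sum(x$deg$is_deg)))
  cat(sprintf("  nominated %d num (%s) x %d den (%s) candidates\n",
              length(x$nomination$numerator), x$nomination$protective_module,
              length(x$nomination$denominator), x$nomination$adverse_module))
  cat(sprintf("  top signature: %s (mean AUC %.3f)\n",
              x$top_signature$name, x$search$ranked$mean_all[1]))
  cat(sprintf("  top-signature median-split HR: %.2f\n",
              x$survival_top$cox$hr))
  invisible(x)
}
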