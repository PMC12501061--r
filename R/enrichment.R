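#' Parse a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes. Duplicate
#' genes within a set are deduplicated; sets left empty are dropped with a
#' warning; a line with fewer than three fields is an error naming the line.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                   i, length(f)))
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(genes) == 0) {
      warning("dropping empty gene set: ", f[1])
      next
    }
    if (f[1] %in% names(sets)) stop("duplicate set name: ", f[1])
    sets[[f[1]]] <- genes
  }
  sets
}

#' Fisher exact enrichment of a gene list against gene sets
#'
#' One-tailed (upper) hypergeometric test of the overlap between the module
#' gene list and each set, after intersecting sets with the universe;
#' Benjamini-Hochberg adjustment across the sets tested.
#'
#' @param module_genes character vector, subset of `universe`.
#' @param universe background gene universe (all genes surviving
#'   preprocessing, not the genome).
#' @param sets named list of gene sets (see [parse_gmt()]).
#' @return data.frame with term, overlap/module/set/universe sizes, `fet_p`
#'   and `fdr`, ordered by p.
#' @export
fisher_enrichment <- function(module_genes, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of the universe")
  n_univ <- length(universe)
  n_mod <- length(module_genes)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, module_genes))
    p <- stats::phyper(k - 1, length(s), n_univ - length(s), n_mod,
                       lower.tail = FALSE)
    data.frame(term = nm, overlap_count = k, module_size = n_mod,
               set_size = length(s), universe_size = n_univ, fet_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$fet_p, method = "BH")
  out[order(out$fet_p), ]
}
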