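# shared fixtures, built in code

# small two-block factor dataset for fast network tests: returns a log2
# expression_matrix plus the true block labels
small_block_data <- function(seed = 1, n = 120, block = 60, n_bg = 180,
                             within_cor = 0.6, anticor = 0.7) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), n, 2)
  f <- cbind(z[, 1], -anticor * z[, 1] + sqrt(1 - anticor^2) * z[, 2])
  lam <- runif(2 * block, 0.6, 1)
  sig <- sqrt(mean(lam^2) * (1 - within_cor) / within_cor)
  genes <- sprintf("g%04d", seq_len(2 * block + n_bg))
  y <- rbind(
    6 + tcrossprod(lam[1:block], f[, 1]),
    6 + tcrossprod(lam[block + 1:block], f[, 2]),
    matrix(0, n_bg, n) + 5
  ) + matrix(rnorm((2 * block + n_bg) * n, sd = sig), 2 * block + n_bg, n)
  dimnames(y) <- list(genes, sprintf("s%03d", seq_len(n)))
  list(expr = expression_matrix(y, "log2"),
       labels = setNames(c(rep(1L, block), rep(2L, block), rep(0L, n_bg)),
                         genes),
       factors = f)
}

# small network config matched to small_block_data sizes
small_net_config <- function(...) {
  network_config(min_module_size = 40, ...)
}

# cached reduced-size simulated dataset (used by several test files)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(sim_params(
        n_samples = 150, n_genes = 600, module_sizes = c(60, 60), seed = 42))
    cache
  }
})

# adjusted Rand index between two labelings (independent check helper)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (max_idx - expected)
}

# genes of a ranked-ratio row, for planted-overlap counting
row_genes <- function(ranked, i) {
  unique(unlist(strsplit(unlist(ranked[i, c("num", "den")]), "+",
                         fixed = TRUE)))
}
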