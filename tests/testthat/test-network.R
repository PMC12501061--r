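test_that("scale-free fit is high on an exact discrete power law", {
  k <- rep(1:50, times = round(2000 * (1:50)^-2))
  sf <- scale_free_fit(k)
  expect_gte(sf$fit, 0.95)
  expect_lt(sf$slope, 0)
})

test_that("soft-threshold selection reports the full candidate table", {
  sd1 <- small_block_data(seed = 2, n = 60, block = 30, n_bg = 40)
  cfg <- network_config(candidate_powers = c(2, 4, 6))
  st <- suppressWarnings(pick_soft_threshold(sd1$expr, cfg))
  expect_equal(nrow(st$fit_table), 3L)
  expect_true(st$beta %in% c(2, 4, 6))
  expect_equal(network_config()$scale_free_target, 0.8)
})

test_that("raising beta never increases adjacency; TOM is a similarity", {
  set.seed(3)
  m <- matrix(rnorm(30 * 40), 30, 40)
  cc <- cor(m)
  a2 <- ratiosig:::adjacency_from_cor(cc, 2, FALSE)
  a6 <- ratiosig:::adjacency_from_cor(cc, 6, FALSE)
  expect_true(all(a6 <= a2 + 1e-15))
  tom <- ratiosig:::tom_similarity(a2)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("two planted blocks are recovered as two clean modules", {
  sd1 <- small_block_data(seed = 5)
  lab <- detect_modules(sd1$expr, small_net_config())
  expect_equal(length(setdiff(unique(lab), 0L)), 2L)
  expect_gte(ari(lab, sd1$labels), 0.9)
  # sample order is irrelevant
  perm <- sample(ncol(sd1$expr))
  lab2 <- detect_modules(ratiosig:::expr_subset(sd1$expr, j = perm),
                         small_net_config())
  expect_identical(lab, lab2)
})

test_that("a block below the minimum module size is left grey", {
  sd1 <- small_block_data(seed = 6, block = 30, n_bg = 100)
  lab <- detect_modules(sd1$expr, network_config(min_module_size = 50))
  expect_true(all(lab == 0))
})

test_that("eigengenes summarize their module up to sign convention", {
  sd1 <- small_block_data(seed = 7)
  lab <- detect_modules(sd1$expr, small_net_config())
  me <- module_eigengenes(sd1$expr, lab)
  expect_equal(unname(apply(me$eigengenes, 2, sd)), rep(1, 2),
               tolerance = 1e-8)
  # variance explained equals the leading eigenvalue share (SVD oracle)
  members <- names(lab)[lab == 1L]
  z <- scale(t(unclass(sd1$expr)[members, ]))
  ev <- eigen(crossprod(z), only.values = TRUE)$values
  expect_equal(unname(me$variance_explained[1]), ev[1] / sum(ev),
               tolerance = 1e-8)
  # flipping every member's sign is absorbed by the orientation rule
  flipped <- unclass(sd1$expr)
  flipped[members, ] <- 2 * rowMeans(flipped[members, ]) - flipped[members, ]
  me2 <- module_eigengenes(expression_matrix(flipped, "log2"), lab)
  expect_gt(abs(cor(me$eigengenes[, 1], me2$eigengenes[, 1])), 0.999)
})

test_that("a module of identical profiles yields that profile as its ME", {
  prof <- rnorm(30)
  m <- matrix(rep(prof, each = 6), 6, 30, byrow = FALSE)
  m <- t(replicate(6, prof)) + 0
  dimnames(m) <- list(sprintf("g%d", 1:6), sprintf("s%d", 1:30))
  lab <- setNames(rep(1L, 6), rownames(m))
  me <- module_eigengenes(expression_matrix(m, "log2"), lab)
  expect_equal(unname(me$eigengenes[, 1]), unname(scale(prof)[, 1]),
               tolerance = 1e-8)
})

test_that("kME is a bounded correlation and separates members", {
  sd1 <- small_block_data(seed = 8)
  lab <- detect_modules(sd1$expr, small_net_config())
  me <- module_eigengenes(sd1$expr, lab)
  kme <- kme_table(sd1$expr, me$eigengenes)
  expect_true(all(abs(kme) <= 1))
  own <- kme[names(lab)[lab == 1L], "M1"]
  bg <- kme[names(lab)[lab == 0L], "M1"]
  expect_gte(median(own) - median(bg), 0.3)
  # a gene exactly equal to an ME correlates 1 with it
  m2 <- rbind(unclass(sd1$expr), me1 = me$eigengenes[, "M1"])
  kme2 <- kme_table(expression_matrix(m2, "log2"), me$eigengenes)
  expect_equal(unname(kme2["me1", "M1"]), 1, tolerance = 1e-10)
})

test_that("hub selection takes ceil(top_frac * size) with lexical ties", {
  kme <- matrix(seq(1, 0, length.out = 50), 50, 1,
                dimnames = list(sprintf("g%02d", 1:50), "M1"))
  lab <- setNames(rep(1L, 50), rownames(kme))
  expect_length(hub_genes(kme, lab)$M1, 5L)
  kme2 <- matrix(rep(0.5, 101), 101, 1,
                 dimnames = list(sprintf("g%03d", 1:101), "M1"))
  lab2 <- setNames(rep(1L, 101), rownames(kme2))
  hubs <- hub_genes(kme2, lab2)$M1
  expect_length(hubs, 11L)                       # ceil(10.1)
  expect_identical(hubs, sort(rownames(kme2))[1:11])  # lexical tie-break
  expect_true(all(hubs %in% names(lab2)[lab2 == 1L]))
})

test_that("module-trait correlation handles self, nulls and constants", {
  sd1 <- small_block_data(seed = 9)
  lab <- detect_modules(sd1$expr, small_net_config())
  me <- module_eigengenes(sd1$expr, lab)$eigengenes
  traits <- cbind(self = me[, 1], const = 1,
                  holey = replace(rnorm(nrow(me)), 1:118, NA))
  rownames(traits) <- rownames(me)
  mt <- module_trait_correlation(me, traits)
  expect_equal(unname(mt$r["M1", "self"]), 1, tolerance = 1e-10)
  expect_lt(mt$p["M1", "self"], 1e-10)
  expect_true(is.na(mt$r["M1", "const"]))
  expect_true(is.na(mt$r["M1", "holey"]))   # < 3 complete pairs
  expect_equal(unname(mt$n["M1", "holey"]), 2)
})

test_that("Fisher module overlap matches the hypergeometric tail", {
  # identical labelings: diagonal overwhelms off-diagonal
  lab <- setNames(rep(1:2, each = 50), sprintf("g%d", 1:100))
  ov <- module_overlap_fisher(lab, lab)
  expect_true(all(diag(ov$p) < 1e-20))
  expect_true(all(ov$p[row(ov$p) != col(ov$p)] > 0.5))
  # 2x2 oracle: universe 20, |A| = 5, |B| = 5, overlap 3
  a <- setNames(c(rep(1L, 5), rep(0L, 15)), sprintf("g%d", 1:20))
  b <- setNames(c(rep(1L, 3), 0L, 0L, 1L, 1L, rep(0L, 13)),
                sprintf("g%d", 1:20))
  p <- module_overlap_fisher(a, b)$p[1, 1]
  oracle <- sum(choose(5, 3:5) * choose(15, 5 - (3:5))) / choose(20, 5)
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_error(module_overlap_fisher(a, setNames(b, paste0("x", 1:20))),
               "universes")
})

test_that("independent random labelings are rarely significant", {
  genes <- sprintf("g%d", 1:300)
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    a <- setNames(sample(rep(1:3, each = 100)), genes)
    b <- setNames(sample(rep(1:3, each = 100)), genes)
    if (min(module_overlap_fisher(a, b)$fdr) > 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the full network fit exposes labels, MEs, kME and hubs", {
  sd1 <- small_block_data(seed = 10)
  net <- fit_network(sd1$expr, small_net_config())
  expect_s3_class(net, "coexpression_network")
  expect_equal(length(net$hubs), 2L)
  expect_equal(ncol(net$eigengenes), 2L)
  expect_lt(bicor(net$eigengenes[, 1], net$eigengenes[, 2]), -0.4)
})
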